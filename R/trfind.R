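# Tandem repeat detection: k-mer seeded candidate periods refined by
# wraparound dynamic-programming alignment.  The alignment scoring is
# the published parameterization (match +2, mismatch -7, indel -7,
# minimum reporting score 50, maximum period 500 bp).

#' Candidate period seeding
#'
#' Lists candidate (position, period) pairs from exact matching k-mers:
#' for every pair of identical k-mers at distance \code{d <= maxPeriod},
#' the position of the earlier k-mer and the distance \code{d} are
#' emitted (deduplicated).  This is the seeding stage of
#' [findTandemRepeats()]; exposed for inspection and testing.
#'
#' @param seq DNA sequence (character or \code{DNAString}).
#' @param k k-mer length (1..12).
#' @param maxPeriod maximum candidate period (bp).
#' @return data.frame with columns \code{position} (1-based start of the
#'   earlier k-mer) and \code{period}.
#' @examples
#' findCandidatePeriods("ACGACGACG", k = 3)
#' @export
findCandidatePeriods <- function(seq, k = 5L, maxPeriod = 500L) {
  x <- .as_dna_chr(seq)
  stopifnot(k >= 1L, k <= 12L)
  if (k > nchar(x))
    return(data.frame(position = integer(0), period = integer(0)))
  s <- cpp_kmer_seeds(x, as.integer(k), as.integer(maxPeriod), 64L)
  if (length(s$pos) == 0L)
    return(data.frame(position = integer(0), period = integer(0)))
  out <- unique(data.frame(position = s$pos - s$dist + 1L, period = s$dist))
  out[order(out$position, out$period), , drop = FALSE]
}

#' Wraparound alignment of a window against a tandem consensus
#'
#' Globally aligns a sequence window against unbounded tandem copies of
#' a consensus period using wraparound dynamic programming: the
#' alignment path may wrap from the end of the period back to its
#' start.  The score is \code{match * #matches - mismatch * #mismatches
#' - indel * #indels}.
#'
#' @param seqWindow the window to align (character or \code{DNAString}).
#' @param consensus the period consensus.
#' @param params a [ScoringParams-class]; defaults to the published
#'   weights 2/7/7.
#' @return a list with \code{score}, \code{percentMatch} (percentage of
#'   alignment columns that are identities), \code{percentIndels},
#'   \code{nMatch}, \code{nMismatch}, \code{nIndel} and
#'   \code{alignment}, a data.frame of alignment columns (\code{op} in
#'   M/X/I/D, 1-based \code{seqPos} and \code{consPos}, and the period
#'   instance index \code{period} delimiting period boundaries).
#' @examples
#' w <- strrep("ACGTACGTGA", 5)
#' wraparoundAlign(w, "ACGTACGTGA")$score  # 2 * 50 = 100
#' @export
wraparoundAlign <- function(seqWindow, consensus, params = scoringParams()) {
  w <- .as_dna_chr(seqWindow); cons <- .as_dna_chr(consensus)
  if (nchar(cons) == 0L) stop("empty consensus")
  if (nchar(w) == 0L) stop("empty sequence window")
  if (nchar(cons) > params@maxPeriod)
    stop("consensus longer than maxPeriod (", params@maxPeriod, ")")
  r <- cpp_wrap_align(w, cons, params@match, params@mismatch, 0L,
                      params@indel, TRUE)
  .wrap_result(r)
}

# shared post-processing of a cpp_wrap_align result
.wrap_result <- function(r) {
  ncol <- length(r$ops)
  op <- c("M", "X", "I", "D")[r$ops]
  consPos <- ifelse(r$cons_pos < 0L, NA_integer_, r$cons_pos + 1L)
  seqPos <- ifelse(r$seq_pos < 0L, NA_integer_, r$seq_pos + 1L)
  # period boundaries: a new instance starts when the consumed consensus
  # coordinate wraps backwards
  period <- integer(ncol)
  if (ncol > 0L) {
    inst <- 1L; prev <- Inf
    for (i in seq_len(ncol)) {
      cp <- consPos[i]
      if (!is.na(cp)) {
        if (cp < prev && is.finite(prev)) inst <- inst + 1L
        prev <- cp
      }
      period[i] <- inst
    }
  }
  tot <- r$n_match + r$n_mismatch + r$n_indel
  list(score = r$score,
       percentMatch = if (tot > 0) 100 * r$n_match / tot else NA_real_,
       percentIndels = if (tot > 0) 100 * r$n_indel / tot else NA_real_,
       nMatch = r$n_match, nMismatch = r$n_mismatch, nIndel = r$n_indel,
       seqStart = r$seq_start, seqEnd = r$seq_end,
       alignment = data.frame(op = op, seqPos = seqPos, consPos = consPos,
                              period = period))
}

# majority-vote consensus over period-aligned copies; ties resolved by
# the base contributed by the earliest copy; unaligned positions keep
# the previous consensus base
.majority_consensus <- function(window, aln, cons) {
  p <- nchar(cons)
  cb <- strsplit(cons, "", fixed = TRUE)[[1]]
  wb <- strsplit(window, "", fixed = TRUE)[[1]]
  a <- aln$alignment
  a <- a[a$op %in% c("M", "X"), , drop = FALSE]
  if (nrow(a) == 0L) return(cons)
  for (j in seq_len(p)) {
    rows <- a$consPos == j
    if (!any(rows)) next
    bases <- wb[a$seqPos[rows]]
    tab <- table(bases)
    best <- names(tab)[tab == max(tab)]
    cb[j] <- if (length(best) == 1L) best else bases[bases %in% best][1L]
  }
  paste(cb, collapse = "")
}

# refine one candidate (window, period): local wraparound alignment with
# iterative majority-consensus updates; recurses into the unmatched
# remainder of the window to catch multiple arrays of the same period
.refine_candidate <- function(seqchr, wstart, wend, d, params,
                              depth = 0L) {
  width <- wend - wstart + 1L
  if (width < max(2L * d, ceiling(params@minCopies * d) - 2L) ||
      width < d + 1L || depth > 6L)
    return(list())
  window <- substr(seqchr, wstart, wend)
  if (.n_frac(window) > 0.10) return(list())
  offsets <- unique(c(1L, max(1L, (width - d) %/% 2L)))
  best <- NULL; bestCons <- NULL
  for (s in offsets) {
    cons0 <- substr(window, s, s + d - 1L)
    if (nchar(cons0) < d || grepl("N", cons0, fixed = TRUE)) next
    a <- .wrap_result(cpp_wrap_align(window, cons0, params@match,
                                     params@mismatch, 0L, params@indel,
                                     FALSE))
    if (is.null(best) || a$score > best$score) { best <- a; bestCons <- cons0 }
  }
  if (is.null(best) || best$score < max(2L * d, params@minScore %/% 2L))
    return(list())
  # iterative consensus refinement
  for (it in 1:3) {
    cons1 <- .majority_consensus(window, best, bestCons)
    if (cons1 == bestCons) break
    a <- .wrap_result(cpp_wrap_align(window, cons1, params@match,
                                     params@mismatch, 0L, params@indel,
                                     FALSE))
    if (a$score <= best$score) break
    best <- a; bestCons <- cons1
  }
  # minimal-period reduction: consensus that is itself an exact tandem
  # of a sub-period is replaced by the sub-period
  p <- nchar(bestCons)
  for (q in seq_len(p - 1L)) {
    if (p %% q != 0L) next
    if (bestCons == strrep(substr(bestCons, 1L, q), p %/% q)) {
      return(.refine_candidate(seqchr, wstart, wend, q, params, depth))
    }
  }
  out <- list()
  consumed <- sum(best$alignment$op %in% c("M", "X", "D"))
  copies <- consumed / d
  if (best$score >= params@minScore && round1(copies) >= params@minCopies) {
    span_start <- wstart + best$seqStart - 1L
    span_end <- wstart + best$seqEnd - 1L
    out[[1L]] <- list(start = span_start, end = span_end, period = d,
                      copies = round1(copies), consensus = bestCons,
                      percentMatch = best$percentMatch,
                      percentIndels = best$percentIndels,
                      score = best$score,
                      entropy = shannonEntropy(substr(seqchr, span_start,
                                                      span_end)))
    # recurse left / right of the matched span
    if (best$seqStart - 1L >= 2L * d)
      out <- c(out, .refine_candidate(seqchr, wstart,
                                      wstart + best$seqStart - 2L, d,
                                      params, depth + 1L))
    if (wend - (wstart + best$seqEnd - 1L) >= 2L * d)
      out <- c(out, .refine_candidate(seqchr, wstart + best$seqEnd, wend,
                                      d, params, depth + 1L))
  }
  out
}

.n_frac <- function(x) {
  n <- nchar(x)
  if (n == 0L) return(0)
  (n - nchar(gsub("N", "", x, fixed = TRUE))) / n
}

# redundancy reduction: candidates sorted by score (ties: smaller
# period); a candidate whose span heavily overlaps an accepted report
# is the same array seen at a harmonic or near-harmonic period and is
# dropped -- reports with distinct spans are always kept
.dedup_reports <- function(reports) {
  if (length(reports) <= 1L) return(reports)
  # minimal-period preference: a noisy array realigned at a harmonic
  # period (2p, 3p, ...) can overfit copy-specific variants and edge
  # the true period out on raw score; when two heavily overlapping
  # reports are near-harmonic and the smaller period scores within
  # 85% of the larger, the larger-period report is discarded first
  drop <- rep(FALSE, length(reports))
  for (i in seq_along(reports)) for (j in seq_along(reports)) {
    if (i == j || drop[i] || drop[j]) next
    r <- reports[[i]]; a <- reports[[j]]
    if (r$period >= a$period) next
    ov <- min(r$end, a$end) - max(r$start, a$start) + 1L
    if (ov <= 0L) next
    if (ov / min(r$end - r$start + 1L, a$end - a$start + 1L) <= 0.7) next
    kk <- round(a$period / r$period)
    if (kk < 2L) next  # near-same periods: raw score decides below
    if (abs(a$period - kk * r$period) > 2L) next
    if (r$score >= 0.85 * a$score) drop[j] <- TRUE
  }
  reports <- reports[!drop]
  if (length(reports) <= 1L) return(reports)
  sc <- vapply(reports, `[[`, numeric(1), "score")
  pd <- vapply(reports, `[[`, numeric(1), "period")
  ord <- order(-sc, pd)
  acc <- list()
  for (i in ord) {
    r <- reports[[i]]
    dup <- FALSE
    for (a in acc) {
      ov <- min(r$end, a$end) - max(r$start, a$start) + 1L
      if (ov <= 0L) next
      if (ov / min(r$end - r$start + 1L, a$end - a$start + 1L) > 0.7) {
        dup <- TRUE; break
      }
    }
    if (!dup) acc[[length(acc) + 1L]] <- r
  }
  acc
}

#' Find tandem repeats
#'
#' Detects all maximal tandem repeat arrays in one or more DNA
#' sequences.  Short sequences (<= 300 bp) are scanned by exhaustive
#' period enumeration; longer sequences are seeded by matching k-mer
#' pairs and refined by local wraparound dynamic-programming alignment
#' with iterative majority-vote consensus updates.  Reported arrays
#' satisfy \code{score >= minScore}, \code{period <= maxPeriod} and
#' \code{copy_number >= minCopies}; overlapping reports of the same
#' array at harmonic periods are reduced to the highest-scoring
#' representative (ties broken towards the smaller period).  Only the
#' forward strand is scanned: a tandem array is its own
#' reverse-complement's mirror.
#'
#' @param seq a \code{DNAStringSet} (or named character vector /
#'   single sequence).
#' @param params a [ScoringParams-class].
#' @return a \code{GRanges} with metadata columns \code{period_size},
#'   \code{copy_number} (1 decimal), \code{percent_match},
#'   \code{percent_indels}, \code{score}, \code{entropy} and
#'   \code{consensus}.
#' @examples
#' findTandemRepeats(strrep("AT", 30))
#' @export
findTandemRepeats <- function(seq, params = scoringParams()) {
  if (is(seq, "DNAStringSet")) {
    seqs <- as.character(seq)
  } else {
    seqs <- .as_dna_chr(seq)
    if (is.null(names(seqs)))
      names(seqs) <- paste0("seq", seq_along(seqs))
  }
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("seq", seq_along(seqs))
  all <- lapply(names(seqs), function(id) {
    reps <- .scan_sequence(seqs[[id]], params)
    if (length(reps) == 0L) return(NULL)
    GRanges(seqnames = id,
            ranges = IRanges::IRanges(
              start = vapply(reps, `[[`, numeric(1), "start"),
              end = vapply(reps, `[[`, numeric(1), "end")),
            period_size = as.integer(vapply(reps, `[[`, numeric(1), "period")),
            copy_number = vapply(reps, `[[`, numeric(1), "copies"),
            percent_match = vapply(reps, `[[`, numeric(1), "percentMatch"),
            percent_indels = vapply(reps, `[[`, numeric(1), "percentIndels"),
            score = vapply(reps, `[[`, numeric(1), "score"),
            entropy = vapply(reps, `[[`, numeric(1), "entropy"),
            consensus = vapply(reps, `[[`, character(1), "consensus"))
  })
  all <- all[!vapply(all, is.null, logical(1))]
  if (length(all) == 0L) {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(
      period_size = integer(0), copy_number = numeric(0),
      percent_match = numeric(0), percent_indels = numeric(0),
      score = numeric(0), entropy = numeric(0), consensus = character(0))
    return(gr)
  }
  res <- do.call(c, all)
  res[order(as.character(seqnames(res)), start(res))]
}

.scan_sequence <- function(seqchr, params) {
  n <- nchar(seqchr)
  reports <- list()
  if (n <= 300L) {
    for (d in seq_len(min(params@maxPeriod, n %/% 2L)))
      reports <- c(reports, .refine_candidate(seqchr, 1L, n, d, params))
  } else {
    k <- params@seedK
    s <- cpp_kmer_seeds(seqchr, k, params@maxPeriod, 16L)
    if (length(s$pos) > 0L) {
      byd <- split(s$pos, s$dist)
      for (dch in names(byd)) {
        d <- as.integer(dch)
        pos <- sort(unique(byd[[dch]]))
        gaps <- c(Inf, diff(pos))
        grp <- cumsum(gaps > d + 2L * k)
        for (g in split(pos, grp)) {
          span <- max(g) - min(g) + k
          # a real array of period d produces matching k-mers at most
          # clean positions of its span; chance k-mer pairs do not
          if (length(g) < max(2L, d %/% 8L)) next
          if (span < 0.5 * d) next
          wstart <- max(1L, min(g) + 1L - d)
          wend <- min(n, max(g) + k + 2L * d)
          reports <- c(reports,
                       .refine_candidate(seqchr, wstart, wend, d, params))
        }
      }
    }
  }
  .dedup_reports(reports)
}

#' Genome-level tandem repeat summary
#'
#' Summary statistics of a repeat scan over one genome: repeat count,
#' total repeat extent (overlapping arrays collapsed to their union
#' before summing), percentage of the genome covered, and unweighted
#' means and ranges of period size, copy number and internal match.
#'
#' @param repeats \code{GRanges} from [findTandemRepeats()] (features
#'   of one genome).
#' @param genome the genome sequence (for its length), or a single
#'   integer giving the genome size in bp.
#' @param genomeId identifier used in the output (defaults to the
#'   \code{seqnames} of the repeats, or \code{"genome"}).
#' @return a one-row data.frame with columns \code{genome_id},
#'   \code{genome_size}, \code{n_repeats}, \code{total_repeat_bp},
#'   \code{pct_genome}, \code{mean_period}, \code{period_min},
#'   \code{period_max}, \code{mean_copies}, \code{copies_min},
#'   \code{copies_max}, \code{mean_internal_match}.  With no repeats
#'   the counts are 0 and the means are \code{NA}.
#' @export
summarizeRepeats <- function(repeats, genome, genomeId = NULL) {
  gsize <- if (is.numeric(genome)) as.integer(genome) else
    nchar(.as_dna_chr(genome))
  if (is.null(genomeId)) {
    genomeId <- if (length(repeats) > 0L)
      as.character(seqnames(repeats))[1L] else "genome"
  }
  n <- length(repeats)
  if (n == 0L) {
    return(data.frame(genome_id = genomeId, genome_size = gsize,
                      n_repeats = 0L, total_repeat_bp = 0L, pct_genome = 0,
                      mean_period = NA_real_, period_min = NA_integer_,
                      period_max = NA_integer_, mean_copies = NA_real_,
                      copies_min = NA_real_, copies_max = NA_real_,
                      mean_internal_match = NA_real_))
  }
  m <- mcols(repeats)
  tot <- sum(width(GenomicRanges::reduce(repeats, ignore.strand = TRUE)))
  data.frame(genome_id = genomeId, genome_size = gsize, n_repeats = n,
             total_repeat_bp = tot, pct_genome = 100 * tot / gsize,
             mean_period = mean(m$period_size),
             period_min = min(m$period_size),
             period_max = max(m$period_size),
             mean_copies = mean(m$copy_number),
             copies_min = min(m$copy_number),
             copies_max = max(m$copy_number),
             mean_internal_match = mean(m$percent_match))
}
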