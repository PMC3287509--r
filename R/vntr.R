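# VNTR locus characterization: decomposition of a locus into period
# instances against a consensus period, plus internal structure
# (direct repeats, palindromic hairpins/dyads).

# copy-string notation shared by the decomposer and the generator:
# full copies, then half copies, then terminal fractions,
# e.g. "7+0.3", "4+2x0.5", "3x0.5", "0.8"
.copy_string <- function(nFull, nHalf, partials) {
  partials <- partials[partials > 0]
  parts <- character(0)
  if (nFull > 0L) parts <- c(parts, as.character(nFull))
  if (nHalf > 0L) parts <- c(parts, sprintf("%dx0.5", nHalf))
  if (length(partials) > 0L)
    parts <- c(parts, sprintf("%.1f", partials))
  if (length(parts) == 0L) return("0")
  paste(parts, collapse = "+")
}

#' Fractional copy number
#'
#' Copy-number contribution of a truncated (partial) period copy:
#' the aligned length divided by the period length, rounded to one
#' decimal (round-half-even).
#'
#' @param alignedLen aligned length in bp (0 < alignedLen <= periodLen).
#' @param periodLen full period length in bp.
#' @return numeric scalar with one decimal.
#' @examples
#' fractionalCopy(108, 141)  # 0.8 -- the core period of a 141 bp VNTR
#' fractionalCopy(141, 141)  # 1.0
#' @export
fractionalCopy <- function(alignedLen, periodLen) {
  if (periodLen <= 0) stop("zero or negative period length")
  if (alignedLen <= 0 || alignedLen > periodLen)
    stop("alignedLen must be in (0, periodLen]")
  round1(alignedLen / periodLen)
}

#' Decompose a VNTR locus into period instances
#'
#' Aligns a locus against a consensus period with local wraparound
#' dynamic programming and cuts the alignment path at consensus
#' coordinate zero into period instances.  Instances are classified
#' \code{full} (complete copy), \code{half} (internal deletion of at
#' least \code{halfThreshold} bp, counted 0.5 copies -- the published
#' half-copies carry 25 and 32 bp deletions) or \code{partial}
#' (truncated copy at an array end, counted by its aligned fraction
#' rounded to one decimal).
#'
#' Decomposition uses affine gap costs (match +2, mismatch -7, gap
#' open -7, gap extend -1 by default) so that the structured internal
#' deletions and terminal half/partial copies of real VNTR alleles are
#' retained as contiguous gaps rather than trimmed from the alignment,
#' while alignment drift into the AT-rich flanks stays strongly
#' penalized.
#'
#' @param locusSeq the locus (may include flanking sequence; the
#'   matched repeat region is located within it).
#' @param consensus the period consensus (>= 10 bp).
#' @param locusId identifier stored in the result.
#' @param halfThreshold minimal internal deletion (bp) classifying an
#'   instance as a half copy.
#' @param minScore minimal alignment score; below it a "no repeat
#'   structure" result (copy number \code{NA}) is returned, not an
#'   error.
#' @param match,mismatch,gapOpen,gapExtend decomposition alignment
#'   weights (a gap of length L costs \code{gapOpen + L * gapExtend}).
#' @return a [PeriodDecomposition-class].
#' @examples
#' cons <- paste(rep("ACGTATTGCA", 2), collapse = "")
#' decomposePeriods(strrep(cons, 3), cons)
#' @export
decomposePeriods <- function(locusSeq, consensus, locusId = "locus",
                             halfThreshold = 20L, minScore = 50L,
                             match = 2L, mismatch = 7L, gapOpen = 7L,
                             gapExtend = 1L) {
  locus <- .as_dna_chr(locusSeq); cons <- .as_dna_chr(consensus)
  if (nchar(cons) < 10L) stop("consensus must be >= 10 bp")
  .check_dna(cons, "consensus"); .check_dna(locus, "locus")
  p <- nchar(cons)
  r <- cpp_wrap_align(locus, cons, as.integer(match), as.integer(mismatch),
                      as.integer(gapOpen), as.integer(gapExtend), FALSE)
  empty <- new("PeriodDecomposition", locusId = locusId, consensus = cons,
               region = IRanges::IRanges(),
               instances = .empty_instances(),
               copyNumber = NA_real_, copyString = NA_character_,
               score = as.numeric(r$score))
  if (r$score < minScore) return(empty)
  a <- .wrap_result(r)$alignment
  if (nrow(a) == 0L) return(empty)
  inst <- .build_instances(a, p, halfThreshold)
  if (nrow(inst) == 0L) return(empty)
  nFull <- sum(inst$class == "full")
  nHalf <- sum(inst$class == "half")
  partials <- inst$copyContribution[inst$class == "partial"]
  cn <- round(nFull + 0.5 * nHalf + sum(partials), 3)
  new("PeriodDecomposition", locusId = locusId, consensus = cons,
      region = IRanges::IRanges(inst$start[1L], inst$end[nrow(inst)]),
      instances = inst, copyNumber = cn,
      copyString = .copy_string(nFull, nHalf, partials),
      score = as.numeric(r$score))
}

.empty_instances <- function() {
  data.frame(start = integer(0), end = integer(0), class = character(0),
              alignedFraction = numeric(0), identity = numeric(0),
              copyContribution = numeric(0))
}

# cut an alignment path (columns M/X/I/D with 1-based seqPos/consPos and
# period index) into classified period instances
.build_instances <- function(a, p, halfThreshold) {
  idx <- unique(a$period)
  rows <- lapply(idx, function(k) {
    seg <- a[a$period == k, , drop = FALSE]
    sp <- seg$seqPos[!is.na(seg$seqPos)]
    if (length(sp) == 0L) return(NULL)  # fully deleted period: no instance
    aligned <- sum(seg$op %in% c("M", "X"))
    nm <- sum(seg$op == "M"); nx <- sum(seg$op == "X")
    # deletion runs: consecutive D columns with consecutive consensus pos
    d <- seg[seg$op == "D", , drop = FALSE]
    dels <- NULL
    if (nrow(d) > 0L) {
      brk <- cumsum(c(1L, diff(d$consPos) != 1L))
      dels <- t(vapply(split(d$consPos, brk), function(cp)
        c(offset = cp[1L], length = length(cp)), numeric(2)))
    }
    list(start = min(sp), end = max(sp),
         alignedFraction = aligned / p,
         identity = if (nm + nx > 0L) 100 * nm / (nm + nx) else NA_real_,
         maxDeletion = if (is.null(dels)) 0L else max(dels[, "length"]),
         deletions = dels)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  n <- length(rows)
  if (n == 0L) return(.empty_instances())
  cls <- character(n); contrib <- numeric(n)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    if (r$maxDeletion >= halfThreshold) {
      cls[i] <- "half"; contrib[i] <- 0.5
    } else if (r$alignedFraction >= 0.9) {
      cls[i] <- "full"; contrib[i] <- 1.0
    } else if (i == 1L || i == n) {
      cls[i] <- "partial"; contrib[i] <- round1(r$alignedFraction)
    } else {
      # interior copy with scattered small indels: counted full
      cls[i] <- "full"; contrib[i] <- 1.0
    }
  }
  out <- data.frame(
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    class = cls,
    alignedFraction = vapply(rows, `[[`, numeric(1), "alignedFraction"),
    identity = vapply(rows, `[[`, numeric(1), "identity"),
    copyContribution = contrib)
  out$deletions <- lapply(rows, `[[`, "deletions")
  # enforce tiling: adjacent instances must abut (alignment path is
  # contiguous in the locus, so this closes gaps from insertion columns
  # attributed across a boundary)
  if (nrow(out) > 1L)
    out$start[-1L] <- out$end[-nrow(out)] + 1L
  out
}

# greedy non-overlapping occurrence count (left to right) of an exact
# unit in a sequence; returns start positions
.occurrences <- function(seq, unit) {
  n <- nchar(seq); u <- nchar(unit)
  pos <- integer(0); i <- 1L
  while (i + u - 1L <= n) {
    if (substr(seq, i, i + u - 1L) == unit) { pos <- c(pos, i); i <- i + u }
    else i <- i + 1L
  }
  pos
}

#' Find internal direct (and optionally inverted) repeats
#'
#' Reports all maximal exactly-repeated units of length in
#' \code{[minUnit, maxUnit]} occurring at least \code{minOccurrences}
#' times at non-overlapping positions.  A unit is maximal when neither
#' of its one-base extensions repeats as often.  Low-complexity units
#' (Shannon entropy <= \code{minEntropy} bits) are suppressed, so
#' homopolymers are never reported.  With \code{allowInverted}, pairs
#' of a unit and its reverse complement are additionally reported as
#' inverted repeats.
#'
#' @param seq DNA sequence (e.g. a VNTR period).
#' @param minUnit,maxUnit unit length range (bp), \code{minUnit >= 5}.
#' @param minOccurrences minimal repeat count (default 2).
#' @param allowInverted also report unit/reverse-complement pairs.
#' @param minEntropy entropy floor in bits (default 1.0).
#' @return data.frame with columns \code{kind} (\code{direct_repeat} or
#'   \code{inverted_repeat}), \code{unit}, \code{unitLength},
#'   \code{nOccurrences} and a list column \code{positions} (1-based
#'   starts; for inverted pairs the reverse-complement occurrence
#'   positions are in \code{positionsRC}).
#' @export
findDirectRepeats <- function(seq, minUnit = 5L, maxUnit = 20L,
                              minOccurrences = 2L, allowInverted = FALSE,
                              minEntropy = 1.0) {
  x <- .as_dna_chr(seq)
  stopifnot(minUnit >= 5L, maxUnit >= minUnit)
  n <- nchar(x)
  out <- list()
  seen <- character(0)
  hi <- min(maxUnit, n %/% minOccurrences)
  for (u in if (hi >= minUnit) hi:minUnit else integer(0)) {
    starts <- seq_len(max(0L, n - u + 1L))
    units <- unique(substring(x, starts, starts + u - 1L))
    for (unit in units) {
      if (unit %in% seen) next
      pos <- .occurrences(x, unit)
      if (length(pos) < minOccurrences) next
      if (shannonEntropy(unit) <= minEntropy) next
      # maximality: no one-base extension of the unit (any flank base
      # observed at any occurrence) repeats as often
      ext <- unique(c(
        paste0(substring(x, pos - 1L, pos - 1L), unit)[pos > 1L],
        paste0(unit, substring(x, pos + u, pos + u))[pos + u <= n]))
      ext <- ext[nchar(ext) == u + 1L]
      maximal <- TRUE
      for (e in ext)
        if (length(.occurrences(x, e)) >= length(pos)) { maximal <- FALSE; break }
      if (!maximal) next
      seen <- c(seen, unit)
      out[[length(out) + 1L]] <- data.frame(
        kind = "direct_repeat", unit = unit, unitLength = u,
        nOccurrences = length(pos))
      out[[length(out)]]$positions <- list(pos)
    }
  }
  if (allowInverted) {
    hi2 <- min(maxUnit, n - minUnit)
    for (u in if (hi2 >= minUnit) hi2:minUnit else integer(0)) {
      starts <- seq_len(max(0L, n - u + 1L))
      units <- unique(substring(x, starts, starts + u - 1L))
      for (unit in units) {
        rc <- revcomp(unit)
        if (rc == unit) next   # palindromic units belong to findDyads()
        if (unit > rc) next    # report each pair once
        pu <- .occurrences(x, unit); pr <- .occurrences(x, rc)
        if (length(pu) < 1L || length(pr) < 1L) next
        if (length(pu) + length(pr) < minOccurrences) next
        if (shannonEntropy(unit) <= minEntropy) next
        row <- data.frame(kind = "inverted_repeat", unit = unit,
                          unitLength = u, nOccurrences = length(pu) + length(pr))
        row$positions <- list(pu); row$positionsRC <- list(pr)
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(kind = character(0), unit = character(0),
                      unitLength = integer(0), nOccurrences = integer(0))
    res$positions <- list()
    return(res)
  }
  res <- do.call(rbind, lapply(out, function(d) {
    if (is.null(d$positionsRC)) d$positionsRC <- list(NULL)
    d
  }))
  res[order(-res$unitLength, vapply(res$positions, min, numeric(1))), ,
      drop = FALSE]
}

#' Find palindromic (dyad) repeats
#'
#' Reports all hairpin-forming dyads: positions where a stem arm of
#' length >= \code{minStem} is followed, after a loop of at most
#' \code{maxLoop} bases, by its reverse complement (allowing up to
#' \code{maxMismatch} mismatching stem pairs).  Dyads are maximal by
#' stem extension: neither growing the stem outward nor inward (into
#' the loop) yields a valid dyad.  A stem of 9 with a loop of 5 spans
#' 2*9+5 = 23 bp, the published hairpin geometry.
#'
#' @param seq DNA sequence.
#' @param minStem minimal stem length (>= 4).
#' @param maxLoop maximal loop length (bp).
#' @param maxMismatch mismatching stem pairs tolerated (default 0).
#' @return data.frame: \code{start} (1-based, first base of the left
#'   arm), \code{end} (last base of the right arm), \code{stemLen},
#'   \code{loopLen}, \code{mismatches}, \code{span}.
#' @examples
#' arm <- "GATCCGTAC"
#' findDyads(paste0("AAA", arm, "TTTTT", revcomp(arm), "AAA"))
#' @export
findDyads <- function(seq, minStem = 4L, maxLoop = 12L, maxMismatch = 0L) {
  x <- .as_dna_chr(seq)
  stopifnot(minStem >= 4L)
  n <- nchar(x)
  b <- strsplit(x, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  cb <- unname(comp[b])
  # pairs(i, j): b[i] pairs with b[j] iff b[i] == complement(b[j])
  pairs <- function(i, j) !is.na(b[i]) && b[i] == cb[j]
  mism <- function(i, j, stem) {
    # arm1 = [i, i+stem-1], arm2 = [j, j+stem-1]; arm1[k] pairs arm2[stem+1-k]
    sum(vapply(seq_len(stem), function(k)
      !pairs(i + k - 1L, j + stem - k), logical(1)))
  }
  out <- list()
  for (i in seq_len(n)) {
    for (loop in 0:maxLoop) {
      maxStem <- (n - i + 1L - loop) %/% 2L
      if (maxStem < minStem) next
      for (stem in minStem:maxStem) {
        j <- i + stem + loop
        if (j + stem - 1L > n) break
        if (mism(i, j, stem) > maxMismatch) next
        # maximal by stem extension?
        extOut <- i > 1L && j + stem <= n &&
          mism(i - 1L, j, stem + 1L) <= maxMismatch
        extIn <- loop >= 2L && mism(i, j - 1L, stem + 1L) <= maxMismatch
        if (extOut || extIn) next
        out[[length(out) + 1L]] <- data.frame(
          start = i, end = j + stem - 1L, stemLen = stem, loopLen = loop,
          mismatches = mism(i, j, stem), span = 2L * stem + loop)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      stemLen = integer(0), loopLen = integer(0),
                      mismatches = integer(0), span = integer(0)))
  res <- unique(do.call(rbind, out))
  res[order(res$start, res$end), , drop = FALSE]
}

#' Copy-number character matrix across strains
#'
#' Assembles per-strain, per-locus copy numbers into a strains x loci
#' matrix of cladistic characters.  A locus missing for a strain is an
#' explicit \code{NA}, never a silent 0.
#'
#' @param decompositionsByStrain named list (one element per strain) of
#'   named lists (one element per locus) of
#'   [PeriodDecomposition-class] objects, [MlvaAllele-class] objects
#'   or plain copy numbers.
#' @return numeric matrix, rownames = strains, colnames = loci.
#' @seealso [copyNumberDistance()]
#' @export
copyNumberCharacters <- function(decompositionsByStrain) {
  stopifnot(length(decompositionsByStrain) >= 2L)
  loci <- unique(unlist(lapply(decompositionsByStrain, names)))
  if (length(loci) == 0L) stop("no shared locus ids")
  m <- matrix(NA_real_, nrow = length(decompositionsByStrain),
              ncol = length(loci),
              dimnames = list(names(decompositionsByStrain), loci))
  for (s in names(decompositionsByStrain)) {
    for (loc in names(decompositionsByStrain[[s]])) {
      v <- decompositionsByStrain[[s]][[loc]]
      m[s, loc] <- if (is.numeric(v)) v else copyNumber(v)
    }
  }
  m
}

#' Manhattan distance between copy-number profiles
#'
#' Pairwise Manhattan (city-block) distance over the copy-number
#' characters of [copyNumberCharacters()]; loci that are \code{NA} in
#' either strain are excluded from that pair.
#'
#' @param m matrix from [copyNumberCharacters()].
#' @return a symmetric distance matrix with an \code{"nLoci"}
#'   attribute counting the loci used per pair.
#' @export
copyNumberDistance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  used <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    d[i, j] <- sum(abs(m[i, ok] - m[j, ok]))
    used[i, j] <- sum(ok)
  }
  attr(d, "nLoci") <- used
  d
}
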