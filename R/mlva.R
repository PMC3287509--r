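# In-silico PCR typing: primer site location, amplicon extraction and
# sizing, per-locus allele calling, multi-locus profiles.

#' A PCR primer pair
#'
#' @slot locusId character.
#' @slot forward,reverse character, 5'->3' primer sequences (>= 15 bp,
#'   IUPAC ambiguity codes allowed).
#' @slot maxMismatch integer, substitutions tolerated per primer site
#'   (default 0; the markers are designed against a reference genome
#'   and amplification failure under divergence is informative).
#' @slot maxProduct integer, maximal product size in bp (default 5000).
#' @export
setClass("PrimerPair", representation(
  locusId = "character", forward = "character", reverse = "character",
  maxMismatch = "integer", maxProduct = "integer"))

setValidity("PrimerPair", function(object) {
  if (nchar(object@forward) < 15L || nchar(object@reverse) < 15L)
    return("primers must be >= 15 bp")
  ok <- !grepl(sprintf("[^%s]", paste(names(Biostrings::IUPAC_CODE_MAP),
                                      collapse = "")),
               c(object@forward, object@reverse))
  if (!all(ok)) return("primers must be DNA (IUPAC codes allowed)")
  if (object@maxMismatch < 0L) return("maxMismatch must be >= 0")
  if (object@maxProduct < 1L) return("maxProduct must be positive")
  TRUE
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair %s: %s / %s (<=%d mismatches, <=%d bp)\n",
              object@locusId, object@forward, object@reverse,
              object@maxMismatch, object@maxProduct))
})

#' Construct a primer pair
#'
#' @param locusId locus identifier.
#' @param forward,reverse primer sequences, 5'->3'.
#' @param maxMismatch substitutions tolerated per site (default 0).
#' @param maxProduct maximal product length in bp.
#' @return a [PrimerPair-class].
#' @export
primerPair <- function(locusId, forward, reverse, maxMismatch = 0L,
                       maxProduct = 5000L) {
  new("PrimerPair", locusId = locusId, forward = toupper(forward),
      reverse = toupper(reverse), maxMismatch = as.integer(maxMismatch),
      maxProduct = as.integer(maxProduct))
}

#' Packaged MLVA primer set
#'
#' The marker primers designed against the wMel reference genome for
#' the two intergenic VNTR loci (VNTR-141, VNTR-105) and the two
#' ankyrin-repeat genes (WD0550, WD0766), plus the standard wsp 81F/691R
#' pair used as a DNA quality control.
#'
#' @param maxMismatch substitutions tolerated per primer site, applied
#'   to every pair (default 0).
#' @return named list of [PrimerPair-class] objects.
#' @examples
#' mlvaPrimers()[["VNTR-141"]]
#' @export
mlvaPrimers <- function(maxMismatch = 0L) {
  tab <- list(
    c("VNTR-141", "GGAGTATTATTGATATGCG",        "GACTAAAGGTTAGTTGCAT"),
    c("VNTR-105", "GCAATTGAAAATGTGGTGCC",       "ATGACACCTTACTTAACCGTC"),
    c("WD0550",   "GGCCACCATGGGATCAGAATTTGAAG", "GATGACTTATACGCAGCCCCATAG"),
    c("WD0766",   "GACCACCATGAAATATGACAAATTT",  "TCAAGTAAGTGCTTTTTCTGTC"),
    c("wsp",      "TGGTCCAATAAGTGATGAAGAAAC",   "AAAAATTAAACGCTACTCCA"))
  out <- lapply(tab, function(r)
    primerPair(r[1], r[2], r[3], maxMismatch = maxMismatch))
  names(out) <- vapply(tab, `[[`, character(1), 1L)
  out
}

#' Locate primer binding sites on a template
#'
#' Finds all sites where the primer matches the template with at most
#' \code{maxMismatch} substitutions (no indels).  Forward sites are
#' direct matches; reverse sites are matches of the primer's reverse
#' complement (the primer would anneal to the minus strand).  IUPAC
#' ambiguity codes in the primer match their expansion sets.
#'
#' @param template template DNA (character or \code{DNAString}).
#' @param primer primer sequence, 5'->3'.
#' @param maxMismatch substitutions tolerated.
#' @return data.frame: \code{start}, \code{end} (1-based footprint on
#'   the template), \code{strand} (\code{"+"} forward, \code{"-"}
#'   reverse).
#' @export
findPrimerSites <- function(template, primer, maxMismatch = 0L) {
  tmpl <- Biostrings::DNAString(.as_dna_chr(template))
  pr <- Biostrings::DNAString(toupper(primer))
  if (length(pr) > length(tmpl))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  fixed <- c(pattern = FALSE, subject = TRUE)
  fwd <- Biostrings::matchPattern(pr, tmpl, max.mismatch = maxMismatch,
                                  fixed = fixed)
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pr), tmpl,
                                  max.mismatch = maxMismatch, fixed = fixed)
  out <- rbind(
    data.frame(start = BiocGenerics::start(fwd), end = BiocGenerics::end(fwd),
               strand = rep("+", length(fwd))),
    data.frame(start = BiocGenerics::start(rev), end = BiocGenerics::end(rev),
               strand = rep("-", length(rev))))
  out[order(out$start), , drop = FALSE]
}

#' In-silico PCR
#'
#' Predicts PCR products of a primer pair on a template: every forward
#' site combined with every downstream reverse site yields one
#' amplicon, provided the product does not exceed
#' \code{maxProduct}.  Product length is measured from the 5' end of
#' the forward footprint to the 5' end of the reverse footprint on the
#' template, i.e. both primer sequences are included (the standard PCR
#' product convention).
#'
#' @param template template DNA; a \code{DNAStringSet} is processed
#'   per record.
#' @param pair a [PrimerPair-class].
#' @param templateId identifier for a bare character template.
#' @return data.frame: \code{template_id}, \code{locus_id},
#'   \code{start}, \code{end}, \code{length}.  No site pair gives a
#'   zero-row frame.
#' @examples
#' tp <- paste0(strrep("GATTACAGATCAGGAC", 2), strrep("TTGACA", 20),
#'              strrep("CAGGATCGATTACAGC", 2))
#' pp <- primerPair("toy", substr(tp, 1, 16), revcomp(substr(tp, nchar(tp) - 15, nchar(tp))))
#' inSilicoPCR(tp, pp)
#' @export
inSilicoPCR <- function(template, pair, templateId = "template") {
  stopifnot(is(pair, "PrimerPair"))
  if (is(template, "DNAStringSet")) {
    res <- lapply(seq_along(template), function(i)
      inSilicoPCR(as.character(template[[i]]), pair,
                  names(template)[i] %||% paste0("template", i)))
    return(do.call(rbind, res))
  }
  tmpl <- .as_dna_chr(template)
  sites <- findPrimerSites(tmpl, pair@forward, pair@maxMismatch)
  fwd <- sites[sites$strand == "+", , drop = FALSE]
  rsites <- findPrimerSites(tmpl, pair@reverse, pair@maxMismatch)
  rev <- rsites[rsites$strand == "-", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev))) {
    if (rev$start[j] <= fwd$end[i]) next
    len <- rev$end[j] - fwd$start[i] + 1L
    if (len > pair@maxProduct) next
    out[[length(out) + 1L]] <- data.frame(
      template_id = templateId, locus_id = pair@locusId,
      start = fwd$start[i], end = rev$end[j], length = len)
  }
  if (length(out) == 0L)
    return(data.frame(template_id = character(0), locus_id = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0)))
  do.call(rbind, out)
}

#' Call an MLVA allele from an amplicon
#'
#' Decomposes the amplicon against the locus period consensus
#' ([decomposePeriods()]) and emits the allele: amplicon length plus,
#' when repeat structure is present, copy number and copy string.
#' Without repeat structure a size-only allele is returned (size-only
#' typing remains possible).
#'
#' @param ampliconSeq amplicon sequence (primer footprints included).
#' @param consensus locus period consensus, or \code{NULL} for a
#'   size-only allele.
#' @param locusId locus identifier.
#' @param ... passed to [decomposePeriods()].
#' @return an [MlvaAllele-class].
#' @export
callAllele <- function(ampliconSeq, consensus, locusId = "locus", ...) {
  amp <- .as_dna_chr(ampliconSeq)
  if (is.null(consensus)) {
    return(new("MlvaAllele", locusId = locusId,
               ampliconLength = nchar(amp), copyNumber = NA_real_,
               copyString = NA_character_, decomposition = NULL))
  }
  dec <- decomposePeriods(amp, consensus, locusId = locusId, ...)
  new("MlvaAllele", locusId = locusId, ampliconLength = nchar(amp),
      copyNumber = copyNumber(dec), copyString = copyString(dec),
      decomposition = dec)
}

#' Build a multi-locus MLVA profile
#'
#' Runs in-silico PCR for every primer pair over a set of template
#' sequences (e.g. all symbiont sequences present in one DNA extract),
#' calls alleles and assembles the per-strain profile.  A locus with
#' more than one distinct amplicon length is flagged as a multiple
#' infection.  The \code{wsp} pair (if present among \code{pairs})
#' serves as the DNA quality control: a profile whose QC locus does
#' not amplify is flagged \code{qcPassed = FALSE}.
#'
#' @param strainId profile identifier.
#' @param templates \code{DNAStringSet} (or character vector) of
#'   template sequences.
#' @param pairs list of [PrimerPair-class], e.g. [mlvaPrimers()].
#' @param consensi named character vector/list of period consensi by
#'   locus id (loci without a consensus are typed by size only).
#' @param qcLocus id of the quality-control locus (default
#'   \code{"wsp"}); \code{NA} to skip QC.
#' @return an [MlvaProfile-class].
#' @export
buildProfile <- function(strainId, templates, pairs,
                         consensi = NULL, qcLocus = "wsp") {
  stopifnot(length(pairs) >= 1L)
  if (!is(templates, "DNAStringSet"))
    templates <- Biostrings::DNAStringSet(.as_dna_chr(templates))
  if (is.null(names(templates)))
    names(templates) <- paste0("template", seq_along(templates))
  ids <- vapply(pairs, function(p) p@locusId, character(1))
  names(pairs) <- ids
  typing <- setdiff(ids, qcLocus)
  alleles <- list(); flags <- logical(0)
  for (loc in typing) {
    amps <- inSilicoPCR(templates, pairs[[loc]])
    a <- list()
    if (nrow(amps) > 0L) {
      for (r in seq_len(nrow(amps))) {
        seqs <- as.character(templates[[amps$template_id[r]]])
        ampseq <- substr(seqs, amps$start[r], amps$end[r])
        cons <- if (!is.null(consensi) && loc %in% names(consensi))
          consensi[[loc]] else NULL
        a[[length(a) + 1L]] <- callAllele(ampseq, cons, locusId = loc)
      }
    }
    alleles[[loc]] <- a
    lens <- unique(vapply(a, ampliconLength, integer(1)))
    flags[loc] <- length(lens) > 1L
  }
  qc <- NA
  if (!is.na(qcLocus) && qcLocus %in% ids)
    qc <- nrow(inSilicoPCR(templates, pairs[[qcLocus]])) > 0L
  new("MlvaProfile", strainId = strainId, alleles = alleles,
      multipleInfection = flags, qcPassed = qc)
}

#' Manhattan distance between two MLVA profiles
#'
#' Distance over per-locus copy numbers of two profiles.  Loci missing
#' a copy number (no amplification, size-only alleles, or ambiguous
#' multi-allele loci) are excluded; their count is reported in the
#' \code{"nExcluded"} attribute.
#'
#' @param p1,p2 [MlvaProfile-class] objects.
#' @return numeric distance with attributes \code{"nLoci"} (used) and
#'   \code{"nExcluded"}.
#' @export
profileDistance <- function(p1, p2) {
  shared <- intersect(names(alleles(p1)), names(alleles(p2)))
  if (length(shared) == 0L) stop("profiles share no locus")
  cn <- function(p, loc) {
    a <- alleles(p)[[loc]]
    if (length(a) != 1L) return(NA_real_)
    copyNumber(a[[1L]])
  }
  v1 <- vapply(shared, cn, numeric(1), p = p1)
  v2 <- vapply(shared, cn, numeric(1), p = p2)
  ok <- !is.na(v1) & !is.na(v2)
  d <- sum(abs(v1[ok] - v2[ok]))
  attr(d, "nLoci") <- sum(ok)
  attr(d, "nExcluded") <- sum(!ok)
  d
}

#' Serialize profiles to TSV
#'
#' One row per strain/locus/allele: strain, locus, amplicon length,
#' copy string, flags.
#'
#' @param profiles list of [MlvaProfile-class].
#' @param path output path.
#' @return invisibly, the written data.frame.
#' @export
writeProfileTsv <- function(profiles, path) {
  rows <- list()
  for (p in profiles) {
    for (loc in names(alleles(p))) {
      a <- alleles(p)[[loc]]
      flag <- paste(c(
        if (isTRUE(p@multipleInfection[[loc]])) "multiple_infection",
        if (isFALSE(qcPassed(p))) "qc_failed"), collapse = ",")
      if (length(a) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          strain = p@strainId, locus = loc, length = NA_integer_,
          copy_string = NA_character_, flags = flag)
      } else for (al in a) {
        rows[[length(rows) + 1L]] <- data.frame(
          strain = p@strainId, locus = loc, length = ampliconLength(al),
          copy_string = copyString(al), flags = flag)
      }
    }
  }
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Gel-like report of amplicon sizes
#'
#' Human-readable band report: per strain and locus, amplicon lengths
#' collapsed when within +/- \code{resolution} bp (an agarose
#' resolution surrogate).  The collapse applies only to this report,
#' never to the underlying data.
#'
#' @param profiles list of [MlvaProfile-class].
#' @param resolution bp window within which bands are merged.
#' @return character vector of report lines.
#' @export
gelReport <- function(profiles, resolution = 5L) {
  out <- character(0)
  for (p in profiles) {
    out <- c(out, sprintf("strain %s%s", p@strainId,
                          if (isFALSE(qcPassed(p))) "  [QC FAILED]" else ""))
    for (loc in names(alleles(p))) {
      lens <- sort(vapply(alleles(p)[[loc]], ampliconLength, integer(1)))
      if (length(lens) == 0L) {
        out <- c(out, sprintf("  %-10s  no product", loc)); next
      }
      bands <- list()
      for (l in lens) {
        if (length(bands) > 0L && l - bands[[length(bands)]][1L] <= resolution)
          bands[[length(bands)]] <- c(bands[[length(bands)]], l)
        else bands[[length(bands) + 1L]] <- l
      }
      lab <- vapply(bands, function(b) sprintf("%.0f bp", mean(b)), character(1))
      out <- c(out, sprintf("  %-10s  %s", loc, paste(lab, collapse = " | ")))
    }
  }
  out
}
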