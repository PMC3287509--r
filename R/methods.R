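#' Accessors for mlvatyper result objects
#'
#' Accessor generics for the S4 result classes: copy numbers and copy
#' strings of period decompositions and alleles, per-locus allele
#' lists of profiles, and the components of an ANK architecture.
#'
#' @param x a [PeriodDecomposition-class], [MlvaAllele-class],
#'   [MlvaProfile-class] or [AnkArchitecture-class] object.
#' @return the corresponding component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("copyNumber", "PeriodDecomposition", function(x) x@copyNumber)
#' @rdname accessors
#' @export
setMethod("copyNumber", "MlvaAllele", function(x) x@copyNumber)
#' @rdname accessors
#' @export
setMethod("copyString", "PeriodDecomposition", function(x) x@copyString)
#' @rdname accessors
#' @export
setMethod("copyString", "MlvaAllele", function(x) x@copyString)
#' @rdname accessors
#' @export
setMethod("locusId", "PeriodDecomposition", function(x) x@locusId)
#' @rdname accessors
#' @export
setMethod("locusId", "MlvaAllele", function(x) x@locusId)
#' @rdname accessors
#' @export
setMethod("periodInstances", "PeriodDecomposition", function(x) x@instances)
#' @rdname accessors
#' @export
setMethod("ampliconLength", "MlvaAllele", function(x) x@ampliconLength)
#' @rdname accessors
#' @export
setMethod("alleles", "MlvaProfile", function(x) x@alleles)
#' @rdname accessors
#' @export
setMethod("qcPassed", "MlvaProfile", function(x) x@qcPassed)
#' @rdname accessors
#' @export
setMethod("ankRepeats", "AnkArchitecture", function(x) x@repeats)
#' @rdname accessors
#' @export
setMethod("tmSegments", "AnkArchitecture", function(x) x@tmSegments)
#' @rdname accessors
#' @export
setMethod("prematureStop", "AnkArchitecture", function(x) x@prematureStop)
#' @rdname accessors
#' @export
setMethod("massKda", "AnkArchitecture", function(x) x@massKda)

setMethod("show", "ScoringParams", function(object) {
  cat(sprintf(
    "ScoringParams: match +%d, mismatch -%d, indel -%d | minScore %d, maxPeriod %d bp, minCopies %.1f, seedK %d\n",
    object@match, object@mismatch, object@indel,
    object@minScore, object@maxPeriod, object@minCopies, object@seedK))
})

setMethod("show", "PeriodDecomposition", function(object) {
  cat(sprintf("PeriodDecomposition of '%s' (period %d bp)\n",
              object@locusId, nchar(object@consensus)))
  if (is.na(object@copyNumber)) {
    cat("  no repeat structure detected\n")
  } else {
    cat(sprintf("  copy number %.1f (%s), %d instance(s), score %g\n",
                object@copyNumber, object@copyString,
                nrow(object@instances), object@score))
    cat(sprintf("  matched region %d-%d within locus\n",
                IRanges::start(object@region), IRanges::end(object@region)))
  }
})

setMethod("show", "MlvaAllele", function(object) {
  cs <- if (is.na(object@copyString)) "size-only" else object@copyString
  cat(sprintf("MlvaAllele %s: %d bp [%s]\n",
              object@locusId, object@ampliconLength, cs))
})

setMethod("show", "MlvaProfile", function(object) {
  cat(sprintf("MlvaProfile '%s' (QC %s)\n", object@strainId,
              if (object@qcPassed) "passed" else "FAILED"))
  for (loc in names(object@alleles)) {
    a <- object@alleles[[loc]]
    if (length(a) == 0L) { cat(sprintf("  %s: no amplification\n", loc)); next }
    lens <- vapply(a, ampliconLength, integer(1))
    flag <- if (object@multipleInfection[[loc]]) "  ** multiple infection" else ""
    cat(sprintf("  %s: %s bp%s\n", loc, paste(lens, collapse = " + "), flag))
  }
})

setMethod("show", "AnkArchitecture", function(object) {
  cat(sprintf("AnkArchitecture '%s': %d ANK unit(s), %d TM segment(s), %.1f kDa\n",
              object@proteinId, nrow(object@repeats),
              length(object@tmSegments), object@massKda))
  if (!is.na(object@prematureStop))
    cat(sprintf("  premature stop at codon %d\n", object@prematureStop))
  if (nrow(object@insertions) > 0L)
    cat(sprintf("  insertion(s): %s\n",
                paste(sprintf("%d bp @ nt %d", object@insertions$length,
                              object@insertions$position), collapse = ", ")))
})
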