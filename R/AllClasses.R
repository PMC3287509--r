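#' Scoring parameters for tandem repeat detection
#'
#' Alignment and reporting parameters of the wraparound
#' dynamic-programming repeat finder.  The defaults are the published
#' parameterization used for endosymbiont genome scans: match +2,
#' mismatch 7, indel 7, minimum reporting score 50, maximum period
#' 500 bp, and a reportable copy-number floor of 1.8.
#'
#' @slot match integer, score added per matching column.
#' @slot mismatch integer, penalty subtracted per mismatching column.
#' @slot indel integer, penalty subtracted per inserted/deleted column.
#' @slot minScore integer, minimum alignment score for a repeat to be
#'   reported.
#' @slot maxPeriod integer, maximum period size (bp) considered.
#' @slot minCopies numeric, minimum copy number for a repeat to be
#'   reported.
#' @slot seedK integer, k-mer length used to seed candidate periods.
#'
#' @seealso [scoringParams()] for the user-facing constructor.
#' @export
setClass("ScoringParams", representation(
  match = "integer", mismatch = "integer", indel = "integer",
  minScore = "integer", maxPeriod = "integer",
  minCopies = "numeric", seedK = "integer"))

setValidity("ScoringParams", function(object) {
  v <- c(object@match, object@mismatch, object@indel,
         object@minScore, object@maxPeriod, object@seedK)
  if (any(is.na(v)) || any(v <= 0))
    return("all scoring parameters must be positive")
  if (object@seedK > 12L) return("seedK must be <= 12")
  if (object@minCopies < 1) return("minCopies must be >= 1")
  TRUE
})

#' Construct scoring parameters
#'
#' @param match,mismatch,indel alignment weights (all positive; the
#'   mismatch and indel values are penalties).
#' @param minScore minimum alignment score to report a repeat.
#' @param maxPeriod maximum period size in bp.
#' @param minCopies minimum copy number of a reportable repeat.
#' @param seedK k-mer length for candidate seeding (1..12).
#' @return a [ScoringParams-class] object.
#' @examples
#' scoringParams()               # published defaults: 2, 7, 7, 50, 500
#' scoringParams(minScore = 30L)
#' @export
scoringParams <- function(match = 2L, mismatch = 7L, indel = 7L,
                          minScore = 50L, maxPeriod = 500L,
                          minCopies = 1.8, seedK = 5L) {
  new("ScoringParams", match = as.integer(match),
      mismatch = as.integer(mismatch), indel = as.integer(indel),
      minScore = as.integer(minScore), maxPeriod = as.integer(maxPeriod),
      minCopies = as.numeric(minCopies), seedK = as.integer(seedK))
}

#' Decomposition of a VNTR locus into period instances
#'
#' Result of aligning a locus against a consensus period with
#' wraparound dynamic programming and cutting the alignment path at
#' consensus coordinate zero.  Each period instance is classified as
#' \code{full} (complete copy), \code{half} (copy carrying an internal
#' deletion at least as long as the half-copy threshold, counted as 0.5
#' copies), or \code{partial} (truncated copy at an array end, counted
#' by its aligned fraction rounded to one decimal).
#'
#' @slot locusId character, identifier of the decomposed sequence.
#' @slot consensus character, the period consensus the locus was
#'   decomposed against.
#' @slot region [IRanges::IRanges] of length 0 or 1: the matched repeat
#'   region within the locus (1-based).
#' @slot instances data.frame with one row per period instance:
#'   \code{start}, \code{end} (1-based within locus), \code{class},
#'   \code{alignedFraction}, \code{identity}, \code{copyContribution},
#'   and a list column \code{deletions} of two-column matrices
#'   (\code{offset} 1-based within consensus, \code{length}).
#' @slot copyNumber numeric, total copy number to one decimal
#'   (\code{NA} when no repeat structure was found).
#' @slot copyString character, structured copy notation such as
#'   \code{"7+0.3"} or \code{"4+2x0.5"}.
#' @slot score numeric, alignment score of the decomposition.
#' @export
setClass("PeriodDecomposition", representation(
  locusId = "character", consensus = "character",
  region = "IRanges", instances = "data.frame",
  copyNumber = "numeric", copyString = "character", score = "numeric"))

setValidity("PeriodDecomposition", function(object) {
  ins <- object@instances
  if (nrow(ins) > 0L) {
    if (is.unsorted(ins$start)) return("instances must be ordered")
    if (any(ins$end[-nrow(ins)] + 1L != ins$start[-1L]))
      return("instance spans must tile the repeat region without gaps")
    if (length(object@region) != 1L)
      return("non-empty decomposition needs a matched region")
    if (ins$start[1L] != IRanges::start(object@region) ||
        ins$end[nrow(ins)] != IRanges::end(object@region))
      return("instances must cover the matched region exactly")
    cn <- sum(ins$copyContribution)
    if (!is.na(object@copyNumber) && abs(cn - object@copyNumber) > 0.051)
      return("copyNumber inconsistent with instance contributions")
  }
  TRUE
})

#' A single MLVA allele at one locus
#'
#' A per-locus allele called from an in-silico PCR amplicon: the
#' amplicon length in bp (the primary typing character, always
#' present) and, when the amplicon interior carries repeat structure,
#' the period copy number and structured copy string from
#' [decomposePeriods()].
#'
#' @slot locusId character.
#' @slot ampliconLength integer, bp, including both primer footprints.
#' @slot copyNumber numeric (NA for size-only alleles).
#' @slot copyString character (NA for size-only alleles).
#' @slot decomposition the underlying [PeriodDecomposition-class], or
#'   \code{NULL} for size-only alleles.
#' @export
setClass("MlvaAllele", representation(
  locusId = "character", ampliconLength = "integer",
  copyNumber = "numeric", copyString = "character",
  decomposition = "ANY"))

setValidity("MlvaAllele", function(object) {
  if (length(object@ampliconLength) != 1L || is.na(object@ampliconLength) ||
      object@ampliconLength < 1L)
    return("ampliconLength must be a positive integer")
  TRUE
})

#' A multi-locus MLVA profile for one strain (or DNA extract)
#'
#' Per-locus lists of alleles (a list, so that co-infecting strains
#' with distinct amplicon sizes are representable), a per-locus
#' multiple-infection flag (more than one distinct amplicon length),
#' and a quality-control flag tied to amplification of the \emph{wsp}
#' QC locus.
#'
#' @slot strainId character.
#' @slot alleles named list (by locus id); each element is a list of
#'   [MlvaAllele-class] objects (possibly empty).
#' @slot multipleInfection named logical, one flag per locus.
#' @slot qcPassed logical, \code{TRUE} when the QC locus amplified.
#' @export
setClass("MlvaProfile", representation(
  strainId = "character", alleles = "list",
  multipleInfection = "logical", qcPassed = "logical"))

setValidity("MlvaProfile", function(object) {
  if (!identical(names(object@alleles), names(object@multipleInfection)))
    return("alleles and multipleInfection must share locus names")
  nlen <- vapply(object@alleles, function(a)
    length(unique(vapply(a, function(x) x@ampliconLength, integer(1)))),
    integer(1))
  if (any((nlen > 1L) != object@multipleInfection))
    return("multipleInfection flag inconsistent with allele lengths")
  TRUE
})

#' ANK repeat-domain architecture of one protein
#'
#' Ordered ankyrin repeat units detected by the packaged profile
#' scanner, predicted transmembrane segments, premature stop position
#' (if any), large insertions detected against a reference ortholog,
#' and protein mass.
#'
#' @slot proteinId character.
#' @slot protein character, the translated protein sequence up to the
#'   first stop.
#' @slot repeats data.frame, one row per ANK unit: \code{index},
#'   \code{aaStart}, \code{aaEnd}, \code{unit}, \code{score}, and
#'   (after [clusterPositions()]) possibly \code{cluster}.
#' @slot tmSegments [IRanges::IRanges] in amino-acid coordinates.
#' @slot prematureStop integer codon position or \code{NA}.
#' @slot insertions data.frame: \code{position} (nt, in the gene),
#'   \code{length} (nt), \code{note}.
#' @slot massKda numeric, average-mass molecular weight in kDa (1 dp).
#' @export
setClass("AnkArchitecture", representation(
  proteinId = "character", protein = "character",
  repeats = "data.frame", tmSegments = "IRanges",
  prematureStop = "integer", insertions = "data.frame",
  massKda = "numeric"))

setValidity("AnkArchitecture", function(object) {
  r <- object@repeats
  if (nrow(r) > 1L) {
    if (is.unsorted(r$aaStart)) return("ANK units must be ordered")
    if (any(r$aaEnd[-nrow(r)] >= r$aaStart[-1L]))
      return("ANK units must be non-overlapping")
  }
  if (nrow(r) > 0L) {
    len <- r$aaEnd - r$aaStart + 1L
    if (any(len < 30L | len > 36L))
      return("ANK unit length must be 30-36 aa")
  }
  TRUE
})
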