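# Deterministic seeded generator of synthetic VNTR loci, ANK genes and
# genomes with ground-truth annotations.  Every structure the analyses
# assume can be planted: tandem arrays with terminal partial and
# internally deleted periods, direct repeats and palindromic hairpins
# inside periods, SNP noise between copies, conserved single-copy
# flanks carrying primer sites, and coding genes built from repeated
# 33-aa ANK units with premature stops, insertion elements and
# transmembrane tails.

# run `expr` under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# most-frequent-codon back-translation table (fixed for reproducibility;
# the codon choice is irrelevant downstream)
.CODON <- c(A = "GCA", R = "CGT", N = "AAT", D = "GAT", C = "TGC",
            Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
            L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCA",
            S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

.back_translate <- function(protein) {
  b <- strsplit(protein, "", fixed = TRUE)[[1L]]
  cod <- .CODON[b]
  if (anyNA(cod)) stop("cannot back-translate residue(s): ",
                       paste(unique(b[is.na(cod)]), collapse = ","))
  paste(cod, collapse = "")
}

# variable positions of the 33-aa ANK unit (the rest are the conserved
# structural core); shared by the generator and documentation
.ANK_VARIABLE <- c(1L, 2L, 3L, 5L, 13L, 14L, 18L, 21L, 22L, 25L, 26L, 33L)

# alphabet sampled at variable positions: solvent-exposed ANK repeat
# positions are polar/charged/small in real domains; keeping the
# synthetic units soluble also keeps hydropathy-based TM prediction
# specific to the planted C-terminal tails
.ANK_SURFACE_AA <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "A",
                     "H", "Y")

#' Generate a synthetic VNTR locus with ground truth
#'
#' Builds \code{flankF + array + flankR} where the array consists of
#' \code{nFull} full periods, \code{nHalf} periods carrying an
#' internal deletion of \code{halfDeletionLen} bp, and a terminal
#' partial period of \code{floor(terminalFraction * periodLen)} bases.
#' Direct-repeat units and a palindromic hairpin can be planted inside
#' the period; primers are the outermost \code{primerLen} bases of the
#' flanks.  Deterministic: the same seed reproduces identical bytes.
#'
#' @param periodLen period length (bp).
#' @param nFull number of complete periods.
#' @param nHalf number of periods with an internal deletion.
#' @param halfDeletionLen internal deletion length (bp; default 25,
#'   must be < periodLen).
#' @param terminalFraction fraction (0..1) of a terminal partial
#'   period appended after the full/half copies.
#' @param snpRate per-base substitution rate applied independently to
#'   each copy after the first (0..0.1).
#' @param flankF,flankR flank lengths (bp).
#' @param plantHairpin \code{NULL} or \code{c(stem =, loop =)}: plant
#'   a palindromic hairpin inside the period.
#' @param plantDirectRepeat \code{NULL} or \code{list(unitLen =,
#'   offsets =)}: plant an exact repeated unit at the given 1-based
#'   period offsets.
#' @param primerLen primer length (bp).
#' @param gc background GC content (default 0.35, AT-rich).
#' @param seed integer RNG seed.
#' @param locusId record id.
#' @return list with \code{seq} (a named \code{DNAStringSet} of length
#'   1) and \code{truth} (period sequence, region, copy number, copy
#'   string, amplicon length, primers, motif positions, seed).
#' @examples
#' sim <- makeVntrLocus(periodLen = 141, nFull = 7, terminalFraction = 0.3,
#'                      flankF = 150, flankR = 150, seed = 1)
#' sim$truth$copyNumber   # 7.3
#' @export
makeVntrLocus <- function(periodLen = 141L, nFull = 4L, nHalf = 0L,
                          halfDeletionLen = 25L, terminalFraction = 0,
                          snpRate = 0, flankF = 150L, flankR = 150L,
                          plantHairpin = NULL, plantDirectRepeat = NULL,
                          primerLen = 20L, gc = 0.35, seed = 1L,
                          locusId = "synthetic_vntr") {
  bad <- character(0)
  if (periodLen < 10L) bad <- c(bad, "periodLen must be >= 10")
  if (nHalf > 0L && halfDeletionLen >= periodLen)
    bad <- c(bad, "halfDeletionLen must be < periodLen")
  if (terminalFraction < 0 || terminalFraction >= 1)
    bad <- c(bad, "terminalFraction must be in [0, 1)")
  if (snpRate < 0 || snpRate > 0.1)
    bad <- c(bad, "snpRate must be in [0, 0.1]")
  if (nFull + nHalf < 1L && terminalFraction == 0)
    bad <- c(bad, "array must contain at least one (partial) copy")
  if (flankF < primerLen || flankR < primerLen)
    bad <- c(bad, "flanks must be at least primerLen")
  if (!is.null(plantHairpin)) {
    if (2 * plantHairpin[["stem"]] + plantHairpin[["loop"]] > periodLen)
      bad <- c(bad, "hairpin does not fit within the period")
  }
  if (!is.null(plantDirectRepeat)) {
    if (max(plantDirectRepeat$offsets) + plantDirectRepeat$unitLen - 1L >
        periodLen)
      bad <- c(bad, "direct repeat does not fit within the period")
  }
  if (length(bad) > 0L)
    stop("invalid VNTR spec: ", paste(bad, collapse = "; "))
  .with_seed(seed, {
    period <- randDna(periodLen, gc)
    motifs <- list()
    if (!is.null(plantDirectRepeat)) {
      u <- plantDirectRepeat$unitLen
      unit <- randDna(u, 0.5)
      while (shannonEntropy(unit) <= 1.0) unit <- randDna(u, 0.5)
      for (off in plantDirectRepeat$offsets) {
        period <- paste0(substr(period, 1L, off - 1L), unit,
                         substr(period, off + u, periodLen))
      }
      motifs$directRepeat <- list(unit = unit,
                                  offsets = plantDirectRepeat$offsets)
    }
    if (!is.null(plantHairpin)) {
      stem <- plantHairpin[["stem"]]; loop <- plantHairpin[["loop"]]
      span <- 2L * stem + loop
      # place the hairpin mid-period, clear of planted direct repeats
      at <- max(1L, (periodLen - span) %/% 2L)
      arm <- randDna(stem, 0.5)
      hp <- paste0(arm, randDna(loop, 0.5), revcomp(arm))
      period <- paste0(substr(period, 1L, at - 1L), hp,
                       substr(period, at + span, periodLen))
      motifs$hairpin <- list(start = at, stem = stem, loop = loop)
    }
    copies <- character(0)
    first <- TRUE
    for (i in seq_len(nFull)) {
      copies <- c(copies, if (first) period else mutateDna(period, snpRate))
      first <- FALSE
    }
    delStart <- (periodLen - halfDeletionLen) %/% 2L + 1L
    for (i in seq_len(nHalf)) {
      cp <- if (first) period else mutateDna(period, snpRate)
      first <- FALSE
      copies <- c(copies, paste0(substr(cp, 1L, delStart - 1L),
                                 substr(cp, delStart + halfDeletionLen,
                                        periodLen)))
    }
    partialLen <- as.integer(floor(terminalFraction * periodLen))
    if (partialLen > 0L)
      copies <- c(copies, substr(period, 1L, partialLen))
    array <- paste(copies, collapse = "")
    fl <- randDna(flankF, gc); fr <- randDna(flankR, gc)
    seqchr <- paste0(fl, array, fr)
    partials <- if (partialLen > 0L) round1(partialLen / periodLen) else
      numeric(0)
    truth <- list(
      locusId = locusId, periodSeq = period, periodLen = periodLen,
      nFull = nFull, nHalf = nHalf, halfDeletionLen = halfDeletionLen,
      delStart = delStart, partialLen = partialLen,
      copyNumber = round(nFull + 0.5 * nHalf + sum(partials), 3),
      copyString = .copy_string(nFull, nHalf, partials),
      regionStart = flankF + 1L, regionEnd = flankF + nchar(array),
      ampliconLength = nchar(seqchr),
      primerF = substr(fl, 1L, primerLen),
      primerR = revcomp(substr(fr, flankR - primerLen + 1L, flankR)),
      motifs = motifs, snpRate = snpRate, seed = seed)
    seqs <- Biostrings::DNAStringSet(setNames(seqchr, locusId))
    list(seq = seqs, truth = truth)
  })
}

#' Generate a synthetic ANK gene with ground truth
#'
#' Builds a CDS of \code{M + ANK units + optional TM tail + stop}.
#' Each unit position gets its own base unit: the profile consensus
#' mutated at the variable positions of the 33-aa repeat (so units at
#' different positions are distinguishable, as in real ANK domains,
#' while the structural core stays conserved).  Base units are a
#' deterministic function of \code{seed} and the unit position, so
#' genes generated with the same seed but different \code{strainId}
#' noise share orthologous units position-by-position.  Duplications,
#' swaps, premature stops and mobile-element-like insertions are
#' planted on request.
#'
#' @param nUnits number of ANK units (1..20).
#' @param duplicateIndices integer vector: after assembling the base
#'   units, insert a copy of each listed unit directly after it.
#' @param swapIndices \code{NULL} or \code{c(i, j)}: swap two units.
#' @param prematureStopCodon \code{NULL} or the 1-based codon at which
#'   a TAA stop is planted.
#' @param insertion \code{NULL} or \code{list(position =, length =)}:
#'   random DNA inserted after the given nt position (>= 4, i.e. not
#'   inside the start codon).
#' @param tmTail append a C-terminal tail encoding two hydrophobic
#'   (transmembrane-like) 23-aa runs.
#' @param strainNoiseRate per-residue substitution rate applied to
#'   every unit (strain-specific divergence).
#' @param strainId used (with \code{seed}) to derive the strain noise
#'   stream.
#' @param seed integer RNG seed defining the base units.
#' @return list with \code{seq} (named \code{DNAStringSet}, the CDS)
#'   and \code{truth} (unit order and peptides, aa starts, events,
#'   expected TM segment count, lengths, seed).
#' @export
makeAnkGene <- function(nUnits = 8L, duplicateIndices = NULL,
                        swapIndices = NULL, prematureStopCodon = NULL,
                        insertion = NULL, tmTail = TRUE,
                        strainNoiseRate = 0, strainId = "strain",
                        seed = 1L) {
  if (nUnits < 1L || nUnits > 20L) stop("nUnits must be in 1..20")
  if (!is.null(insertion) && insertion$position < 4L)
    stop("insertion would disrupt the start codon")
  cons <- ankProfile()$consensus
  aas <- names(.AA_BG)
  baseUnit <- function(pos) {
    # deterministic per (seed, position)
    .with_seed(seed * 1000L + pos, {
      b <- strsplit(cons, "", fixed = TRUE)[[1L]]
      for (v in .ANK_VARIABLE)
        if (stats::runif(1) < 0.9) b[v] <- sample(.ANK_SURFACE_AA, 1L)
      paste(b, collapse = "")
    })
  }
  units <- vapply(seq_len(nUnits), baseUnit, character(1))
  labels <- as.character(seq_len(nUnits))
  if (!is.null(duplicateIndices)) {
    for (di in sort(duplicateIndices, decreasing = TRUE)) {
      units <- append(units, units[di], after = di)
      labels <- append(labels, paste0(labels[di], "d"), after = di)
    }
  }
  if (!is.null(swapIndices)) {
    i <- swapIndices[1L]; j <- swapIndices[2L]
    units[c(i, j)] <- units[c(j, i)]
    labels[c(i, j)] <- labels[c(j, i)]
  }
  if (strainNoiseRate > 0) {
    strainSeed <- seed + sum(utf8ToInt(strainId))
    units <- .with_seed(strainSeed, vapply(units, function(u) {
      b <- strsplit(u, "", fixed = TRUE)[[1L]]
      hit <- which(stats::runif(length(b)) < strainNoiseRate)
      for (h in hit) b[h] <- sample(setdiff(aas, b[h]), 1L)
      paste(b, collapse = "")
    }, character(1), USE.NAMES = FALSE))
  }
  tail_aa <- if (tmTail) {
    hydro <- paste(rep(c("L", "I", "V"), length.out = 23L), collapse = "")
    polar <- paste(rep(c("D", "K", "S", "T", "N", "Q", "E"),
                       length.out = 25L), collapse = "")
    paste0("GSGS", hydro, polar, hydro, "RKH")
  } else ""
  protein <- paste0("M", paste(units, collapse = ""), tail_aa)
  cds <- paste0(.back_translate(protein), "TAA")
  if (!is.null(prematureStopCodon)) {
    k <- prematureStopCodon
    if (k < 2L || k > nchar(cds) %/% 3L) stop("premature stop out of range")
    cds <- paste0(substr(cds, 1L, 3L * (k - 1L)), "TAA",
                  substr(cds, 3L * k + 1L, nchar(cds)))
  }
  insSeq <- NULL
  if (!is.null(insertion)) {
    insSeq <- .with_seed(seed + 7L, randDna(insertion$length, 0.35))
    cds <- paste0(substr(cds, 1L, insertion$position), insSeq,
                  substr(cds, insertion$position + 1L, nchar(cds)))
  }
  id <- sprintf("%s_ank", strainId)
  truth <- list(
    geneId = id, nUnits = length(units), unitLabels = labels,
    units = unname(units), unitAaStarts = 2L + 33L * (seq_along(units) - 1L),
    tmTail = tmTail, expectedTmSegments = if (tmTail) 2L else 0L,
    prematureStopCodon = prematureStopCodon, insertion = insertion,
    insertedSeq = insSeq, cdsLength = nchar(cds), seed = seed,
    strainNoiseRate = strainNoiseRate)
  list(seq = Biostrings::DNAStringSet(setNames(cds, id)), truth = truth)
}

#' Generate a synthetic genome with embedded VNTR loci
#'
#' Embeds the arrays produced by [makeVntrLocus()] (including their
#' conserved flanks) at non-overlapping random positions in a seeded
#' random background of the stated GC content.
#'
#' @param nLoci number of loci (0 allowed: pure background).
#' @param backgroundLen background length (bp).
#' @param specs list of argument lists for [makeVntrLocus()], recycled
#'   to \code{nLoci}; per-locus seeds are derived from \code{seed}.
#' @param seed integer RNG seed.
#' @param gc background GC content.
#' @return list with \code{seq} (named \code{DNAStringSet}),
#'   \code{gff} (a \code{GRanges} of the planted repeat regions with
#'   \code{period_size}, \code{copy_number}, \code{copy_string}) and
#'   \code{loci} (per-locus truth from [makeVntrLocus()], with genome
#'   coordinates \code{genomeStart}/\code{genomeEnd} of the repeat
#'   region added).
#' @export
makeGenome <- function(nLoci, backgroundLen, specs = list(list()),
                       seed = 1L, gc = 0.35) {
  stopifnot(nLoci >= 0L, backgroundLen >= 1L)
  specs <- rep(specs, length.out = max(nLoci, 1L))
  loci <- list()
  if (nLoci > 0L) {
    for (i in seq_len(nLoci)) {
      sp <- specs[[i]]
      sp$seed <- seed * 100L + i
      sp$locusId <- sprintf("locus%d", i)
      loci[[i]] <- do.call(makeVntrLocus, sp)
    }
  }
  .with_seed(seed, {
    bg <- randDna(backgroundLen, gc)
    lens <- vapply(loci, function(l) nchar(as.character(l$seq[[1L]])),
                   integer(1))
    if (sum(lens) > 0.8 * backgroundLen)
      stop("loci do not fit: ", sum(lens), " bp of loci in ",
           backgroundLen, " bp background")
    # non-overlapping insertion points, left to right
    free <- backgroundLen - sum(lens)
    cuts <- if (nLoci > 0L)
      sort(sample.int(free - 1L, nLoci)) else integer(0)
    pieces <- character(0); truthRows <- list()
    prev <- 0L; offset <- 0L
    for (i in seq_len(nLoci)) {
      pieces <- c(pieces, substr(bg, prev + 1L, cuts[i]),
                  as.character(loci[[i]]$seq[[1L]]))
      insertAt <- cuts[i] + offset  # genome position before the locus
      tr <- loci[[i]]$truth
      tr$genomeStart <- insertAt + tr$regionStart
      tr$genomeEnd <- insertAt + tr$regionEnd
      loci[[i]]$truth <- tr
      truthRows[[i]] <- tr
      prev <- cuts[i]; offset <- offset + lens[i]
    }
    pieces <- c(pieces, substr(bg, prev + 1L, backgroundLen))
    genome <- paste(pieces, collapse = "")
    gff <- if (nLoci > 0L) {
      GRanges(seqnames = "synthetic_genome",
              ranges = IRanges::IRanges(
                start = vapply(truthRows, `[[`, integer(1), "genomeStart"),
                end = vapply(truthRows, `[[`, integer(1), "genomeEnd")),
              period_size = as.integer(vapply(truthRows, function(x) as.numeric(x$periodLen), numeric(1))),
              copy_number = vapply(truthRows, `[[`, numeric(1), "copyNumber"),
              copy_string = vapply(truthRows, `[[`, character(1), "copyString"))
    } else GRanges()
    list(seq = Biostrings::DNAStringSet(c(synthetic_genome = genome)),
         gff = gff, loci = lapply(loci, `[[`, "truth"))
  })
}
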