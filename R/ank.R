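# ANK (ankyrin) repeat-domain architecture: translation, repeat-unit
# detection with a packaged position-weight profile, transmembrane
# prediction by hydropathy, protein mass, insertion detection, unit
# alignment and repeat-unit phylogenetics.

.pkg_env <- new.env(parent = emptyenv())

# Kyte-Doolittle hydropathy scale
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

# average amino-acid residue masses (Da) and the mass of water
.AA_MASS <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
              V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
              I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
              K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
              F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.WATER <- 18.0153

# Robinson-Robinson background amino-acid frequencies
.AA_BG <- c(A = 0.0780, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0192,
            Q = 0.0426, E = 0.0629, G = 0.0738, H = 0.0219, I = 0.0514,
            L = 0.0901, K = 0.0574, M = 0.0224, F = 0.0385, P = 0.0520,
            S = 0.0711, T = 0.0584, W = 0.0132, Y = 0.0321, V = 0.0644)

#' Translate a coding sequence
#'
#' Translates a CDS with the bacterial genetic code (ATG and GTG both
#' accepted as methionine starts); codons containing N translate to X.
#' The first in-frame stop codon occurring before 90\% of the CDS
#' length flags a premature stop.
#'
#' @param dna the CDS (character or \code{DNAString}), length >= 3.
#' @param frame reading-frame offset (0, 1 or 2).
#' @return list with \code{protein} (sequence up to the first stop),
#'   \code{stopCodon} (1-based codon index of the first stop, or
#'   \code{NA}), and \code{prematureStop} (the stop codon index when
#'   premature, else \code{NA}).
#' @examples
#' translateCds("ATGAAATAA")  # "MK", stop at codon 3, not premature
#' @export
translateCds <- function(dna, frame = 0L) {
  x <- .as_dna_chr(dna)
  x <- substr(x, frame + 1L, nchar(x))
  if (nchar(x) < 3L) stop("CDS shorter than one codon")
  ncod <- nchar(x) %/% 3L
  x <- substr(x, 1L, 3L * ncod)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(x),
                                           if.fuzzy.codon = "X"))
  if (substr(x, 1L, 3L) %in% c("ATG", "GTG"))
    aa <- paste0("M", substr(aa, 2L, nchar(aa)))
  stops <- gregexpr("*", aa, fixed = TRUE)[[1L]]
  stopCodon <- if (stops[1L] == -1L) NA_integer_ else as.integer(stops[1L])
  protein <- if (is.na(stopCodon)) aa else substr(aa, 1L, stopCodon - 1L)
  premature <- !is.na(stopCodon) && stopCodon < 0.9 * ncod
  list(protein = protein, stopCodon = stopCodon,
       prematureStop = if (premature) stopCodon else NA_integer_)
}

#' Packaged ANK position-weight profile
#'
#' Loads (and caches) the 33-column log-odds profile built from the
#' packaged seed alignment of canonical 33-aa ankyrin repeat units
#' (\code{inst/extdata/ank_seed_units.fasta}; a curated synthetic seed
#' set written from the published ankyrin consensus).  Scores are sums
#' of log2 odds against Robinson-Robinson background frequencies with
#' a small pseudocount.
#'
#' @param thresholdBits detection threshold in bits used as the default
#'   by [findAnkRepeats()]; the packaged calibration constant.
#' @return list with \code{pssm} (20 x 33 log2-odds matrix),
#'   \code{consensus} (33-aa consensus of the profile),
#'   \code{selfScore} (score of the consensus) and \code{threshold}.
#' @export
ankProfile <- function(thresholdBits = 25) {
  key <- sprintf("ank_profile_%g", thresholdBits)
  if (!is.null(.pkg_env[[key]])) return(.pkg_env[[key]])
  path <- system.file("extdata", "ank_seed_units.fasta",
                      package = "mlvatyper", mustWork = TRUE)
  units <- as.character(readFasta(path, moltype = "protein"))
  stopifnot(all(nchar(units) == 33L))
  aas <- names(.AA_BG)
  pssm <- matrix(0, nrow = 20L, ncol = 33L, dimnames = list(aas, NULL))
  mat <- do.call(rbind, strsplit(units, "", fixed = TRUE))
  pseudo <- 2
  for (j in seq_len(33L)) {
    cnt <- table(factor(mat[, j], levels = aas))
    p <- (as.numeric(cnt) + pseudo * .AA_BG) / (nrow(mat) + pseudo)
    pssm[, j] <- log2(p / .AA_BG)
  }
  consensus <- paste(aas[apply(pssm, 2L, which.max)], collapse = "")
  prof <- list(pssm = pssm, consensus = consensus,
               selfScore = .pssm_score(consensus, pssm, 1L),
               threshold = thresholdBits)
  .pkg_env[[key]] <- prof
  prof
}

# score of the length-33 window of `protein` starting at `at`
.pssm_score <- function(protein, pssm, at) {
  w <- strsplit(substr(protein, at, at + 32L), "", fixed = TRUE)[[1L]]
  idx <- match(w, rownames(pssm))
  sum(pssm[cbind(idx[!is.na(idx)], which(!is.na(idx)))])
}

#' Detect ANK repeat units in a protein
#'
#' Scans a protein with the packaged 33-column ANK log-odds profile and
#' selects non-overlapping units greedily from left to right: at the
#' first window reaching the threshold, the best-scoring start within
#' the next few residues is taken and the scan resumes after the unit,
#' so adjacent units may abut.
#'
#' @param protein protein sequence (character or \code{AAString}).
#' @param profile profile from [ankProfile()].
#' @param threshold score threshold in bits; defaults to the profile's
#'   packaged calibration constant.
#' @param slack how far (aa) beyond the first above-threshold window
#'   the unit start may be optimized (default 3).
#' @return data.frame: \code{index}, \code{aaStart}, \code{aaEnd},
#'   \code{unit}, \code{score}.  Proteins shorter than 30 aa give zero
#'   rows.
#' @export
findAnkRepeats <- function(protein, profile = ankProfile(),
                           threshold = NULL, slack = 3L) {
  p <- toupper(.as_aa_chr(protein))
  threshold <- threshold %||% profile$threshold
  n <- nchar(p)
  empty <- data.frame(index = integer(0), aaStart = integer(0),
                      aaEnd = integer(0), unit = character(0),
                      score = numeric(0))
  if (n < 30L) return(empty)
  nw <- n - 32L
  if (nw < 1L) return(empty)
  # window scores via column-wise accumulation
  b <- strsplit(p, "", fixed = TRUE)[[1L]]
  idx <- match(b, rownames(profile$pssm))
  sc <- numeric(nw)
  for (j in seq_len(33L)) {
    v <- idx[j:(j + nw - 1L)]
    contrib <- ifelse(is.na(v), 0, profile$pssm[cbind(v, j)])
    contrib[is.na(contrib)] <- 0
    sc <- sc + contrib
  }
  out <- list(); i <- 1L
  while (i <= nw) {
    if (sc[i] >= threshold) {
      cand <- i:min(i + slack, nw)
      j <- cand[which.max(sc[cand])]
      out[[length(out) + 1L]] <- data.frame(
        index = length(out) + 1L, aaStart = j, aaEnd = j + 32L,
        unit = substr(p, j, j + 32L), score = sc[j])
      i <- j + 33L
    } else i <- i + 1L
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

.as_aa_chr <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  as.character(x)
}

#' Predict transmembrane segments by hydropathy
#'
#' Kyte-Doolittle sliding-window hydropathy: a transmembrane segment
#' is the union of all windows whose mean hydropathy exceeds the
#' cutoff; segments separated by fewer than \code{mergeGap} residues
#' are merged and segments shorter than \code{minLen} are dropped.
#'
#' @param protein protein sequence.
#' @param window odd window width (default 19).
#' @param cutoff mean-hydropathy cutoff (default 1.6).
#' @param mergeGap merge segments closer than this many aa (default 5).
#' @param minLen minimal reported segment length in aa (default 15).
#' @return an \code{IRanges} of segments in aa coordinates.
#' @examples
#' length(predictTm(strrep("L", 30)))  # 1
#' length(predictTm(strrep("D", 30)))  # 0
#' @export
predictTm <- function(protein, window = 19L, cutoff = 1.6,
                      mergeGap = 5L, minLen = 15L) {
  stopifnot(window %% 2L == 1L)
  p <- toupper(.as_aa_chr(protein))
  n <- nchar(p)
  if (n < window) return(IRanges::IRanges())
  h <- .KD[strsplit(p, "", fixed = TRUE)[[1L]]]
  h[is.na(h)] <- 0
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2L))
  centers <- which(!is.na(means) & means > cutoff)
  if (length(centers) == 0L) return(IRanges::IRanges())
  half <- (window - 1L) %/% 2L
  segs <- IRanges::reduce(IRanges::IRanges(pmax(1L, centers - half),
                                           pmin(n, centers + half)))
  segs <- IRanges::reduce(segs, min.gapwidth = mergeGap)
  segs[IRanges::width(segs) >= minLen]
}

#' Protein mass in kDa
#'
#' Molecular weight from average amino-acid residue masses plus one
#' water, reported in kDa to one decimal.  X counts as an average
#' residue.
#'
#' @param protein protein sequence (no stop characters).
#' @return numeric, kDa (1 decimal).
#' @examples
#' proteinMass("GG")  # 2 x 57.0519 + 18.0153 = 132.1 Da = 0.1 kDa
#' @export
proteinMass <- function(protein) {
  p <- toupper(.as_aa_chr(protein))
  if (nchar(p) == 0L) stop("empty protein")
  if (grepl("*", p, fixed = TRUE)) stop("protein contains a stop character")
  b <- strsplit(p, "", fixed = TRUE)[[1L]]
  m <- .AA_MASS[b]
  m[is.na(m)] <- mean(.AA_MASS)  # X / unknown
  round1((sum(m) + .WATER) / 1000)
}

#' Detect large insertions against a reference ortholog
#'
#' Globally aligns a gene to a reference ortholog (match +2, mismatch
#' -7, gap open -7, gap extend -1) and reports every gap in the
#' reference of at least \code{minLen} bp as an insertion, with its
#' position on the reference and exact length.  Mobile-element
#' insertions (IS elements) appear as such blocks.
#'
#' @param gene gene sequence (DNA).
#' @param referenceOrtholog reference ortholog (DNA).
#' @param minLen minimal insertion length reported (default 100).
#' @return data.frame: \code{position} (1-based on the reference, the
#'   base after which the insertion occurs), \code{length},
#'   \code{note}.
#' @export
detectInsertion <- function(gene, referenceOrtholog, minLen = 100L) {
  g <- .as_dna_chr(gene); r <- .as_dna_chr(referenceOrtholog)
  .check_dna(g, "gene"); .check_dna(r, "reference")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -7,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(g), Biostrings::DNAString(r), type = "global",
    substitutionMatrix = mat, gapOpening = 6, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  matches <- sum(pa == sa & pa != "-")
  # unrelated sequences still reach ~2/3 LCS-style matches under cheap
  # gap extension, but only at a strongly negative alignment score
  if (100 * matches / min(nchar(g), nchar(r)) < 50 ||
      Biostrings::score(aln) <= 0)
    stop("not orthologous: alignment identity below 50%")
  gap <- sa == "-"
  out <- list()
  if (any(gap)) {
    runs <- rle(gap)
    endcol <- cumsum(runs$lengths)
    startcol <- endcol - runs$lengths + 1L
    refpos <- cumsum(!gap)  # reference coordinate at each column
    for (k in which(runs$values & runs$lengths >= minLen)) {
      pos <- if (startcol[k] == 1L) 0L else refpos[startcol[k] - 1L]
      out[[length(out) + 1L]] <- data.frame(
        position = pos, length = runs$lengths[k], note = "insertion")
    }
  }
  if (length(out) == 0L)
    return(data.frame(position = integer(0), length = integer(0),
                      note = character(0)))
  do.call(rbind, out)
}

#' Correct single-base frameshifts against a reference ortholog
#'
#' Aligns a gene to an in-frame reference and pads alignment gaps in
#' the gene whose length is not a multiple of three (1-2 nt, the
#' signature of a sequencing or evolutionary frameshift) with N so
#' that downstream translation stays in frame.
#'
#' @param gene gene sequence.
#' @param referenceOrtholog in-frame reference ortholog.
#' @return list: \code{gene} (corrected sequence), \code{corrections}
#'   (data.frame of \code{position}, \code{inserted}).
#' @export
correctFrameshifts <- function(gene, referenceOrtholog) {
  g <- .as_dna_chr(gene); r <- .as_dna_chr(referenceOrtholog)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -7,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(g), Biostrings::DNAString(r), type = "global",
    substitutionMatrix = mat, gapOpening = 6, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  corr <- list()
  runs <- rle(pa == "-")
  endcol <- cumsum(runs$lengths)
  genepos <- cumsum(pa != "-")
  res <- g
  shift <- 0L
  for (k in seq_along(runs$lengths)) {
    if (!runs$values[k]) next
    len <- runs$lengths[k] %% 3L
    if (len == 0L) next
    at <- genepos[endcol[k]] + shift  # insert after this gene base
    res <- paste0(substr(res, 1L, at), strrep("N", len),
                  substr(res, at + 1L, nchar(res)))
    corr[[length(corr) + 1L]] <- data.frame(position = at, inserted = len)
    shift <- shift + len
  }
  list(gene = res,
       corrections = if (length(corr)) do.call(rbind, corr) else
         data.frame(position = integer(0), inserted = integer(0)))
}

#' Multiple alignment of ANK repeat units
#'
#' Center-star progressive alignment of near-equal-length repeat
#' units: the center is the unit with the highest total pairwise
#' alignment score; every other unit is aligned to the center
#' (BLOSUM62, affine gaps) and the pairwise alignments are merged
#' ("once a gap, always a gap").
#'
#' @param units named character vector of units (2 or more; lengths
#'   30-36 aa).
#' @return named character vector of gapped aligned sequences, all of
#'   equal width; degapping restores the inputs.
#' @export
alignRepeatUnits <- function(units) {
  units <- vapply(units, .as_aa_chr, character(1))
  if (length(units) < 2L) stop("need >= 2 units to align")
  if (is.null(names(units)) || anyDuplicated(names(units)))
    stop("units must have unique names")
  if (any(nchar(units) < 30L | nchar(units) > 36L))
    stop("unit lengths must be within 30-36 aa")
  if (length(unique(units)) == 1L) return(units)  # trivial: no gaps
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62 <- get("BLOSUM62", envir = environment())
  aaset <- Biostrings::AAStringSet(units)
  scores <- Biostrings::pairwiseAlignment(
    rep(aaset, each = length(units)), rep(aaset, times = length(units)),
    substitutionMatrix = BLOSUM62, gapOpening = 10, gapExtension = 4,
    scoreOnly = TRUE)
  tot <- rowSums(matrix(scores, nrow = length(units), byrow = TRUE))
  center <- which.max(tot)
  cseq <- units[[center]]
  lc <- nchar(cseq)
  # per-unit anchors (char aligned to each center residue) and inserts
  # (string inserted before each center residue; index lc+1 = after end)
  anchors <- matrix("-", nrow = length(units), ncol = lc)
  inserts <- matrix("", nrow = length(units), ncol = lc + 1L)
  for (u in seq_along(units)) {
    if (u == center) {
      anchors[u, ] <- strsplit(cseq, "")[[1L]]
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(units[[u]]), Biostrings::AAString(cseq),
      substitutionMatrix = BLOSUM62, gapOpening = 10, gapExtension = 4,
      type = "global")
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    r <- 1L
    for (col in seq_along(sa)) {
      if (sa[col] == "-") {
        inserts[u, r] <- paste0(inserts[u, r], pa[col])
      } else {
        anchors[u, r] <- pa[col]
        r <- r + 1L
      }
    }
  }
  W <- apply(inserts, 2L, function(x) max(nchar(x)))
  pad <- function(x, w) paste0(x, strrep("-", w - nchar(x)))
  out <- vapply(seq_along(units), function(u) {
    parts <- character(0)
    for (r in seq_len(lc))
      parts <- c(parts, pad(inserts[u, r], W[r]), anchors[u, r])
    paste(c(parts, pad(inserts[u, lc + 1L], W[lc + 1L])), collapse = "")
  }, character(1))
  names(out) <- names(units)
  out
}

#' Pairwise p-distances over aligned units
#'
#' Proportion of differing residues among columns where both sequences
#' are ungapped.
#'
#' @param aligned named character vector from [alignRepeatUnits()].
#' @return symmetric numeric matrix.
#' @export
pDistance <- function(aligned) {
  m <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ok <- m[i, ] != "-" & m[j, ] != "-"
    d[i, j] <- d[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 1
  }
  d
}

#' Neighbor-joining tree of ANK repeat units
#'
#' Aligns the units (unless already aligned), computes p-distances and
#' builds a neighbor-joining tree.  Deterministic for a given input
#' order: ties in the NJ selection criterion are broken towards the
#' earliest pair in input order.  All-identical units yield a star
#' tree with zero branch lengths.
#'
#' @param units named character vector of units (>= 3), or an already
#'   aligned set (\code{aligned = TRUE}).
#' @param aligned set to \code{TRUE} when \code{units} are already
#'   gapped alignment rows.
#' @param bootstrap number of bootstrap replicates (resampling
#'   alignment columns); when > 0, per-node support counts are
#'   attached as \code{node.label}.
#' @return an [ape::phylo] tree; serialize with [ape::write.tree()].
#' @export
repeatUnitTree <- function(units, aligned = FALSE, bootstrap = 0L) {
  if (length(units) < 3L) stop("need >= 3 units for a tree")
  al <- if (aligned) units else alignRepeatUnits(units)
  tree <- njTree(pDistance(al))
  if (bootstrap > 0L) {
    m <- do.call(rbind, strsplit(al, "", fixed = TRUE))
    reps <- lapply(seq_len(bootstrap), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      alb <- setNames(apply(m[, cols, drop = FALSE], 1L, paste,
                            collapse = ""), names(al))
      njTree(pDistance(alb))
    })
    supp <- ape::prop.clades(tree, reps, rooted = FALSE)
    supp[is.na(supp)] <- 0L
    tree$node.label <- supp
  }
  tree
}

#' Position clusters and repeat-unit events across orthologs
#'
#' Clusters repeat units by single-linkage at an identity threshold
#' and reports, per cluster, the ordered unit indices each strain
#' contributes, plus two event classes: \emph{duplication} (one strain
#' contributes two or more adjacent indices to the same cluster,
#' i.e. a lineage-specific tandem duplication) and \emph{shuffling}
#' (two strains' shared clusters occur in a different relative order).
#'
#' @param units character vector of repeat units (aa).
#' @param strain character vector, strain of each unit.
#' @param index integer vector, 1-based position of each unit along
#'   its protein.
#' @param identityThreshold single-linkage identity threshold in
#'   \code{[0,1]}; units join a cluster when p-distance <=
#'   \code{1 - identityThreshold}.
#' @return list with \code{clusters} (data.frame: strain, index,
#'   cluster), \code{duplications} (strain, cluster, indices) and
#'   \code{shufflings} (strainA, strainB, clusterA, clusterB).
#' @export
clusterPositions <- function(units, strain, index,
                             identityThreshold = 0.8) {
  stopifnot(length(units) == length(strain),
            length(units) == length(index))
  labels <- sprintf("%s_%d", strain, index)
  names(units) <- labels
  al <- alignRepeatUnits(units)
  d <- pDistance(al)
  hc <- hclust(as.dist(d), method = "single")
  cl <- cutree(hc, h = 1 - identityThreshold)
  df <- data.frame(strain = strain, index = index, cluster = unname(cl))
  df <- df[order(df$strain, df$index), , drop = FALSE]
  # duplications
  dup <- list()
  for (c0 in unique(df$cluster)) for (s in unique(df$strain)) {
    ii <- sort(df$index[df$cluster == c0 & df$strain == s])
    if (length(ii) >= 2L && any(diff(ii) == 1L))
      dup[[length(dup) + 1L]] <- data.frame(
        strain = s, cluster = c0, indices = paste(ii, collapse = ","))
  }
  # shuffling: order inversions of shared clusters between strain pairs
  shuf <- list()
  strains <- unique(df$strain)
  firstIdx <- function(s) {
    sub <- df[df$strain == s, , drop = FALSE]
    tapply(sub$index, sub$cluster, min)
  }
  fi <- lapply(setNames(strains, strains), firstIdx)
  if (length(strains) >= 2L) {
    for (a in seq_along(strains)) for (b in seq_along(strains)) {
      if (b <= a) next
      sa <- strains[a]; sb <- strains[b]
      shared <- intersect(names(fi[[sa]]), names(fi[[sb]]))
      if (length(shared) < 2L) next
      for (x in seq_along(shared)) for (y in seq_along(shared)) {
        if (y <= x) next
        cx <- shared[x]; cy <- shared[y]
        da <- fi[[sa]][cx] - fi[[sa]][cy]
        db <- fi[[sb]][cx] - fi[[sb]][cy]
        if (sign(da) != 0 && sign(db) != 0 && sign(da) != sign(db))
          shuf[[length(shuf) + 1L]] <- data.frame(
            strainA = sa, strainB = sb,
            clusterA = as.integer(cx), clusterB = as.integer(cy))
      }
    }
  }
  list(clusters = df,
       duplications = if (length(dup)) do.call(rbind, dup) else
         data.frame(strain = character(0), cluster = integer(0),
                    indices = character(0)),
       shufflings = if (length(shuf)) do.call(rbind, shuf) else
         data.frame(strainA = character(0), strainB = character(0),
                    clusterA = integer(0), clusterB = integer(0)))
}

#' Assemble the full ANK architecture of a gene
#'
#' Translation, ANK unit detection, transmembrane prediction, mass,
#' and (with a reference ortholog) large-insertion detection, bundled
#' into one [AnkArchitecture-class] object.  The mass and all
#' protein-level features are computed from the translation up to the
#' first stop, so a premature stop ablates downstream units and
#' transmembrane segments.
#'
#' @param cds the gene CDS (DNA).
#' @param proteinId identifier.
#' @param reference optional reference ortholog CDS for insertion
#'   detection.
#' @param profile ANK profile, see [ankProfile()].
#' @param ... passed to [findAnkRepeats()].
#' @return an [AnkArchitecture-class].
#' @export
ankArchitecture <- function(cds, proteinId = "gene", reference = NULL,
                            profile = ankProfile(), ...) {
  tr <- translateCds(cds)
  reps <- findAnkRepeats(tr$protein, profile = profile, ...)
  tm <- predictTm(tr$protein)
  ins <- if (is.null(reference)) {
    data.frame(position = integer(0), length = integer(0),
               note = character(0))
  } else detectInsertion(cds, reference)
  mass <- if (nchar(tr$protein) > 0L) proteinMass(tr$protein) else 0
  new("AnkArchitecture", proteinId = proteinId, protein = tr$protein,
      repeats = reps, tmSegments = tm,
      prematureStop = tr$prematureStop, insertions = ins,
      massKda = mass)
}
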