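# Independent oracles used across the suite.  These deliberately avoid
# the package's wraparound DP and motif scanners: the tandem oracle
# goes through Biostrings local alignment against an explicitly
# repeated consensus, and the motif oracles are literal triple-loop
# enumerations of the definitions.

rand_dna <- function(n, gc = 0.35) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# best tandem-repeat alignment over all periods <= maxq and all phase
# choices, scored 2 / -7 / -7 by local alignment of the full string
# against an explicit linear concatenation of the candidate consensus
oracle_best_repeat <- function(seq, maxq = 10L, minCopies = 1.8) {
  n <- nchar(seq)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -7,
                                                     baseOnly = TRUE)
  best <- list(score = -Inf)
  for (q in seq_len(min(maxq, n - 1L))) {
    reps <- ceiling(n / q) + 2L
    for (s in 0:(n - q)) {
      cons <- substr(seq, s + 1L, s + q)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seq),
        Biostrings::DNAString(strrep(cons, reps)),
        type = "local", substitutionMatrix = submat,
        gapOpening = 0, gapExtension = 7)
      sc <- Biostrings::score(aln)
      copies <- Biostrings::nchar(Biostrings::subject(aln)) / q
      if (copies < minCopies) next
      if (sc > best$score) {
        pr <- aln@pattern@range
        best <- list(score = sc, period = q,
                     start = BiocGenerics::start(pr),
                     end = BiocGenerics::end(pr))
      }
    }
  }
  best
}

# literal enumeration of maximal exact direct repeats (unit length in
# [minu, maxu], >= minocc greedy non-overlapping occurrences, entropy
# filter, no one-base extension as frequent)
oracle_direct_repeats <- function(seq, minu, maxu, minocc = 2L,
                                  minEntropy = 1.0) {
  n <- nchar(seq)
  greedy_occ <- function(unit) {
    u <- nchar(unit); pos <- integer(0); i <- 1L
    while (i + u - 1L <= n) {
      if (substr(seq, i, i + u - 1L) == unit) { pos <- c(pos, i); i <- i + u }
      else i <- i + 1L
    }
    pos
  }
  found <- list()
  for (u in minu:min(maxu, n %/% minocc)) {
    if (u > n) break
    for (i in 1:(n - u + 1L)) {
      unit <- substr(seq, i, i + u - 1L)
      if (unit %in% names(found)) next
      pos <- greedy_occ(unit)
      if (length(pos) < minocc) next
      if (mlvatyper::shannonEntropy(unit) <= minEntropy) next
      exts <- character(0)
      for (p0 in pos) {
        if (p0 > 1L)
          exts <- c(exts, substr(seq, p0 - 1L, p0 + u - 1L))
        if (p0 + u <= n)
          exts <- c(exts, substr(seq, p0, p0 + u))
      }
      exts <- unique(exts[nchar(exts) == u + 1L])
      if (any(vapply(exts, function(e) length(greedy_occ(e)) >= length(pos),
                     logical(1)))) next
      found[[unit]] <- list(unit = unit, unitLength = u, positions = pos)
    }
  }
  found
}

# literal cubic enumeration of maximal dyads
oracle_dyads <- function(seq, minStem, maxLoop, maxMismatch = 0L) {
  n <- nchar(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mism <- function(i, j, stem) {
    s <- 0L
    for (k in seq_len(stem)) {
      x <- b[i + k - 1L]; y <- b[j + stem - k]
      if (is.na(comp[x]) || comp[x] != y) s <- s + 1L
    }
    s
  }
  out <- list()
  for (i in seq_len(n)) for (loop in 0:maxLoop) for (stem in minStem:n) {
    j <- i + stem + loop
    if (j + stem - 1L > n) break
    if (mism(i, j, stem) > maxMismatch) next
    extOut <- i > 1L && j + stem <= n && mism(i - 1L, j, stem + 1L) <= maxMismatch
    extIn <- loop >= 2L && mism(i, j - 1L, stem + 1L) <= maxMismatch
    if (extOut || extIn) next
    out[[length(out) + 1L]] <- c(start = i, end = j + stem - 1L,
                                 stemLen = stem, loopLen = loop)
  }
  if (length(out) == 0L) return(NULL)
  unique(do.call(rbind, out))
}

# naive sliding-window primer site scan
oracle_primer_sites <- function(template, primer, maxMismatch) {
  n <- nchar(template); m <- nchar(primer)
  hits <- function(p) {
    pos <- integer(0)
    pb <- strsplit(p, "")[[1]]
    tb <- strsplit(template, "")[[1]]
    for (i in seq_len(n - m + 1L)) {
      if (sum(tb[i:(i + m - 1L)] != pb) <= maxMismatch) pos <- c(pos, i)
    }
    pos
  }
  list(fwd = hits(primer), rev = hits(mlvatyper::revcomp(primer)))
}
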