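# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shannon entropy of base composition
#'
#' Entropy in bits (0..2 for DNA) of the mononucleotide composition of a
#' sequence; used to suppress homopolymer / low-complexity motifs.
#'
#' @param x character scalar, DNA sequence.
#' @return numeric scalar, bits.
#' @examples
#' shannonEntropy("ACGTACGT")  # 2 bits
#' shannonEntropy("AAAAAAAA")  # 0 bits
#' @export
shannonEntropy <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  b <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  b <- b[b %in% c("A", "C", "G", "T")]
  if (length(b) == 0L) return(0)
  p <- table(b) / length(b)
  -sum(p * log2(p))
}

# round to 1 decimal; R's round() implements the round-half-even
# convention used throughout for copy numbers
round1 <- function(x) round(x, 1L)

# uppercase character sequence from DNAString / character
.as_dna_chr <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  toupper(as.character(x))
}

.check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop(what, " contains non-DNA characters (A/C/G/T/N expected)")
  invisible(x)
}

# seeded uniform random DNA with given GC content
randDna <- function(n, gc = 0.35) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# apply substitution noise to a DNA string at a given per-base rate
mutateDna <- function(x, rate) {
  if (rate <= 0) return(x)
  b <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  for (i in hit) {
    b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  }
  paste(b, collapse = "")
}
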