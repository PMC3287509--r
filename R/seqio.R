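#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] /
#' [Biostrings::readAAStringSet()] that enforces the conventions the
#' rest of the toolkit assumes: sequences are uppercased, ids are taken
#' as the first whitespace-delimited token of each header, empty files
#' and duplicated ids are errors.
#'
#' @param path path to a FASTA file.
#' @param moltype \code{"dna"} (default) or \code{"protein"}.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- if (moltype == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  names(set) <- ids
  if (moltype == "dna") {
    Biostrings::DNAStringSet(toupper(as.character(set)))
  } else {
    Biostrings::AAStringSet(toupper(as.character(set)))
  }
}

#' Write repeat annotations to GFF3
#'
#' Writes a [GenomicRanges::GRanges] of repeat features to GFF3 with
#' 1-based inclusive coordinates (the GFF3 convention).  Metadata
#' columns (e.g. \code{period_size}, \code{copy_number}, \code{score})
#' are carried into column 9 attributes; a \code{score} column is also
#' placed in GFF column 6.
#'
#' @param gr a \code{GRanges}, e.g. from [findTandemRepeats()].  An
#'   empty \code{GRanges} yields a header-only file.
#' @param path output path.
#' @param source,type GFF3 source and type columns.
#' @return invisibly, \code{path}.
#' @seealso [readGff3()] for the inverse.
#' @export
writeGff3 <- function(gr, path, source = "mlvatyper", type = "tandem_repeat") {
  stopifnot(is(gr, "GRanges"))
  if (length(gr) > 0L && any(GenomicRanges::start(gr) < 1L))
    stop("negative or zero coordinate in GFF3 output")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(gr) == 0L) return(invisible(path))
  m <- GenomicRanges::mcols(gr)
  score <- if ("score" %in% colnames(m)) m$score else rep(".", length(gr))
  attrcols <- setdiff(colnames(m), character(0))
  attrs <- vapply(seq_along(gr), function(i) {
    if (length(attrcols) == 0L) return(sprintf("ID=feature%d", i))
    kv <- vapply(attrcols, function(cn) {
      v <- m[[cn]][i]
      sprintf("%s=%s", cn, as.character(v))
    }, character(1))
    paste(c(sprintf("ID=feature%d", i), kv), collapse = ";")
  }, character(1))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                   as.character(GenomicRanges::seqnames(gr)), source, type,
                   GenomicRanges::start(gr), GenomicRanges::end(gr),
                   as.character(score), strand, attrs)
  writeLines(lines, con)
  invisible(path)
}

#' Read a GFF3 annotation file
#'
#' Reads GFF3 (via [rtracklayer::import()]) into a \code{GRanges};
#' inverse of [writeGff3()] up to attribute types.
#'
#' @param path path to a GFF3 file.
#' @return a \code{GRanges}.
#' @export
readGff3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

#' Reverse complement of a DNA sequence
#'
#' Character-in/character-out reverse complement (an involution),
#' delegating to [Biostrings::reverseComplement()].  Protein input is
#' rejected.
#'
#' @param dna character scalar (or \code{DNAString}); IUPAC ambiguity
#'   codes are allowed.
#' @return character scalar.
#' @examples
#' revcomp("AAAC")  # "GTTT"
#' revcomp("ACGT")  # its own reverse complement
#' @export
revcomp <- function(dna) {
  x <- .as_dna_chr(dna)
  if (grepl("[EFILPQZJOX*]", x))
    stop("revcomp() expects DNA, got protein-like residues")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
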