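# Neighbor-joining (Saitou & Nei, as modified by Studier & Keppler)
# on a distance matrix.  Implemented here so the tree construction is
# part of the package surface; ape serves as plumbing for the phylo
# container and newick serialization (and as an independent
# cross-check in the test suite).

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining: iteratively joins the pair minimizing
#' the Q criterion, with ties broken deterministically towards the
#' earliest pair in input (label) order.  Negative branch lengths are
#' clamped to zero.  For additive distance matrices the true tree is
#' recovered.
#'
#' @param d symmetric numeric matrix with labelled rows/columns (or a
#'   \code{dist}).
#' @return an [ape::phylo] tree (unrooted for >= 3 leaves).
#' @examples
#' d <- matrix(c(0, 2, 4, 4, 2, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' njTree(d)
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2L)
  labels <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  fmt <- function(x) sprintf("%.10g", max(0, x))
  node <- labels  # newick fragment per active node
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # earliest pair in current node order among minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    newlab <- sprintf("(%s:%s,%s:%s)", node[i], fmt(bi), node[j], fmt(bj))
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    node <- c(node[keep], newlab)
    D <- D2
  }
  nwk <- if (nrow(D) == 2L) {
    sprintf("(%s:%s,%s:%s);", node[1], fmt(D[1, 2] / 2),
            node[2], fmt(D[1, 2] / 2))
  } else {
    ba <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    bb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    bc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    sprintf("(%s:%s,%s:%s,%s:%s);", node[1], fmt(ba), node[2], fmt(bb),
            node[3], fmt(bc))
  }
  ape::read.tree(text = nwk)
}
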