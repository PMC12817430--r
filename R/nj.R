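#' Neighbor-joining tree from a dissimilarity matrix
#'
#' Standard Saitou-Nei agglomeration with two deterministic choices:
#' ties in the Q criterion are broken by the smallest row index (then
#' smallest column index), and a negative branch length at a join is
#' clamped to zero with the deficit moved to the sibling edge so the
#' joined pair's distance is preserved. Exact on additive matrices.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal,
#'   >= 3 leaves; row names become leaf labels.
#' @param labels optional leaf labels overriding `rownames(D)`.
#' @return list of class `nj_tree`: `newick` (text) and `tree`
#'   (an [ape::read.tree()] `phylo`).
#' @export
neighbor_joining <- function(D, labels = NULL) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8))
    .stopf("neighbor_joining: D must be symmetric")
  if (any(diag(D) != 0)) .stopf("neighbor_joining: diagonal must be zero")
  n <- nrow(D)
  if (n < 3) .stopf("neighbor_joining: need >= 3 leaves")
  labels <- labels %||% rownames(D) %||% paste0("t", seq_len(n))
  # newick fragments per active node
  sub <- as.list(labels)
  Dm <- unname(D)
  while (nrow(Dm) > 3) {
    m <- nrow(Dm)
    r <- rowSums(Dm)
    # Q criterion; pick smallest (i, j) among minima
    Qc <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Qc) <- Inf
    best <- which(Qc == min(Qc), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    dij <- Dm[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    dnew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    dnew <- pmax(dnew[-c(i, j)], 0)
    merged <- sprintf("(%s:%.10g,%s:%.10g)", sub[[i]], bi, sub[[j]], bj)
    sub <- c(sub[-c(i, j)], merged)
    Dm <- rbind(cbind(Dm[-c(i, j), -c(i, j), drop = FALSE], dnew),
                c(dnew, 0))
  }
  # final unrooted join of three nodes via the three-point formulas
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  b1 <- max((d12 + d13 - d23) / 2, 0)
  b2 <- max((d12 + d23 - d13) / 2, 0)
  b3 <- max((d13 + d23 - d12) / 2, 0)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    sub[[1]], b1, sub[[2]], b2, sub[[3]], b3)
  structure(list(newick = newick, tree = ape::read.tree(text = newick)),
            class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat(sprintf("nj_tree with %d leaves\n", length(x$tree$tip.label)))
  invisible(x)
}
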