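#' Per-individual observed heterozygosity
#'
#' `H_o` is the proportion of heterozygous calls (dosage 1) among an
#' individual's non-missing genotypes. Individuals with no non-missing
#' genotype get `NA`.
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @return named numeric vector of `H_o`.
#' @export
observed_heterozygosity <- function(G) {
  d <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  n_called <- rowSums(!is.na(d))
  h <- rowSums(d == 1L, na.rm = TRUE) / n_called
  h[n_called == 0] <- NA_real_
  h
}

#' Group (ESU) allele frequencies
#'
#' Alternate-allele frequency and non-missing allele-copy count per
#' site, per group. Estimating frequencies within groups rather than
#' across the whole data set avoids bias from strong between-group
#' divergence.
#'
#' @param G a [genotype_matrix()].
#' @param groups character vector mapping each individual to a group
#'   (aligned with rows, or named by individual id).
#' @return list of class `group_frequencies`: per group a list with
#'   `p` (frequency, `NaN` where no copies observed) and `n` (allele
#'   copies).
#' @export
group_allele_freqs <- function(G, groups) {
  d <- G$dosages
  groups <- .align_labels(groups, G$individual_ids, "groups")
  out <- lapply(split(seq_len(nrow(d)), groups), function(idx) {
    dd <- d[idx, , drop = FALSE]
    n <- 2L * colSums(!is.na(dd))
    p <- colSums(dd, na.rm = TRUE) / n
    list(p = p, n = n)
  })
  structure(out, class = "group_frequencies")
}

.align_labels <- function(labels, ids, what) {
  if (!is.null(names(labels))) {
    miss <- setdiff(ids, names(labels))
    if (length(miss)) .stopf("%s: no mapping for individual %s", what, miss[1])
    labels <- labels[ids]
  }
  if (length(labels) != length(ids))
    .stopf("%s must map every individual", what)
  as.character(labels)
}

#' Per-individual inbreeding coefficient F = (O - E) / (N - E)
#'
#' `O` is the observed number of homozygous sites, `N` the number of
#' sites used, and `E` the expected homozygous count under
#' Hardy-Weinberg given group allele frequencies, with the per-site
#' small-sample correction `E_site = 1 - 2 p (1 - p) n / (n - 1)`
#' (`n` = allele copies observed in the group at the site). Sites
#' monomorphic within the group contribute 1 to `E` and are retained
#' unless `drop_monomorphic = TRUE`. Frequencies are taken within each
#' individual's own group to avoid confounding by population structure.
#'
#' @param G a [genotype_matrix()].
#' @param groups individual-to-group map (see [group_allele_freqs()]).
#' @param freqs optional precomputed [group_allele_freqs()]; computed
#'   from `G` and `groups` when absent.
#' @param drop_monomorphic drop sites with within-group frequency 0
#'   or 1.
#' @return data.frame: `individual_id`, `group`, `N`, `O`, `E`, `H_o`,
#'   `F` (`NA` where undefined, e.g. `N == E`).
#' @export
inbreeding_F <- function(G, groups, freqs = NULL, drop_monomorphic = FALSE) {
  groups <- .align_labels(groups, G$individual_ids, "groups")
  if (is.null(freqs)) freqs <- group_allele_freqs(G, groups)
  d <- G$dosages
  out <- data.frame(individual_id = G$individual_ids, group = groups,
                    N = NA_integer_, O = NA_integer_, E = NA_real_,
                    H_o = NA_real_, F = NA_real_)
  for (i in seq_len(nrow(d))) {
    fr <- freqs[[groups[i]]]
    if (is.null(fr)) .stopf("no frequencies for group %s", groups[i])
    ok <- !is.na(d[i, ]) & fr$n >= 2 & is.finite(fr$p)
    if (drop_monomorphic) ok <- ok & fr$p > 0 & fr$p < 1
    p <- fr$p[ok]; n <- fr$n[ok]; g <- d[i, ok]
    N <- length(g)
    O <- sum(g != 1L)
    E <- sum(1 - 2 * p * (1 - p) * n / (n - 1))
    f <- if (N == 0 || abs(N - E) < 1e-12) NA_real_ else (O - E) / (N - E)
    out$N[i] <- N; out$O[i] <- O; out$E[i] <- E
    out$H_o[i] <- if (N > 0) 1 - O / N else NA_real_
    out$F[i] <- f
  }
  out
}

# per-group per-locus summaries used by both F_ST estimators
.fst_group_stats <- function(d, idx) {
  dd <- d[idx, , drop = FALSE]
  n <- colSums(!is.na(dd))                 # diploid individuals called
  p <- colSums(dd, na.rm = TRUE) / (2 * n)
  h <- colSums(dd == 1L, na.rm = TRUE) / n # observed het proportion
  list(n = n, p = p, h = h)
}

# Weir & Cockerham 1984 variance components for two groups, vectorised
# over loci; returns per-locus a and a+b+c
.wc_pair <- function(s1, s2) {
  n1 <- s1$n; n2 <- s2$n
  ok <- n1 >= 2 & n2 >= 2
  p1 <- s1$p; p2 <- s2$p; h1 <- s1$h; h2 <- s2$h
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- 0; b[!ok] <- 0; cc[!ok] <- 0
  list(num = a, den = a + b + cc)
}

# Hudson estimator (ratio of averages, allele-count corrected)
.hudson_pair <- function(s1, s2) {
  m1 <- 2 * s1$n; m2 <- 2 * s2$n          # allele copies
  ok <- m1 >= 2 & m2 >= 2
  p1 <- s1$p; p2 <- s2$p
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!ok] <- 0; den[!ok] <- 0
  list(num = num, den = den)
}

#' Pairwise multi-locus F_ST between groups
#'
#' Ratio-of-averages (sum of per-locus numerator components over sum of
#' denominator components) for either the Weir-Cockerham 1984 variance
#' components (default; the field standard) or the Hudson estimator.
#' Callers following the admixture workflow should pass only
#' non-admixed individuals (maximum off-ESU ancestry below the
#' admixture threshold).
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @param pop_labels group label per individual (aligned or named).
#' @param estimator `"weir_cockerham"` or `"hudson"`.
#' @return symmetric matrix of F_ST with zero diagonal.
#' @export
pairwise_fst <- function(G, pop_labels,
                         estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  d <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  pop_labels <- .align_labels(pop_labels, ids, "pop_labels")
  gs <- split(seq_len(nrow(d)), pop_labels)
  small <- names(gs)[lengths(gs) < 2]
  if (length(small))
    .stopf("group %s has fewer than 2 individuals", small[1])
  stats_by_group <- lapply(gs, function(idx) .fst_group_stats(d, idx))
  gnames <- names(gs)
  k <- length(gnames)
  out <- matrix(0, k, k, dimnames = list(gnames, gnames))
  pairfun <- if (estimator == "weir_cockerham") .wc_pair else .hudson_pair
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    comp <- pairfun(stats_by_group[[i]], stats_by_group[[j]])
    num <- sum(comp$num[is.finite(comp$num)])
    den <- sum(comp$den[is.finite(comp$den)])
    out[i, j] <- out[j, i] <- if (den > 0) num / den else NA_real_
  }
  out
}

#' Identity-by-state dissimilarity between individuals
#'
#' `d(i, j)` is the mean over shared (both non-missing) loci of
#' `|g_i - g_j| / 2`; 0 for identical genotypes, 1 for individuals
#' fixed for opposite alleles everywhere. Pairs sharing fewer than
#' `min_overlap` loci get `NA` with a warning.
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @param min_overlap minimum shared non-missing loci (default 50).
#' @return symmetric individuals x individuals matrix, zero diagonal.
#' @export
ibs_dissimilarity <- function(G, min_overlap = 50) {
  d <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  M <- (!is.na(d)) * 1
  A <- list(`0` = (d == 0L), `1` = (d == 1L), `2` = (d == 2L))
  A <- lapply(A, function(x) { x[is.na(x)] <- FALSE; x * 1 })
  # sum |gi - gj| over shared loci via dosage-class cross products
  S <- (A[["0"]] %*% t(A[["1"]])) + (A[["1"]] %*% t(A[["0"]])) +
       (A[["1"]] %*% t(A[["2"]])) + (A[["2"]] %*% t(A[["1"]])) +
       2 * ((A[["0"]] %*% t(A[["2"]])) + (A[["2"]] %*% t(A[["0"]])))
  overlap <- M %*% t(M)
  D <- S / (2 * overlap)
  low <- overlap < min_overlap
  if (any(low[upper.tri(low)])) {
    .warnf("ibs_dissimilarity: %d pair(s) below min_overlap = %d set to NA",
           sum(low[upper.tri(low)]), min_overlap)
    D[low] <- NA_real_
  }
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  D
}
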