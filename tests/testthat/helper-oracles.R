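# Independent brute-force oracles and small fixture builders shared by
# the test files. Oracles are deliberately written as plain scalar
# loops, independent of the vectorised implementation paths they check.

# genotype matrix with explicit positions on one or more scaffolds
toy_genotypes <- function(dosages, pos = NULL, chrom = NULL, ids = NULL,
                          ann = NULL, depth = NULL) {
  dosages <- as.matrix(dosages)
  j <- ncol(dosages)
  pos <- pos %||% (seq_len(j) * 10000L)
  chrom <- chrom %||% rep("scaffold_1", j)
  genotype_matrix(dosages, ids %||% paste0("ind", seq_len(nrow(dosages))),
                  data.frame(chrom = chrom, pos = pos,
                             ref = rep("A", j), alt = rep("T", j)),
                  site_annotations = ann, depth = depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive per-site transcription of the filter cascade
oracle_site_filters <- function(G, cfg) {
  d <- G$dosages; dep <- G$depth; ann <- G$site_annotations
  if (!is.null(dep)) d[!is.na(d) & (is.na(dep) | dep < cfg$min_genotype_depth)] <- NA
  keep <- rep(TRUE, ncol(d))
  for (s in seq_len(ncol(d))) {
    g <- d[, s]
    ac <- sum(g, na.rm = TRUE); an <- 2 * sum(!is.na(g))
    if (min(ac, an - ac) < cfg$min_minor_allele_count) { keep[s] <- FALSE; next }
    if (!is.null(dep)) {
      ds <- dep[, s]; ds[is.na(g)] <- NA
      if (mean(ds, na.rm = TRUE) < cfg$min_mean_site_depth) { keep[s] <- FALSE; next }
    }
    if (ann$AB[s] <= cfg$het_allele_balance[1] ||
        ann$AB[s] >= cfg$het_allele_balance[2]) { keep[s] <- FALSE; next }
    inside <- ann$ABHOM[s] >= cfg$hom_allele_balance[1] &&
      ann$ABHOM[s] <= cfg$hom_allele_balance[2]
    if (if (cfg$hom_ab_keep_outside) inside else !inside) { keep[s] <- FALSE; next }
    if (ann$MQR[s] <= cfg$mapq_ratio[1] ||
        ann$MQR[s] >= cfg$mapq_ratio[2]) { keep[s] <- FALSE; next }
    if (ann$QD[s] <= cfg$min_quality_per_depth) { keep[s] <- FALSE; next }
    if (!is.null(dep)) {
      ds <- dep[, s]; ds[is.na(g)] <- NA
      if (mean(ds, na.rm = TRUE) > cfg$max_mean_site_depth) { keep[s] <- FALSE; next }
    }
    if (mean(is.na(g)) > cfg$max_site_missingness) { keep[s] <- FALSE; next }
  }
  keep
}

# greedy thinning oracle over one sorted position vector
oracle_thin <- function(pos, window) {
  keep <- logical(length(pos))
  last <- NULL
  for (i in seq_along(pos)) {
    if (is.null(last) || pos[i] - last >= window) { keep[i] <- TRUE; last <- pos[i] }
  }
  keep
}

# scalar Weir & Cockerham 1984 components at one locus, two groups
oracle_wc_locus <- function(g1, g2) {
  stats <- function(g) {
    g <- g[!is.na(g)]
    list(n = length(g), p = sum(g) / (2 * length(g)), h = mean(g == 1))
  }
  s1 <- stats(g1); s2 <- stats(g2)
  r <- 2
  nbar <- (s1$n + s2$n) / r
  nc <- (s1$n + s2$n - (s1$n^2 + s2$n^2) / (s1$n + s2$n)) / (r - 1)
  pbar <- (s1$n * s1$p + s2$n * s2$p) / (r * nbar)
  s2v <- (s1$n * (s1$p - pbar)^2 + s2$n * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (s1$n * s1$h + s2$n * s2$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# exhaustive nearest-neighbour mixing scan (first-minimum tie-break)
oracle_mixing <- function(D, pops, group) {
  sel <- which(pops %in% group)
  res <- sapply(sel, function(i) {
    dr <- D[i, sel]; dr[match(i, sel)] <- Inf
    pops[sel][which.min(dr)] != pops[i]
  })
  tapply(res, pops[sel], mean)[group]
}

# spherical law of cosines, an independent great-circle formula
oracle_great_circle <- function(a, b, R = 6371) {
  tr <- pi / 180
  R * acos(pmin(1, sin(a[1] * tr) * sin(b[1] * tr) +
                  cos(a[1] * tr) * cos(b[1] * tr) * cos((b[2] - a[2]) * tr)))
}

# evidence constructor shorthand for classifier tests
ev <- function(pop, sources, alloch = character(), admixed = FALSE,
               homog = FALSE, collector = FALSE, habitat = NULL) {
  population_evidence(pop, c(46, 8), sources,
                      allochthonous_sources = alloch, admixed = admixed,
                      has_homogeneous_source_evidence = homog,
                      collector_assessment = collector,
                      habitat_modification_period = habitat)
}

# Dirichlet(1) rows, test-local twin of the package-internal initialiser
.rdirichlet_test <- function(n, k) {
  x <- matrix(rexp(n * k), n, k); x / rowSums(x)
}

truth_to_category <- c(natural = "natural",
                       seeded_homogeneous = "seeded_autochthonous_homogeneous",
                       seeded_admixed = "seeded_admixed",
                       seeded_allochthonous = "seeded_allochthonous")
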