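#' Quality-filter configuration
#'
#' Defaults reproduce the study design this package operationalises:
#' minor allele count >= 1, per-genotype depth >= 2 (failing genotypes
#' are set missing, not dropped), mean site depth in `[5, 30]`,
#' heterozygote allele balance inside `(0.2, 0.8)`, homozygote allele
#' balance outside `(0.01, 0.9)`, reference/alternate mapping-quality
#' ratio inside `(0.25, 1.75)`, quality-per-depth > 0.2, site
#' missingness <= 10% ("more than 10%" removed), individual missingness
#' <= 55% ("more than 55%" removed).
#'
#' @param min_minor_allele_count,min_genotype_depth,min_mean_site_depth,max_mean_site_depth
#'   depth/count thresholds.
#' @param het_allele_balance `(low, high)` keep-inside interval for the
#'   heterozygote allele-balance annotation `AB`.
#' @param hom_allele_balance `(low_max, high_min)`; with
#'   `hom_ab_keep_outside = TRUE` (default) a site is kept when its
#'   homozygote allele balance `ABHOM` is `< low_max` or `> high_min`.
#'   The source wording is ambiguous; the switch flips to keep-inside.
#' @param mapq_ratio keep-inside interval for `MQR`.
#' @param min_quality_per_depth lower bound on `QD`.
#' @param max_site_missingness,max_individual_missingness fractions in
#'   `[0, 1]`; strictly greater is removed.
#' @param hom_ab_keep_outside see `hom_allele_balance`.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_minor_allele_count = 1,
                          min_genotype_depth = 2,
                          min_mean_site_depth = 5,
                          max_mean_site_depth = 30,
                          het_allele_balance = c(0.2, 0.8),
                          hom_allele_balance = c(0.01, 0.9),
                          mapq_ratio = c(0.25, 1.75),
                          min_quality_per_depth = 0.2,
                          max_site_missingness = 0.10,
                          max_individual_missingness = 0.55,
                          hom_ab_keep_outside = TRUE) {
  for (iv in list(het_allele_balance, hom_allele_balance, mapq_ratio))
    if (iv[1] >= iv[2]) .stopf("invalid config: interval low must be < high")
  .check_prob(max_site_missingness, "max_site_missingness")
  .check_prob(max_individual_missingness, "max_individual_missingness")
  structure(as.list(environment()), class = "filter_config")
}

#' Apply the site filter cascade
#'
#' Rules fire in the study's stated order: (1) per-genotype depth
#' masking (before any missingness is computed), (2) minor allele
#' count, (3) minimum mean site depth, (4) heterozygote allele balance,
#' (5) homozygote allele balance, (6) mapping-quality ratio,
#' (7) quality-per-depth, (8) maximum mean site depth, (9) site
#' missingness. Annotation-based rules whose annotation is absent are
#' skipped with a warning, so VCFs from any caller are accepted.
#' The cascade is idempotent.
#'
#' @param G a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (data.frame `rule`, `sites_removed`; masking is reported as
#'   `genotypes_masked`).
#' @export
apply_site_filters <- function(G, cfg = filter_config()) {
  report <- data.frame(rule = character(0), sites_removed = integer(0))
  note <- function(rule, removed)
    report <<- rbind(report, data.frame(rule = rule, sites_removed = removed))
  ann <- function(nm) {
    if (!is.null(G$site_annotations) && nm %in% names(G$site_annotations))
      G$site_annotations[[nm]]
    else NULL
  }

  masked <- 0L
  if (!is.null(G$depth)) {
    low <- !is.na(G$dosages) & (is.na(G$depth) | G$depth < cfg$min_genotype_depth)
    masked <- sum(low)
    G$dosages[low] <- NA_integer_
  } else {
    .warnf("apply_site_filters: no per-genotype depth; depth masking skipped")
  }
  note("genotype_depth_mask", masked)

  drop_sites <- function(rule, bad) {
    bad[is.na(bad)] <- FALSE
    note(rule, sum(bad))
    if (any(bad)) G <<- subset_genotypes(G, j = which(!bad))
  }

  # minor allele count on post-masking calls
  ac <- colSums(G$dosages, na.rm = TRUE)
  an <- 2L * colSums(!is.na(G$dosages))
  mac <- pmin(ac, an - ac)
  drop_sites("minor_allele_count", mac < cfg$min_minor_allele_count)

  mean_depth <- function() {
    if (is.null(G$depth)) return(NULL)
    d <- G$depth; d[is.na(G$dosages)] <- NA_integer_
    colMeans(d, na.rm = TRUE)
  }
  md <- mean_depth()
  if (is.null(md)) .warnf("apply_site_filters: mean-depth rules skipped (no depth)")
  if (!is.null(md)) drop_sites("min_mean_site_depth", md < cfg$min_mean_site_depth)

  apply_ann <- function(rule, nm, bad_fun) {
    v <- ann(nm)
    if (is.null(v)) {
      .warnf("apply_site_filters: rule %s skipped (annotation %s absent)", rule, nm)
      note(rule, NA_integer_)
    } else drop_sites(rule, bad_fun(v))
  }
  apply_ann("het_allele_balance", "AB", function(v)
    v <= cfg$het_allele_balance[1] | v >= cfg$het_allele_balance[2])
  apply_ann("hom_allele_balance", "ABHOM", function(v) {
    inside <- v >= cfg$hom_allele_balance[1] & v <= cfg$hom_allele_balance[2]
    if (cfg$hom_ab_keep_outside) inside else !inside
  })
  apply_ann("mapq_ratio", "MQR", function(v)
    v <= cfg$mapq_ratio[1] | v >= cfg$mapq_ratio[2])
  apply_ann("quality_per_depth", "QD", function(v)
    v <= cfg$min_quality_per_depth)

  md <- mean_depth()
  if (!is.null(md)) drop_sites("max_mean_site_depth", md > cfg$max_mean_site_depth)

  miss <- colMeans(is.na(G$dosages))
  drop_sites("site_missingness", miss > cfg$max_site_missingness)

  list(genotypes = G, report = report)
}

#' Remove individuals with excessive missingness
#'
#' Individuals whose fraction of missing genotypes is strictly greater
#' than `max_missing` are removed; order of the remaining individuals
#' is preserved.
#'
#' @param G a [genotype_matrix()].
#' @param max_missing fraction in `[0, 1]` (default 0.55).
#' @return filtered [genotype_matrix()].
#' @export
filter_individuals <- function(G, max_missing = 0.55) {
  .check_prob(max_missing, "max_missing")
  miss <- rowMeans(is.na(G$dosages))
  keep <- miss <= max_missing
  if (!any(keep)) .stopf("empty cohort: every individual exceeds %.0f%% missingness",
                         100 * max_missing)
  if (all(keep)) G else subset_genotypes(G, i = which(keep))
}

#' Thin SNPs to at most one per window
#'
#' Greedy per-scaffold scan: the first site of a scaffold is kept, and
#' thereafter any site at least `window_bp` base pairs from the last
#' kept site. Scaffolds are independent; given sorted input the result
#' is deterministic and no two kept sites are closer than `window_bp`.
#'
#' @param G a [genotype_matrix()] (loci sorted; the container enforces
#'   this, unsorted input would be sorted with a warning).
#' @param window_bp window length in bp (default 5000).
#' @return thinned [genotype_matrix()].
#' @export
ld_thin <- function(G, window_bp = 5000) {
  if (window_bp <= 0) return(G)
  keep <- logical(n_loci(G))
  for (chr in unique(G$loci$chrom)) {
    idx <- which(G$loci$chrom == chr)
    pos <- G$loci$pos[idx]
    if (is.unsorted(pos)) {            # container sorts, but be safe
      .warnf("ld_thin: unsorted positions on %s; sorting", chr)
      o <- order(pos); idx <- idx[o]; pos <- pos[o]
    }
    last <- -Inf
    for (i in seq_along(idx)) {
      if (pos[i] - last >= window_bp || !is.finite(last)) {
        keep[idx[i]] <- TRUE
        last <- pos[i]
      }
    }
  }
  subset_genotypes(G, j = which(keep))
}
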