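#' Specify an evolutionary significant unit (ESU) for simulation
#'
#' An ESU is a strongly diverged lineage within the species. Its allele
#' frequencies are drawn around a shared ancestral frequency under the
#' Balding-Nichols model, so `drift` maps directly onto the expected
#' F_ST between this ESU and the ancestral pool.
#'
#' @param esu_id label.
#' @param drift Balding-Nichols differentiation parameter in (0, 1).
#' @param centroid numeric `c(lat, lon)` of the ESU range centre,
#'   decimal degrees.
#' @param range_radius_km nominal natural range radius, km (> 0).
#' @return an `esu_spec` list.
#' @export
esu_spec <- function(esu_id, drift, centroid, range_radius_km = 100) {
  .check_prob(drift, "drift", open = TRUE)
  if (length(centroid) != 2 || abs(centroid[1]) > 90 || abs(centroid[2]) > 180)
    .stopf("invalid config: centroid must be c(lat, lon) in valid ranges")
  if (range_radius_km <= 0) .stopf("invalid config: range_radius_km must be > 0")
  structure(list(esu_id = as.character(esu_id), drift = drift,
                 centroid = as.numeric(centroid),
                 range_radius_km = range_radius_km),
            class = "esu_spec")
}

#' Specify a simulated population
#'
#' @param pop_id label.
#' @param coords numeric `c(lat, lon)`.
#' @param n_individuals diploid individuals to simulate (>= 1).
#' @param category one of `natural`, `seeded_homogeneous`,
#'   `seeded_admixed`, `seeded_allochthonous`. `natural` requires exactly
#'   one source at proportion 1 and `founder_size = 0`.
#' @param sources named numeric vector of ESU mixture proportions
#'   (names are ESU ids; must sum to 1).
#' @param founder_size seed-lot founder count; the lot frequencies are a
#'   binomial sample of `2 * founder_size` allele copies from the source
#'   mixture. 0 disables the bottleneck.
#' @param seed_lot optional label; seeded populations sharing a label
#'   are sown from one and the same seed lot (one draw of lot
#'   frequencies), which is what makes commercial multi-site seeding
#'   detectable as a star cluster. Default: one private lot per
#'   population.
#' @param within_drift Balding-Nichols drift of this population's own
#'   frequencies around its source mixture. Natural populations need a
#'   non-zero value (local drift within the ESU); seeded populations
#'   default to 0 because the seed-lot bottleneck already supplies their
#'   differentiation.
#' @return a `population_spec` list.
#' @export
population_spec <- function(pop_id, coords, n_individuals, category,
                            sources, founder_size = NULL, seed_lot = NULL,
                            within_drift = NULL) {
  category <- match.arg(category, c("natural", "seeded_homogeneous",
                                    "seeded_admixed", "seeded_allochthonous"))
  if (is.null(names(sources)) || any(!nzchar(names(sources))))
    .stopf("invalid config: sources must be a named vector of ESU proportions")
  .check_prob(sources, "source proportions")
  if (abs(sum(sources) - 1) > 1e-9)
    .stopf("invalid config: source proportions must sum to 1")
  if (n_individuals < 1) .stopf("invalid config: n_individuals >= 1 required")
  if (is.null(founder_size))
    founder_size <- if (category == "natural") 0L else 10L
  if (category == "natural") {
    if (length(sources) != 1 || founder_size != 0)
      .stopf("invalid config: natural populations have one source and no bottleneck")
    if (is.null(within_drift)) within_drift <- 0.05
  } else {
    if (is.null(within_drift)) within_drift <- 0
  }
  if (within_drift < 0 || within_drift >= 1)
    .stopf("invalid config: within_drift must lie in [0, 1)")
  structure(list(pop_id = as.character(pop_id), coords = as.numeric(coords),
                 n_individuals = as.integer(n_individuals),
                 category = category, sources = sources,
                 founder_size = as.integer(founder_size),
                 seed_lot = seed_lot %||% paste0("lot_", pop_id),
                 within_drift = within_drift),
            class = "population_spec")
}

#' Scenario configuration for the synthetic-data generator
#'
#' @param esus list of [esu_spec()].
#' @param populations list of [population_spec()]; every source ESU must
#'   be present in `esus`.
#' @param n_loci number of simulated biallelic SNPs.
#' @param ancestral_freq_bounds ancestral allele frequencies are i.i.d.
#'   uniform on this interval (subset of (0, 1)).
#' @param missing_rate i.i.d. probability that a genotype call is
#'   missing (missing completely at random).
#' @param replicate_pairs number of individuals re-genotyped as
#'   technical replicates.
#' @param injected_error_rate per-genotype probability that a replicate
#'   call is perturbed to a different dosage.
#' @param rng_seed integer seed; the whole scenario is deterministic
#'   given the seed.
#' @param locus_spacing_bp locus gaps are drawn uniformly in
#'   `(spacing, 2 * spacing]`, emulating an already-thinned SNP panel.
#' @param n_scaffolds scaffolds over which loci are distributed.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(esus, populations, n_loci = 2000,
                            ancestral_freq_bounds = c(0.05, 0.95),
                            missing_rate = 0.02, replicate_pairs = 0,
                            injected_error_rate = 0.005, rng_seed = 1,
                            locus_spacing_bp = 6000, n_scaffolds = 10) {
  if (n_loci < 1) .stopf("invalid config: n_loci >= 1 required")
  .check_prob(ancestral_freq_bounds, "ancestral_freq_bounds", open = TRUE)
  if (diff(ancestral_freq_bounds) < 0) .stopf("invalid config: bounds reversed")
  if (missing_rate < 0 || missing_rate >= 1)
    .stopf("invalid config: missing_rate in [0, 1) required")
  if (injected_error_rate < 0 || injected_error_rate >= 1)
    .stopf("invalid config: injected_error_rate in [0, 1) required")
  esu_ids <- vapply(esus, `[[`, "", "esu_id")
  if (anyDuplicated(esu_ids)) .stopf("invalid config: duplicate ESU ids")
  for (p in populations) {
    miss <- setdiff(names(p$sources), esu_ids)
    if (length(miss))
      .stopf("invalid config: population %s references unknown ESU %s",
             p$pop_id, miss[1])
  }
  structure(list(esus = esus, populations = populations,
                 n_loci = as.integer(n_loci),
                 ancestral_freq_bounds = ancestral_freq_bounds,
                 missing_rate = missing_rate,
                 replicate_pairs = as.integer(replicate_pairs),
                 injected_error_rate = injected_error_rate,
                 rng_seed = as.integer(rng_seed),
                 locus_spacing_bp = locus_spacing_bp,
                 n_scaffolds = as.integer(n_scaffolds)),
            class = "scenario_config")
}

#' Draw ancestral allele frequencies
#'
#' @param n_loci number of loci.
#' @param bounds `c(low, high)` with `0 < low <= high < 1`.
#' @return numeric vector of length `n_loci`, i.i.d. uniform on
#'   `[low, high]`. Uses the current RNG state.
#' @export
draw_ancestral_freqs <- function(n_loci, bounds = c(0.05, 0.95)) {
  .check_prob(bounds, "bounds", open = TRUE)
  if (bounds[1] > bounds[2]) .stopf("invalid config: bounds reversed")
  if (n_loci == 0) return(numeric(0))
  stats::runif(n_loci, bounds[1], bounds[2])
}

#' Draw ESU allele frequencies under the Balding-Nichols model
#'
#' For each ESU `k` with drift `F_k`, locus frequencies are drawn
#' `p_kj ~ Beta(pbar_j (1 - F_k) / F_k, (1 - pbar_j)(1 - F_k) / F_k)`,
#' so `E[p_kj] = pbar_j` and `Var[p_kj] = F_k pbar_j (1 - pbar_j)`.
#'
#' @param p_bar ancestral frequency vector.
#' @param drifts per-ESU drift values in (0, 1), optionally named.
#' @return matrix `K x n_loci` of ESU frequencies.
#' @export
draw_esu_freqs <- function(p_bar, drifts) {
  if (any(drifts <= 0 | drifts >= 1))
    .stopf("invalid config: drift parameters must lie in (0, 1)")
  P <- matrix(NA_real_, length(drifts), length(p_bar),
              dimnames = list(names(drifts), NULL))
  for (k in seq_along(drifts)) {
    s <- (1 - drifts[k]) / drifts[k]
    P[k, ] <- stats::rbeta(length(p_bar), p_bar * s, (1 - p_bar) * s)
  }
  P
}

#' Sample seed-lot allele frequencies
#'
#' A commercial seed lot is modelled as a finite founder sample: source
#' ESU frequencies are first mixed with the given weights, then the
#' mixture frequency `f_j` is replaced by `x_j / (2 * founder_size)`
#' with `x_j ~ Binomial(2 * founder_size, f_j)`. `founder_size = 0`
#' returns the mixture unchanged.
#'
#' @param source_freqs matrix (sources x loci) or vector of source
#'   frequencies.
#' @param proportions mixture weights summing to 1 (scalar 1 allowed for
#'   a single source).
#' @param founder_size founder individuals in the lot (>= 0).
#' @return frequency vector of the seed lot.
#' @export
make_seed_lot <- function(source_freqs, proportions = 1, founder_size = 0) {
  if (is.vector(source_freqs)) source_freqs <- matrix(source_freqs, nrow = 1)
  if (length(proportions) != nrow(source_freqs))
    .stopf("proportions length must match number of sources")
  if (abs(sum(proportions) - 1) > 1e-9) .stopf("mixture weights must sum to 1")
  if (founder_size < 0) .stopf("founder_size must be >= 0")
  f <- as.vector(proportions %*% source_freqs)
  if (founder_size == 0) return(f)
  stats::rbinom(length(f), 2L * founder_size, f) / (2 * founder_size)
}

# negative-binomial per-genotype depth and per-site annotation draws;
# these exist only so the QC filter cascade has something to act on
.simulate_annotations <- function(n, j) {
  depth <- matrix(stats::rnbinom(n * j, size = 6, mu = 14), n, j)
  ab <- stats::rbeta(j, 8, 8)                      # het allele balance ~ 0.5
  mid <- stats::runif(j) < 0.03                    # a few bad hom-AB sites
  abhom <- ifelse(mid, stats::runif(j, 0.01, 0.9),
                  ifelse(stats::runif(j) < 0.5, stats::runif(j, 0, 0.01),
                         stats::runif(j, 0.9, 1)))
  qd <- stats::rgamma(j, shape = 4, scale = 3)     # quality per depth
  mqr <- stats::rnorm(j, 1, 0.12)                  # ref/alt mapping-quality ratio
  list(depth = depth,
       ann = data.frame(AB = ab, ABHOM = abhom, QD = qd, MQR = mqr))
}

#' Simulate diploid genotypes from ancestry and ESU frequencies
#'
#' Genotypes are `g_ij ~ Binomial(2, f_ij)` with
#' `f_ij = sum_k q_ik p_kj` (no linkage, Hardy-Weinberg within mixture
#' components). Per-genotype depth and per-site annotations are drawn
#' from fixed illustrative distributions so the filter cascade is
#' exercisable; missingness is applied i.i.d.
#'
#' @param Q individuals x K ancestry matrix, rows summing to 1.
#' @param P K x loci frequency matrix in `[0, 1]`.
#' @param missing_rate i.i.d. missing-call probability.
#' @param individual_ids,pop_prefix optional row labels.
#' @param start_scaffold,locus_spacing_bp,n_scaffolds locus layout.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(Q, P, missing_rate = 0,
                               individual_ids = NULL,
                               locus_spacing_bp = 6000, n_scaffolds = 10,
                               pop_prefix = "ind", start_scaffold = 1) {
  Q <- as.matrix(Q); P <- as.matrix(P)
  if (ncol(Q) != nrow(P)) .stopf("shape error: ncol(Q) = %d != nrow(P) = %d",
                                 ncol(Q), nrow(P))
  if (any(abs(rowSums(Q) - 1) > 1e-9)) .stopf("Q rows must sum to 1")
  if (any(P < 0 | P > 1)) .stopf("P entries must lie in [0, 1]")
  n <- nrow(Q); j <- ncol(P)
  f <- Q %*% P
  g <- matrix(stats::rbinom(n * j, 2L, pmin(pmax(f, 0), 1)), n, j)
  if (missing_rate > 0)
    g[matrix(stats::runif(n * j) < missing_rate, n, j)] <- NA_integer_
  loci <- .locus_layout(j, locus_spacing_bp, n_scaffolds, start_scaffold)
  ann <- .simulate_annotations(n, j)
  ids <- individual_ids %||% paste0(pop_prefix, seq_len(n))
  genotype_matrix(g, ids, loci, ann$ann, ann$depth)
}

.locus_layout <- function(j, spacing, n_scaffolds, start_scaffold = 1) {
  per <- ceiling(j / n_scaffolds)
  # zero-padded so lexicographic locus sorting preserves generation order
  chrom <- rep(sprintf("scaffold_%03d", start_scaffold - 1 + seq_len(n_scaffolds)),
               each = per)[seq_len(j)]
  # gaps in (spacing, 2*spacing]: simulated panels are post-thinning sparse,
  # so a default 5 kb LD-thin pass leaves them intact
  gaps <- spacing + sample.int(spacing, j, replace = TRUE)
  pos <- stats::ave(gaps, chrom, FUN = cumsum)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, j, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Generate a full georeferenced scenario with known truth
#'
#' Draws ancestral and ESU frequencies, builds per-population frequency
#' vectors (Balding-Nichols within-population drift for natural
#' populations; mixture-then-bottleneck seed lots for seeded ones,
#' shared across populations sowing the same `seed_lot`), simulates
#' genotypes with annotations and missingness, produces error-injected
#' technical replicate copies, and returns the ground truth. Fully
#' deterministic given `config$rng_seed`.
#'
#' @param config a [scenario_config()].
#' @param out_dir optional directory; when given, writes `scenario.vcf`,
#'   `metadata.tsv`, `replicates.vcf` (if any) and `truth.tsv`.
#' @return list with `genotypes` ([genotype_matrix()]), `metadata`
#'   (data.frame: individual_id, pop_id, latitude, longitude, status),
#'   `replicates` (genotype_matrix of replicate copies or `NULL`),
#'   `replicate_pairs` (data.frame id/replicate_id), and `truth`
#'   (list: `true_Q`, `true_P`, `true_category`, `seed_lot_freqs`,
#'   `pop_freqs`).
#' @export
generate_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$rng_seed)
  esu_ids <- vapply(config$esus, `[[`, "", "esu_id")
  drifts <- stats::setNames(vapply(config$esus, `[[`, 0, "drift"), esu_ids)

  p_bar <- draw_ancestral_freqs(config$n_loci, config$ancestral_freq_bounds)
  P <- draw_esu_freqs(p_bar, drifts)

  # per-population effective frequencies
  lot_freqs <- list()
  pop_freqs <- list()
  for (p in config$populations) {
    w <- p$sources[esu_ids[esu_ids %in% names(p$sources)]]
    src <- P[names(w), , drop = FALSE]
    if (p$category == "natural") {
      f <- as.vector(src)
      if (p$within_drift > 0)
        f <- as.vector(draw_esu_freqs(f, p$within_drift))
    } else {
      if (is.null(lot_freqs[[p$seed_lot]]))
        lot_freqs[[p$seed_lot]] <- make_seed_lot(src, as.numeric(w), p$founder_size)
      f <- lot_freqs[[p$seed_lot]]
      if (p$within_drift > 0)
        f <- as.vector(draw_esu_freqs(f, p$within_drift))
    }
    pop_freqs[[p$pop_id]] <- pmin(pmax(f, 0), 1)
  }

  n_total <- sum(vapply(config$populations, `[[`, 0L, "n_individuals"))
  ids <- character(0); pops <- character(0)
  true_Q <- matrix(0, n_total, length(esu_ids),
                   dimnames = list(NULL, esu_ids))
  g <- matrix(NA_integer_, n_total, config$n_loci)
  row0 <- 0L
  for (p in config$populations) {
    idx <- row0 + seq_len(p$n_individuals)
    ids[idx] <- sprintf("%s_%02d", p$pop_id, seq_len(p$n_individuals))
    pops[idx] <- p$pop_id
    true_Q[idx, names(p$sources)] <- matrix(p$sources, p$n_individuals,
                                            length(p$sources), byrow = TRUE)
    f <- pop_freqs[[p$pop_id]]
    g[idx, ] <- matrix(stats::rbinom(p$n_individuals * config$n_loci, 2L,
                                     rep(f, each = p$n_individuals)),
                       p$n_individuals, config$n_loci)
    row0 <- row0 + p$n_individuals
  }
  if (config$missing_rate > 0)
    g[matrix(stats::runif(length(g)) < config$missing_rate, nrow(g))] <- NA_integer_
  rownames(true_Q) <- ids

  loci <- .locus_layout(config$n_loci, config$locus_spacing_bp, config$n_scaffolds)
  ann <- .simulate_annotations(n_total, config$n_loci)
  G <- genotype_matrix(g, ids, loci, ann$ann, ann$depth)

  metadata <- data.frame(
    individual_id = ids, pop_id = pops,
    latitude = vapply(pops, function(pp) .pop_by_id(config, pp)$coords[1], 0),
    longitude = vapply(pops, function(pp) .pop_by_id(config, pp)$coords[2], 0),
    status = vapply(pops, function(pp)
      if (.pop_by_id(config, pp)$category == "natural") "natural" else "unknown", ""),
    row.names = NULL, stringsAsFactors = FALSE)

  replicates <- NULL; rep_pairs <- NULL
  if (config$replicate_pairs > 0) {
    take <- seq_len(min(config$replicate_pairs, n_total))
    # re-draw calls from the same individual genotypes, inject errors and
    # fresh missingness (independent library preparation)
    rg <- G$dosages[take, , drop = FALSE]
    err <- matrix(stats::runif(length(rg)) < config$injected_error_rate, nrow(rg))
    err[is.na(rg)] <- FALSE
    if (any(err)) {
      shift <- 1L + (stats::runif(sum(err)) < 0.5)         # +1 or +2 mod 3
      rg[err] <- (rg[err] + shift) %% 3L
    }
    if (config$missing_rate > 0)
      rg[matrix(stats::runif(length(rg)) < config$missing_rate, nrow(rg))] <- NA_integer_
    rann <- .simulate_annotations(length(take), config$n_loci)
    rep_ids <- paste0(ids[take], ".rep")
    # use G$loci (already sorted) so replicate columns stay aligned
    replicates <- genotype_matrix(rg, rep_ids, G$loci, rann$ann, rann$depth)
    rep_pairs <- data.frame(id = ids[take], replicate_id = rep_ids,
                            stringsAsFactors = FALSE)
  }

  truth <- list(true_Q = true_Q, true_P = P,
                true_category = stats::setNames(
                  vapply(config$populations, `[[`, "", "category"),
                  vapply(config$populations, `[[`, "", "pop_id")),
                seed_lot_freqs = lot_freqs, pop_freqs = pop_freqs)

  out <- list(genotypes = G, metadata = metadata, replicates = replicates,
              replicate_pairs = rep_pairs, truth = truth, config = config)
  if (!is.null(out_dir)) .write_scenario(out, out_dir)
  out
}

.pop_by_id <- function(config, pop_id) {
  for (p in config$populations) if (p$pop_id == pop_id) return(p)
  .stopf("unknown population %s", pop_id)
}

.write_scenario <- function(scn, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    .stopf("I/O error: cannot create output directory %s", out_dir)
  write_vcf(scn$genotypes, file.path(out_dir, "scenario.vcf"))
  utils::write.table(scn$metadata, file.path(out_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(scn$replicates)) {
    write_vcf(scn$replicates, file.path(out_dir, "replicates.vcf"))
    utils::write.table(scn$replicate_pairs,
                       file.path(out_dir, "replicate_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_truth(scn$truth, file.path(out_dir, "truth.tsv"))
  invisible(out_dir)
}

#' Write / read scenario ground truth as key-value text
#'
#' One `key<TAB>value` row per entry; matrix rows are serialised as
#' comma-separated values with 15 significant digits. Keys:
#' `category.<pop>`, `Q.<individual>`, `P.<esu>`, `lot.<seed_lot>`.
#'
#' @param truth truth list from [generate_scenario()].
#' @param path output file.
#' @return the path (write) or a truth-like list (read).
#' @export
write_truth <- function(truth, path) {
  num <- function(x) paste(sprintf("%.15g", x), collapse = ",")
  lines <- c(
    paste0("category.", names(truth$true_category), "\t", truth$true_category),
    paste0("Q.", rownames(truth$true_Q), "\t",
           apply(truth$true_Q, 1, num)),
    paste0("P.", rownames(truth$true_P), "\t", apply(truth$true_P, 1, num)),
    if (length(truth$seed_lot_freqs))
      paste0("lot.", names(truth$seed_lot_freqs), "\t",
             vapply(truth$seed_lot_freqs, num, "")))
  con <- file(path, "wb")  # fixed newlines => byte-identical across platforms
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  key <- raw[[1]]; val <- raw[[2]]
  pick <- function(prefix) {
    sel <- startsWith(key, prefix)
    stats::setNames(val[sel], sub(prefix, "", key[sel], fixed = TRUE))
  }
  nums <- function(x) lapply(x, function(s) as.numeric(strsplit(s, ",")[[1]]))
  qs <- pick("Q."); ps <- pick("P.")
  list(true_category = pick("category."),
       true_Q = do.call(rbind, nums(qs)) |> `rownames<-`(names(qs)),
       true_P = do.call(rbind, nums(ps)) |> `rownames<-`(names(ps)),
       seed_lot_freqs = nums(pick("lot.")))
}

#' Packaged demonstration scenario
#'
#' The reference validation world used throughout the test-suite: three
#' ESUs (two autochthonous with natural reference populations, one
#' allochthonous with none), two natural populations plus one natural
#' population of a second ESU, three populations sown from a single
#' shared seed lot, one allochthonous-seeded and one admixed-seeded
#' population. Drift levels follow the low end of differentiation
#' observed between strongly diverged conspecific lineages (about 0.2),
#' within-ESU population drift is 0.05, and seed lots bottleneck through
#' 10 founders.
#'
#' @param rng_seed scenario seed.
#' @param n_loci simulated SNPs (default 1200 so that >= 1000 survive QC).
#' @param n_per_pop individuals per population.
#' @param replicate_pairs technical replicate individuals.
#' @param injected_error_rate replicate error probability.
#' @return a [scenario_config()].
#' @export
demo_scenario_config <- function(rng_seed = 1, n_loci = 1200, n_per_pop = 10,
                                 replicate_pairs = 0,
                                 injected_error_rate = 0.005) {
  esus <- list(
    esu_spec("ESU_West", 0.20, c(46.8, 7.1)),
    esu_spec("ESU_South", 0.25, c(46.0, 8.9)),
    esu_spec("ESU_Foreign", 0.20, c(48.5, 25.0)))
  pops <- list(
    population_spec("NAT_A1", c(46.90, 7.00), n_per_pop, "natural",
                    c(ESU_West = 1)),
    population_spec("NAT_A2", c(46.70, 7.30), n_per_pop, "natural",
                    c(ESU_West = 1)),
    population_spec("NAT_B1", c(46.00, 8.90), n_per_pop, "natural",
                    c(ESU_South = 1)),
    population_spec("SEED_S1", c(46.95, 7.50), n_per_pop, "seeded_homogeneous",
                    c(ESU_West = 1), seed_lot = "lot_west"),
    population_spec("SEED_S2", c(47.10, 6.90), n_per_pop, "seeded_homogeneous",
                    c(ESU_West = 1), seed_lot = "lot_west"),
    population_spec("SEED_S3", c(46.60, 7.60), n_per_pop, "seeded_homogeneous",
                    c(ESU_West = 1), seed_lot = "lot_west"),
    population_spec("SEED_L1", c(47.40, 7.00), n_per_pop, "seeded_allochthonous",
                    c(ESU_Foreign = 1)),
    population_spec("SEED_M1", c(46.85, 7.20), n_per_pop, "seeded_admixed",
                    c(ESU_West = 0.5, ESU_Foreign = 0.5)))
  scenario_config(esus, pops, n_loci = n_loci,
                  replicate_pairs = replicate_pairs,
                  injected_error_rate = injected_error_rate,
                  rng_seed = rng_seed)
}
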