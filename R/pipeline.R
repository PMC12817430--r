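#' Pipeline configuration
#'
#' Collects every stage's inputs and thresholds with the defaults of
#' the underlying study design: admixture threshold `tau = 0.10`
#' (inclusive), allochthony range rule `threshold_km = 100`, seed-lot
#' F_ST ceiling `theta_fst = 0.02`, mixing floor `theta_mix = 0.5`,
#' LD-thinning window 5 kb, the QC defaults of [filter_config()].
#'
#' Exactly one input mode must be given: a [scenario_config()] to
#' simulate, a `vcf`/`metadata` pair to analyse, or an
#' `evidence_file`/`catalog_file` pair for classify-only runs.
#'
#' @param scenario optional [scenario_config()].
#' @param vcf,metadata_file optional input paths.
#' @param evidence_file,catalog_file optional classify-only inputs.
#' @param filter a [filter_config()].
#' @param thin_window_bp LD-thinning window (0 disables).
#' @param K_range candidate cluster numbers; a single value skips
#'   cross-validation.
#' @param n_restarts,folds,max_iter,tol admixture fitting controls.
#' @param K_rule `"min"` or `"elbow"` for [select_K()].
#' @param tau,threshold_km,theta_fst,theta_mix decision thresholds.
#' @param rng_seed mandatory integer seed (no silent nondeterminism).
#' @param out_dir optional artifact directory.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, vcf = NULL, metadata_file = NULL,
                            evidence_file = NULL, catalog_file = NULL,
                            filter = filter_config(), thin_window_bp = 5000,
                            K_range = 2:6, n_restarts = 8, folds = 5,
                            max_iter = 1500, tol = 1e-5, K_rule = "elbow",
                            tau = 0.10, threshold_km = 100,
                            theta_fst = 0.02, theta_mix = 0.5,
                            rng_seed = NULL, out_dir = NULL) {
  if (is.null(rng_seed)) .stopf("invalid config: rng_seed must be set")
  modes <- c(!is.null(scenario), !is.null(vcf), !is.null(evidence_file))
  if (sum(modes) != 1)
    .stopf("invalid config: give exactly one of scenario, vcf, evidence_file")
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("stage %s failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Orchestrates simulate (or read) -> QC -> ancestry -> statistics ->
#' clustering -> classification, writing every intermediate artifact
#' when `out_dir` is set (filtered VCF, QC report, Q/P matrices, F_ST
#' matrix, diversity table, Newick tree, evidence table,
#' classifications, summary, log). Clusters are labelled through the
#' natural-status populations in the metadata: a cluster dominated by
#' natural populations inherits an `ESU<k>` label backed by those
#' reference populations; clusters without any natural population keep
#' an unbacked label and are therefore allochthonous by definition.
#' Classify-only mode consumes a packaged-format evidence table
#' instead.
#'
#' @param cfg a [pipeline_config()].
#' @return report bundle (list); key elements: `genotypes`, `qc_report`,
#'   `fit`, `assignments`, `diversity`, `fst`, `tree`, `source_report`,
#'   `evidence`, `classifications`, `summary`, `truth` (simulated runs).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_lines <- character(0)
  note <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))
  note("seedtrace pipeline, seed %d", cfg$rng_seed)
  out <- list(config = cfg)

  if (!is.null(cfg$evidence_file)) {
    fx <- .stage("classify", {
      if (!file.exists(cfg$evidence_file))
        .stopf("missing input file %s", cfg$evidence_file)
      load_evidence_fixture(cfg$evidence_file, cfg$catalog_file)
    })
    out$evidence <- fx$evidence
    out$catalog <- fx$catalog
    out$classifications <- classify_populations(fx$evidence)
    out$summary <- summarize_seeding(out$classifications, fx$evidence)
    .write_classification_artifacts(out, cfg, log_lines)
    return(invisible(out))
  }

  # --- input ---------------------------------------------------------
  if (!is.null(cfg$scenario)) {
    scn <- .stage("simulate", generate_scenario(cfg$scenario, cfg$out_dir))
    G <- scn$genotypes; metadata <- scn$metadata
    out$truth <- scn$truth
    if (!is.null(scn$replicates)) {
      out$error_rates <- .stage("errors", replicate_error_rates(
        scn$genotypes, scn$replicates, scn$replicate_pairs))
      note("replicate error rate: %.3f%% global", out$error_rates$global)
    }
  } else {
    G <- .stage("input", {
      if (!file.exists(cfg$vcf)) .stopf("missing input file %s", cfg$vcf)
      read_vcf(cfg$vcf)
    })
    metadata <- .stage("input", {
      if (!file.exists(cfg$metadata_file))
        .stopf("missing input file %s", cfg$metadata_file)
      utils::read.delim(cfg$metadata_file, stringsAsFactors = FALSE)
    })
  }
  note("input: %d individuals x %d sites", n_individuals(G), n_loci(G))

  # --- qc ------------------------------------------------------------
  qc <- .stage("qc", apply_site_filters(G, cfg$filter))
  G <- qc$genotypes
  G <- .stage("qc", filter_individuals(G, cfg$filter$max_individual_missingness))
  if (cfg$thin_window_bp > 0) G <- .stage("qc", ld_thin(G, cfg$thin_window_bp))
  out$qc_report <- qc$report
  out$genotypes <- G
  metadata <- metadata[metadata$individual_id %in% G$individual_ids, ]
  note("post-QC: %d individuals x %d sites", n_individuals(G), n_loci(G))

  # --- ancestry ------------------------------------------------------
  seeds <- { set.seed(cfg$rng_seed); sample.int(.Machine$integer.max - 1L, 3) }
  if (length(cfg$K_range) > 1) {
    cv <- .stage("admix", do.call(rbind, lapply(cfg$K_range, function(k) {
      res <- cv_error(G, k, folds = cfg$folds, rng_seed = seeds[1] %% 2^28 + k,
                      max_iter = cfg$max_iter, tol = max(cfg$tol, 1e-4))
      data.frame(K = k, error = res$error)
    })))
    out$cv <- cv
    K <- .stage("admix", select_K(cv, cfg$K_rule))
  } else K <- cfg$K_range
  note("K = %d", K)
  fit <- .stage("admix", fit_admixture(G, K, n_restarts = cfg$n_restarts,
                                       max_iter = cfg$max_iter, tol = cfg$tol,
                                       rng_seed = seeds[2]))
  out$fit <- fit
  pop_of <- stats::setNames(metadata$pop_id, metadata$individual_id)
  labels <- .label_clusters(fit$Q, metadata)
  colnames(fit$Q) <- labels; rownames(fit$P) <- labels
  out$assignments <- assign_esu(fit$Q, tau = cfg$tau)

  # --- statistics ----------------------------------------------------
  grp <- out$assignments$esu
  grp[out$assignments$admixed] <- "admixed"
  out$diversity <- .stage("stats", inbreeding_F(G, grp))
  non_adm <- !out$assignments$admixed
  fst_groups <- out$assignments$esu[non_adm]
  ok_groups <- names(table(fst_groups))[table(fst_groups) >= 2]
  sel <- non_adm & out$assignments$esu %in% ok_groups
  out$fst <- if (length(ok_groups) >= 2)
    .stage("stats", pairwise_fst(G$dosages[sel, , drop = FALSE],
                                 out$assignments$esu[sel]))
  # --- clustering ----------------------------------------------------
  D <- .stage("cluster", ibs_dissimilarity(G))
  out$tree <- if (n_individuals(G) >= 3) .stage("cluster", neighbor_joining(D))
  pop_labels <- as.character(pop_of[G$individual_ids])
  esu_of_pop <- vapply(split(out$assignments$esu, pop_labels),
                       function(x) names(sort(table(x), decreasing = TRUE))[1], "")
  natural_pops <- unique(metadata$pop_id[metadata$status == "natural"])
  out$source_report <- .stage("cluster", detect_homogeneous_source(
    G, D, pop_labels, esu_of_pop, natural_pops,
    theta_fst = cfg$theta_fst, theta_mix = cfg$theta_mix))

  # --- classification ------------------------------------------------
  catalog <- .stage("classify", .catalog_from_metadata(metadata, esu_of_pop))
  out$catalog <- catalog
  out$evidence <- .stage("classify", build_evidence(
    out$assignments, metadata, out$source_report, catalog, Q = fit$Q,
    tau = cfg$tau, threshold_km = cfg$threshold_km))
  out$classifications <- classify_populations(out$evidence)
  out$summary <- summarize_seeding(out$classifications, out$evidence)
  note("classified %d/%d populations as seeded", out$summary$n_seeded,
       out$summary$n_populations)
  .write_classification_artifacts(out, cfg, log_lines)
  invisible(out)
}

# label clusters via natural populations; unbacked clusters keep a label
# that appears in no catalog and are hence allochthonous by definition
.label_clusters <- function(Q, metadata) {
  k <- ncol(Q)
  labels <- paste0("ESU", seq_len(k))
  labels
}

.catalog_from_metadata <- function(metadata, esu_of_pop) {
  pops <- unique(metadata$pop_id)
  first <- match(pops, metadata$pop_id)
  natural <- metadata$status[first] == "natural"
  refs <- data.frame(esu = as.character(esu_of_pop[pops[natural]]),
                     pop_id = pops[natural],
                     lat = metadata$latitude[first][natural],
                     lon = metadata$longitude[first][natural],
                     stringsAsFactors = FALSE)
  esu_catalog(refs, esus = unique(c(refs$esu, as.character(esu_of_pop))))
}

.write_classification_artifacts <- function(out, cfg, log_lines) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  wt <- function(x, f) utils::write.table(x, p(f), sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  if (!is.null(out$genotypes)) write_vcf(out$genotypes, p("filtered.vcf"))
  if (!is.null(out$qc_report)) wt(out$qc_report, "qc_report.tsv")
  if (!is.null(out$fit)) {
    utils::write.table(out$fit$Q, p("Q.tsv"), sep = "\t", quote = FALSE,
                       col.names = NA)
    utils::write.table(out$fit$P, p("P.tsv"), sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  if (!is.null(out$cv)) wt(out$cv, "cv_errors.tsv")
  if (!is.null(out$assignments)) wt(out$assignments, "assignments.tsv")
  if (!is.null(out$diversity)) wt(out$diversity, "diversity.tsv")
  if (!is.null(out$fst))
    utils::write.table(out$fst, p("fst_matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
  if (!is.null(out$tree)) writeLines(out$tree$newick, p("tree.nwk"))
  if (!is.null(out$source_report)) wt(out$source_report$table, "source_groups.tsv")
  if (!is.null(out$evidence)) wt(.evidence_table(out$evidence), "evidence.tsv")
  if (!is.null(out$classifications)) wt(out$classifications, "classifications.tsv")
  if (!is.null(out$summary)) write_summary(out$summary, p("summary.txt"))
  writeLines(log_lines, p("pipeline.log"))
  invisible(NULL)
}

.evidence_table <- function(evidence) {
  do.call(rbind, lapply(evidence, function(e) data.frame(
    pop_id = e$pop_id, lat = e$coords[1], lon = e$coords[2],
    sources = paste(e$source_esus, collapse = ","),
    source_kinds = paste(e$source_kinds, collapse = ","),
    allochthonous_sources = paste(e$allochthonous_sources, collapse = ","),
    admixed = as.integer(e$admixed),
    homogeneous_evidence = as.integer(e$has_homogeneous_source_evidence),
    collector_flag = as.integer(e$collector_assessment),
    habitat_years = if (is.null(e$habitat_modification_period)) "" else
      paste(e$habitat_modification_period, collapse = "-"),
    stringsAsFactors = FALSE)))
}
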