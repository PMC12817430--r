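#' Classify one population from its evidence record
#'
#' Decision rules fire in priority order on genomic evidence only:
#'
#' * **R1** exactly one source ESU and it is allochthonous ->
#'   `seeded_allochthonous` (even if the population is also admixed:
#'   a single foreign provenance outranks the admixture signal);
#' * **R2** else admixed with at least one allochthonous source ->
#'   `seeded_admixed`;
#' * **R3** else star-cluster (homogeneous seed source) evidence with
#'   all sources autochthonous -> `seeded_autochthonous_homogeneous`;
#' * **R4** else `natural` — in particular, admixture involving only
#'   autochthonous ESUs is treated as natural gene flow, and
#'   populations with only non-genomic evidence stay natural.
#'
#' The non-genomic fields never change the category.
#'
#' @param ev a [population_evidence()].
#' @return `classification_result`: `pop_id`, `category`,
#'   `direct_seeding` (logical), `rationale` (fired rule).
#' @export
classify_population <- function(ev) {
  stopifnot(inherits(ev, "population_evidence"))
  if (!length(ev$source_esus))
    .stopf("population %s: empty source ESU list", ev$pop_id)
  alloch <- length(ev$allochthonous_sources) > 0
  if (length(ev$source_esus) == 1 &&
      ev$source_esus %in% ev$allochthonous_sources) {
    category <- "seeded_allochthonous"; rule <- "R1_single_allochthonous_source"
  } else if (ev$admixed && alloch) {
    category <- "seeded_admixed"; rule <- "R2_admixed_with_allochthonous"
  } else if (ev$has_homogeneous_source_evidence && !alloch) {
    category <- "seeded_autochthonous_homogeneous"
    rule <- "R3_homogeneous_autochthonous_source"
  } else {
    category <- "natural"; rule <- "R4_default_natural"
  }
  structure(list(pop_id = ev$pop_id, category = category,
                 direct_seeding = category != "natural",
                 rationale = rule),
            class = "classification_result")
}

#' Classify a list of populations
#'
#' @param evidence list of [population_evidence()].
#' @return data.frame: `pop_id`, `category`, `direct_seeding`,
#'   `rationale`.
#' @export
classify_populations <- function(evidence) {
  res <- lapply(evidence, classify_population)
  data.frame(pop_id = vapply(res, `[[`, "", "pop_id"),
             category = vapply(res, `[[`, "", "category"),
             direct_seeding = vapply(res, `[[`, TRUE, "direct_seeding"),
             rationale = vapply(res, `[[`, "", "rationale"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarise seeding classifications
#'
#' Counts and percentages (one decimal, round half away from zero) of
#' seeded populations overall and per category, of populations with
#' any allochthonous seed material, of the two non-genomic evidence
#' lines, and the genomic-minus-collector detection difference. Years
#' since habitat modification are reported under the start-, end- and
#' midpoint-year conventions because the underlying records are year
#' ranges.
#'
#' @param results data.frame from [classify_populations()].
#' @param evidence matching list of [population_evidence()].
#' @param sampling_year reference year for "years since modification".
#' @return a `seeding_summary` list.
#' @export
summarize_seeding <- function(results, evidence, sampling_year = 2021) {
  if (anyDuplicated(results$pop_id)) .stopf("duplicate pop_id in results")
  n <- nrow(results)
  pct <- function(k) round_half_away(100 * k / n, 1)
  n_seeded <- sum(results$direct_seeding)
  by_cat <- table(factor(results$category,
                         levels = c("natural", "seeded_allochthonous",
                                    "seeded_admixed",
                                    "seeded_autochthonous_homogeneous")))
  ev <- evidence[results$pop_id]
  n_alloch_any <- sum(vapply(ev, function(e)
    length(e$allochthonous_sources) > 0, TRUE))
  n_collector <- sum(vapply(ev, `[[`, TRUE, "collector_assessment"))
  hab <- Filter(Negate(is.null),
                lapply(ev, `[[`, "habitat_modification_period"))
  yrs_since <- function(pickr) if (length(hab))
    mean(vapply(hab, function(h) sampling_year - pickr(h), 0)) else NA_real_
  structure(list(
    n_populations = n,
    n_seeded = n_seeded, pct_seeded = pct(n_seeded),
    n_natural = as.integer(by_cat[["natural"]]),
    pct_natural = pct(by_cat[["natural"]]),
    n_allochthonous = as.integer(by_cat[["seeded_allochthonous"]]),
    pct_allochthonous = pct(by_cat[["seeded_allochthonous"]]),
    n_admixed_seeded = as.integer(by_cat[["seeded_admixed"]]),
    pct_admixed_seeded = pct(by_cat[["seeded_admixed"]]),
    n_homogeneous_autochthonous =
      as.integer(by_cat[["seeded_autochthonous_homogeneous"]]),
    pct_homogeneous_autochthonous =
      pct(by_cat[["seeded_autochthonous_homogeneous"]]),
    n_allochthonous_material = n_alloch_any,
    pct_allochthonous_material = pct(n_alloch_any),
    n_collector_flagged = n_collector,
    pct_collector_flagged = pct(n_collector),
    n_habitat_modified = length(hab),
    mean_years_since_modification = c(
      start = yrs_since(function(h) h[1]),
      end = yrs_since(function(h) h[2]),
      midpoint = yrs_since(function(h) mean(h))),
    genomic_minus_collector_pct =
      round_half_away(100 * (n_seeded - n_collector) / n, 1)),
    class = "seeding_summary")
}

#' @export
print.seeding_summary <- function(x, ...) {
  cat(sprintf("Seeding summary over %d populations\n", x$n_populations))
  cat(sprintf("  direct-seeded:                 %d (%.1f%%)\n", x$n_seeded, x$pct_seeded))
  cat(sprintf("    allochthonous:               %d (%.1f%%)\n", x$n_allochthonous, x$pct_allochthonous))
  cat(sprintf("    admixed seed sources:        %d (%.1f%%)\n", x$n_admixed_seeded, x$pct_admixed_seeded))
  cat(sprintf("    homogeneous autochthonous:   %d (%.1f%%)\n", x$n_homogeneous_autochthonous, x$pct_homogeneous_autochthonous))
  cat(sprintf("  natural:                       %d (%.1f%%)\n", x$n_natural, x$pct_natural))
  cat(sprintf("  any allochthonous material:    %d (%.1f%%)\n", x$n_allochthonous_material, x$pct_allochthonous_material))
  cat(sprintf("  collector-flagged:             %d (%.1f%%)\n", x$n_collector_flagged, x$pct_collector_flagged))
  cat(sprintf("  habitat modification records:  %d\n", x$n_habitat_modified))
  m <- x$mean_years_since_modification
  if (is.finite(m[1]))
    cat(sprintf("    mean years since modification (start/end/midpoint): %.1f / %.1f / %.1f\n",
                m[1], m[2], m[3]))
  cat(sprintf("  genomic - collector:           %.1f%%\n", x$genomic_minus_collector_pct))
  invisible(x)
}

# key-value serialisation used by the pipeline
write_summary <- function(x, path) {
  m <- x$mean_years_since_modification
  kv <- c(n_populations = x$n_populations,
          n_seeded = x$n_seeded, pct_seeded = x$pct_seeded,
          n_natural = x$n_natural, pct_natural = x$pct_natural,
          n_allochthonous = x$n_allochthonous,
          pct_allochthonous = x$pct_allochthonous,
          n_admixed_seeded = x$n_admixed_seeded,
          pct_admixed_seeded = x$pct_admixed_seeded,
          n_homogeneous_autochthonous = x$n_homogeneous_autochthonous,
          pct_homogeneous_autochthonous = x$pct_homogeneous_autochthonous,
          n_allochthonous_material = x$n_allochthonous_material,
          pct_allochthonous_material = x$pct_allochthonous_material,
          n_collector_flagged = x$n_collector_flagged,
          pct_collector_flagged = x$pct_collector_flagged,
          n_habitat_modified = x$n_habitat_modified,
          mean_years_since_modification_start = m[["start"]],
          mean_years_since_modification_end = m[["end"]],
          mean_years_since_modification_midpoint = m[["midpoint"]],
          genomic_minus_collector_pct = x$genomic_minus_collector_pct)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0(names(kv), "\t", vapply(kv, format, "")), con)
  invisible(path)
}
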