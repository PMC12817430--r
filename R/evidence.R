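#' Per-population evidence record
#'
#' One record per population collecting everything the decision rules
#' consume: contributing source ESUs and how they contribute
#' (`homogeneous` assignment vs `admixture_component`), whether the
#' population carries star-cluster (shared homogeneous seed source)
#' evidence, whether at least one individual is admixed, and which
#' sources fail the range (allochthony) test. The two non-genomic
#' fields (`collector_assessment`, `habitat_modification_period`) are
#' carried for comparison only and never influence classification.
#'
#' @param pop_id label.
#' @param coords `c(lat, lon)`.
#' @param source_esus character vector of contributing ESUs.
#' @param source_kinds `"homogeneous"` or `"admixture_component"`, one
#'   per source.
#' @param has_homogeneous_source_evidence logical.
#' @param admixed logical: >= 1 individual above the admixture
#'   threshold.
#' @param allochthonous_sources subset of `source_esus` failing the
#'   range test.
#' @param collector_assessment logical (non-genomic).
#' @param habitat_modification_period optional `c(start, end)` years
#'   (non-genomic), or `NULL`.
#' @return a `population_evidence` list.
#' @export
population_evidence <- function(pop_id, coords = c(NA_real_, NA_real_),
                                source_esus, source_kinds = NULL,
                                has_homogeneous_source_evidence = FALSE,
                                admixed = FALSE,
                                allochthonous_sources = character(),
                                collector_assessment = FALSE,
                                habitat_modification_period = NULL) {
  source_esus <- as.character(source_esus)
  if (is.null(source_kinds))
    source_kinds <- rep(if (admixed) "admixture_component" else "homogeneous",
                        length(source_esus))
  if (length(source_kinds) != length(source_esus))
    .stopf("population %s: source_kinds length mismatch", pop_id)
  if (length(setdiff(allochthonous_sources, source_esus)))
    .stopf("population %s: allochthonous_sources must be a subset of source_esus",
           pop_id)
  structure(list(pop_id = as.character(pop_id), coords = as.numeric(coords),
                 source_esus = source_esus, source_kinds = source_kinds,
                 has_homogeneous_source_evidence =
                   isTRUE(has_homogeneous_source_evidence),
                 admixed = isTRUE(admixed),
                 allochthonous_sources = as.character(allochthonous_sources),
                 collector_assessment = isTRUE(collector_assessment),
                 habitat_modification_period = habitat_modification_period),
            class = "population_evidence")
}

#' Build per-population evidence from upstream results
#'
#' Merges (i) per-individual ESU assignments with admixture flags
#' (individual source components are the ESUs with ancestry at or
#' above `tau` for admixed individuals, the assigned ESU otherwise),
#' (ii) the homogeneous-source (star-cluster) report, and (iii) the
#' allochthony test of every contributing ESU, into one
#' [population_evidence()] record per population.
#'
#' @param assignments data.frame from [assign_esu()].
#' @param metadata data.frame with `individual_id`, `pop_id`,
#'   `latitude`, `longitude` (optional `collector_assessment`,
#'   `habitat_start`, `habitat_end`).
#' @param source_report a [detect_homogeneous_source()] result (or
#'   `NULL`).
#' @param catalog an [esu_catalog()].
#' @param Q ancestry matrix with ESU column names (needed to resolve
#'   the components of admixed individuals).
#' @param tau admixture threshold.
#' @param threshold_km allochthony distance threshold.
#' @return list of [population_evidence()] records, one per population.
#' @export
build_evidence <- function(assignments, metadata, source_report, catalog,
                           Q = NULL, tau = 0.10, threshold_km = 100) {
  miss <- setdiff(assignments$individual_id, metadata$individual_id)
  if (length(miss))
    .stopf("individual %s has no population mapping", miss[1])
  meta <- metadata[match(assignments$individual_id, metadata$individual_id), ]
  flagged <- if (is.null(source_report)) character(0) else source_report$flagged_pops
  out <- list()
  for (pop in unique(meta$pop_id)) {
    rows <- which(meta$pop_id == pop)
    coords <- c(meta$latitude[rows[1]], meta$longitude[rows[1]])
    src <- character(0); kind <- character(0)
    for (r in rows) {
      if (assignments$admixed[r] && !is.null(Q)) {
        comp <- colnames(Q)[Q[assignments$individual_id[r], ] >= tau]
        src <- c(src, comp)
        kind <- c(kind, rep("admixture_component", length(comp)))
      } else {
        src <- c(src, assignments$esu[r])
        kind <- c(kind, "homogeneous")
      }
    }
    keep <- !duplicated(src)
    src <- src[keep]; kind <- kind[keep]
    alloch <- src[vapply(src, function(e)
      allochthony_test(coords, e, catalog, threshold_km) == "allochthonous",
      TRUE)]
    mrow <- which(metadata$pop_id == pop)[1]
    out[[pop]] <- population_evidence(
      pop_id = pop, coords = coords, source_esus = src, source_kinds = kind,
      has_homogeneous_source_evidence = pop %in% flagged,
      admixed = any(assignments$admixed[rows]),
      allochthonous_sources = alloch,
      collector_assessment =
        isTRUE(metadata$collector_assessment[mrow]),
      habitat_modification_period =
        if (!is.null(metadata$habitat_start) &&
            is.finite(metadata$habitat_start[mrow]))
          c(metadata$habitat_start[mrow], metadata$habitat_end[mrow]))
  }
  out
}

#' Load the packaged evidence fixture
#'
#' Reads a tab-separated encoding of per-population seeding evidence
#' (the package ships, under `inst/extdata`, a transcription of the
#' published Swiss survey summary: 31 populations, 17 of which carry
#' at least one line of evidence; coordinates in that file are
#' synthetic placeholders, the published table prints none) together
#' with the regional ESU catalog.
#'
#' Schema (one row per population): `pop_id`, `lat`, `lon`, `sources`
#' (comma list), `source_kinds` (comma list, same length),
#' `allochthonous_sources` (comma list), `admixed` (0/1),
#' `homogeneous_evidence` (0/1), `collector_flag` (0/1),
#' `habitat_years` (`start-end`, a single year, or empty).
#'
#' @param path evidence TSV; defaults to the packaged fixture.
#' @param catalog_path catalog TSV (`esu`, `pop_id`, `lat`, `lon`;
#'   empty `pop_id` = ESU present without natural reference
#'   populations); defaults to the packaged catalog.
#' @return list with `evidence` (list of [population_evidence()]) and
#'   `catalog` (an [esu_catalog()]).
#' @export
load_evidence_fixture <- function(path = NULL, catalog_path = NULL) {
  path <- path %||% system.file("extdata", "table2_evidence.tsv",
                                package = "seedtrace", mustWork = TRUE)
  catalog_path <- catalog_path %||% system.file("extdata", "esu_catalog.tsv",
                                                package = "seedtrace",
                                                mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#",
                           colClasses = c(pop_id = "character",
                                          habitat_years = "character"))
  need <- c("pop_id", "lat", "lon", "sources", "source_kinds",
            "allochthonous_sources", "admixed", "homogeneous_evidence",
            "collector_flag", "habitat_years")
  if (!all(need %in% names(tab)))
    .stopf("schema error in %s: missing column(s) %s", path,
           paste(setdiff(need, names(tab)), collapse = ", "))
  split_list <- function(x) if (is.na(x) || !nzchar(x)) character(0)
    else trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  evidence <- lapply(seq_len(nrow(tab)), function(r) {
    row <- tab[r, ]
    src <- split_list(row$sources)
    kinds <- split_list(row$source_kinds)
    if (length(kinds) != length(src))
      .stopf("schema error in %s, line %d: %d sources but %d kinds",
             path, r + 1L, length(src), length(kinds))
    hab <- NULL
    if (!is.na(row$habitat_years) && nzchar(row$habitat_years)) {
      yrs <- as.integer(strsplit(row$habitat_years, "-", fixed = TRUE)[[1]])
      if (anyNA(yrs)) .stopf("schema error in %s, line %d: bad habitat_years",
                             path, r + 1L)
      hab <- c(yrs[1], yrs[length(yrs)])
    }
    population_evidence(
      pop_id = row$pop_id, coords = c(row$lat, row$lon),
      source_esus = src, source_kinds = kinds,
      has_homogeneous_source_evidence = row$homogeneous_evidence == 1,
      admixed = row$admixed == 1,
      allochthonous_sources = split_list(row$allochthonous_sources),
      collector_assessment = row$collector_flag == 1,
      habitat_modification_period = hab)
  })
  names(evidence) <- tab$pop_id
  if (anyDuplicated(tab$pop_id))
    .stopf("schema error in %s: duplicate pop_id", path)
  cat_tab <- utils::read.delim(catalog_path, sep = "\t",
                               stringsAsFactors = FALSE, comment.char = "#",
                               colClasses = c(pop_id = "character"))
  list(evidence = evidence, catalog = esu_catalog(cat_tab))
}
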