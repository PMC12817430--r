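#' Nearest-neighbour mixing index of populations within a group
#'
#' For each population of the candidate group, the index is the
#' fraction of its individuals whose nearest neighbour (by the
#' dissimilarity matrix, among all individuals belonging to the group's
#' populations, excluding self) lies in a *different* population of the
#' group. Populations sown from one homogeneous seed lot mix freely
#' (index near the between/total ratio); distinct natural populations
#' keep their individuals together (index near 0). Distance ties are
#' broken deterministically by the smallest individual index.
#'
#' @param D individuals x individuals dissimilarity matrix (labelled).
#' @param pop_labels population label per individual (aligned with the
#'   rows of `D`, or named by individual id).
#' @param group character vector of population ids forming the
#'   candidate group.
#' @return named numeric vector, one index per population (`NA` for
#'   singleton populations, which are excluded from group decisions).
#' @export
population_mixing_index <- function(D, pop_labels, group) {
  ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
  pop_labels <- .align_labels(pop_labels, ids, "pop_labels")
  sel <- which(pop_labels %in% group)
  if (length(sel) < 2) .stopf("mixing index needs >= 2 individuals in group")
  Dg <- D[sel, sel, drop = FALSE]
  pg <- pop_labels[sel]
  nn_other <- vapply(seq_along(sel), function(i) {
    dr <- Dg[i, ]; dr[i] <- Inf
    j <- which.min(dr)            # first minimum = smallest index tie-break
    pg[j] != pg[i]
  }, TRUE)
  idx <- tapply(nn_other, pg, mean)
  counts <- table(pg)
  idx[names(counts)[counts < 2]] <- NA_real_
  out <- stats::setNames(as.numeric(idx[group]), group)
  out
}

#' Detect populations sharing a homogeneous seed source
#'
#' Formalises the visual "star-shaped cluster" criterion: within each
#' group of populations assigned to the same ESU, a candidate set is
#' flagged as sharing one homogeneous seed source when (a) every
#' pairwise population F_ST within the set is below `theta_fst` and
#' (b) the mean nearest-neighbour mixing index across the set is at
#' least `theta_mix`. Candidate sets grow greedily from the
#' lowest-F_ST pair; a population (natural reference populations
#' included) is only absorbed while all its pairwise F_ST values to
#' the set stay below `theta_fst`. After a set is flagged its
#' populations are removed and the search repeats, so several seed
#' sources per ESU can be reported.
#'
#' @param G a [genotype_matrix()].
#' @param D dissimilarity matrix from [ibs_dissimilarity()].
#' @param pop_labels population label per individual.
#' @param esu_of_pop named character vector mapping each population to
#'   its assigned ESU.
#' @param natural_pops character vector of populations known natural
#'   (reported in the output; the F_ST guard is what protects them).
#' @param theta_fst F_ST ceiling for "same seed lot" (default 0.02).
#' @param theta_mix mixing-index floor (default 0.5).
#' @param estimator F_ST estimator, see [pairwise_fst()].
#' @return `source_group_report`: list with `groups` (list of flagged
#'   candidate sets: populations, per-population mixing index, mean
#'   mixing, max within-set F_ST, esu, flagged) and `table` (one row
#'   per candidate set) plus `flagged_pops`.
#' @export
detect_homogeneous_source <- function(G, D, pop_labels, esu_of_pop,
                                      natural_pops = character(),
                                      theta_fst = 0.02, theta_mix = 0.5,
                                      estimator = "weir_cockerham") {
  ids <- G$individual_ids
  pop_labels <- .align_labels(pop_labels, ids, "pop_labels")
  sizes <- table(pop_labels)
  groups_out <- list()
  for (esu in unique(esu_of_pop)) {
    pops <- names(esu_of_pop)[esu_of_pop == esu]
    pops <- pops[pops %in% names(sizes)[sizes >= 2]]
    if (length(pops) < 2) next
    sel <- pop_labels %in% pops
    fst <- pairwise_fst(G$dosages[sel, , drop = FALSE], pop_labels[sel],
                        estimator = estimator)
    remaining <- pops
    repeat {
      if (length(remaining) < 2) break
      fr <- fst[remaining, remaining, drop = FALSE]
      off <- fr; diag(off) <- Inf
      if (min(off) >= theta_fst) break
      best <- which(off == min(off), arr.ind = TRUE)[1, ]
      set <- remaining[sort(best)]
      repeat {
        cand <- setdiff(remaining, set)
        if (!length(cand)) break
        worst <- vapply(cand, function(p) max(fst[p, set]), 0)
        if (min(worst) >= theta_fst) break
        set <- c(set, cand[which.min(worst)])
      }
      mix <- population_mixing_index(D, pop_labels, set)
      mean_mix <- mean(mix, na.rm = TRUE)
      flagged <- length(set) >= 2 && is.finite(mean_mix) && mean_mix >= theta_mix
      groups_out[[length(groups_out) + 1L]] <- list(
        esu = esu, populations = set, mixing_index = mix,
        mean_mixing = mean_mix,
        max_within_fst = max(fst[set, set][upper.tri(diag(length(set)))]),
        natural_members = intersect(set, natural_pops),
        flagged = flagged)
      remaining <- setdiff(remaining, set)
    }
  }
  tab <- if (length(groups_out)) {
    do.call(rbind, lapply(groups_out, function(g)
      data.frame(esu = g$esu,
                 populations = paste(g$populations, collapse = ","),
                 n_populations = length(g$populations),
                 mean_mixing = g$mean_mixing,
                 max_within_fst = g$max_within_fst,
                 flagged = g$flagged, stringsAsFactors = FALSE)))
  } else {
    data.frame(esu = character(0), populations = character(0),
               n_populations = integer(0), mean_mixing = numeric(0),
               max_within_fst = numeric(0), flagged = logical(0))
  }
  flagged_pops <- unlist(lapply(groups_out,
                                function(g) if (g$flagged) g$populations))
  structure(list(groups = groups_out, table = tab,
                 flagged_pops = flagged_pops %||% character(0),
                 theta_fst = theta_fst, theta_mix = theta_mix),
            class = "source_group_report")
}

#' @export
print.source_group_report <- function(x, ...) {
  cat(sprintf("source_group_report: %d candidate set(s), %d flagged\n",
              length(x$groups), sum(x$table$flagged)))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}
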