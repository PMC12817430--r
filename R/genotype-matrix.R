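#' Genotype matrix container
#'
#' The central data structure of the pipeline: a matrix of alt-allele
#' dosages (0, 1, 2 or `NA` for missing) for diploid individuals at
#' biallelic SNPs, together with locus coordinates, optional per-site
#' numeric annotations and optional per-genotype sequencing depth.
#' Loci are kept sorted by scaffold then position; positions must be
#' strictly increasing within a scaffold.
#'
#' @param dosages integer matrix, individuals x loci, values in
#'   `{0, 1, 2, NA}`.
#' @param individual_ids character vector of row labels.
#' @param loci data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single bases).
#' @param site_annotations optional data.frame of per-site numeric
#'   fields (e.g. `AB`, `ABHOM`, `QD`, `MQR`), one row per locus.
#' @param depth optional integer matrix of per-genotype read depth,
#'   same dimensions as `dosages`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, individual_ids = rownames(dosages),
                            loci, site_annotations = NULL, depth = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  n <- nrow(dosages); j <- ncol(dosages)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  if (length(individual_ids) != n)
    .stopf("individual_ids length %d != %d rows", length(individual_ids), n)
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) .stopf("dosages must be 0, 1, 2 or NA")
  loci <- as.data.frame(loci)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(loci)))
    .stopf("loci must have columns %s", paste(need, collapse = ", "))
  if (nrow(loci) != j) .stopf("loci rows %d != %d dosage columns", nrow(loci), j)
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)

  ord <- order(loci$chrom, loci$pos)
  if (is.unsorted(ord) || any(ord != seq_len(j))) {
    loci <- loci[ord, , drop = FALSE]
    dosages <- dosages[, ord, drop = FALSE]
    if (!is.null(site_annotations))
      site_annotations <- site_annotations[ord, , drop = FALSE]
    if (!is.null(depth)) depth <- depth[, ord, drop = FALSE]
  }
  dup <- duplicated(paste(loci$chrom, loci$pos))
  if (any(dup)) .stopf("duplicate locus positions (e.g. %s:%d)",
                       loci$chrom[dup][1], loci$pos[dup][1])
  if (!is.null(site_annotations)) {
    site_annotations <- as.data.frame(site_annotations)
    if (nrow(site_annotations) != j)
      .stopf("site_annotations rows != number of loci")
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!all(dim(depth) == dim(dosages)))
      .stopf("depth dimensions differ from dosages")
  }
  rownames(dosages) <- individual_ids
  rownames(loci) <- NULL
  structure(list(dosages = dosages, individual_ids = individual_ids,
                 loci = loci, site_annotations = site_annotations,
                 depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%d scaffolds), %.1f%% missing\n",
              n_individuals(x), n_loci(x), length(unique(x$loci$chrom)),
              100 * mean(is.na(x$dosages))))
  if (!is.null(x$site_annotations))
    cat("  site annotations:", paste(names(x$site_annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals / loci
#' @param G a [genotype_matrix()].
#' @return integer count.
#' @export
n_individuals <- function(G) nrow(G$dosages)

#' @rdname n_individuals
#' @export
n_loci <- function(G) ncol(G$dosages)

# internal subset keeping all slots consistent
subset_genotypes <- function(G, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(n_individuals(G))
  if (is.null(j)) j <- seq_len(n_loci(G))
  genotype_matrix(G$dosages[i, j, drop = FALSE],
                  G$individual_ids[i],
                  G$loci[j, , drop = FALSE],
                  if (!is.null(G$site_annotations)) G$site_annotations[j, , drop = FALSE],
                  if (!is.null(G$depth)) G$depth[i, j, drop = FALSE])
}
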