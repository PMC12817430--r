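#' Genotyping error rates from technical replicates
#'
#' Each pair of replicate genotype vectors is compared at co-called
#' sites (both calls non-missing). The global rate is the pooled
#' discordance percentage. Class-conditional rates condition on the
#' genotype class (homozygous / heterozygous) of one replicate; because
#' the conditioning member is arbitrary, both orderings are computed
#' and averaged, which makes the estimate symmetric in pair order and
#' reproduces the homozygous << heterozygous asymmetry expected from
#' allele dropout.
#'
#' @param G a [genotype_matrix()] holding the original calls, or a
#'   plain list of pairs (see `pairs`).
#' @param replicates a [genotype_matrix()] holding replicate calls over
#'   the same loci, or `NULL` when `G` is a list of pairs.
#' @param pairs data.frame with columns `id`, `replicate_id` naming the
#'   paired individuals; alternatively, when `G` is a list, each list
#'   element is `list(a = <dosage vector>, b = <dosage vector>)`.
#' @return an `error_rates` list: `global`, `homozygous`,
#'   `heterozygous` (percent), `n_pairs`, `n_sites_compared`.
#' @export
replicate_error_rates <- function(G, replicates = NULL, pairs = NULL) {
  if (inherits(G, "genotype_matrix")) {
    stopifnot(inherits(replicates, "genotype_matrix"), !is.null(pairs))
    ka <- paste(G$loci$chrom, G$loci$pos)
    kb <- paste(replicates$loci$chrom, replicates$loci$pos)
    shared <- intersect(ka, kb)
    if (!length(shared)) .stopf("undefined rate: replicate loci do not overlap")
    ia <- match(shared, ka); ib <- match(shared, kb)
    plist <- lapply(seq_len(nrow(pairs)), function(r)
      list(a = G$dosages[match(pairs$id[r], G$individual_ids), ia],
           b = replicates$dosages[match(pairs$replicate_id[r],
                                        replicates$individual_ids), ib]))
  } else plist <- G

  n_co <- 0L; n_disc <- 0L
  hom_n <- het_n <- hom_d <- het_d <- c(0L, 0L)   # per ordering
  for (pr in plist) {
    a <- pr$a; b <- pr$b
    if (length(a) != length(b)) .stopf("pair members must share loci")
    co <- !is.na(a) & !is.na(b)
    a <- a[co]; b <- b[co]
    disc <- a != b
    n_co <- n_co + length(a); n_disc <- n_disc + sum(disc)
    for (o in 1:2) {
      first <- if (o == 1) a else b
      hom <- first != 1L
      hom_n[o] <- hom_n[o] + sum(hom);  hom_d[o] <- hom_d[o] + sum(disc[hom])
      het_n[o] <- het_n[o] + sum(!hom); het_d[o] <- het_d[o] + sum(disc[!hom])
    }
  }
  if (n_co == 0) .stopf("undefined rate: zero co-called sites")
  rate <- function(d, n) if (n > 0) 100 * d / n else NA_real_
  both <- function(d, n) {           # orderings with an empty class drop out
    r <- c(rate(d[1], n[1]), rate(d[2], n[2]))
    if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
  }
  structure(list(
    global = 100 * n_disc / n_co,
    homozygous = both(hom_d, hom_n),
    heterozygous = both(het_d, het_n),
    n_pairs = length(plist), n_sites_compared = n_co),
    class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf(paste0("Genotyping error rates over %d pair(s), %d co-called sites\n",
                     "  global:       %.2f%%\n  homozygous:   %.2f%%\n",
                     "  heterozygous: %.2f%%\n"),
              x$n_pairs, x$n_sites_compared, x$global, x$homozygous,
              x$heterozygous))
  invisible(x)
}
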