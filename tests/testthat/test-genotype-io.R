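# VCF reading/writing, filter cascade, thinning, replicate error rates

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

vcf_header <- function(samples = c("s1", "s2")) c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", samples), collapse = "\t"))

test_that("read_vcf parses GT, drops non-SNPs, maps ./. to missing", {
  f <- write_lines_tmp(c(vcf_header(), paste(
    c("chr1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/0\t0/0",
      "chr1\t200\t.\tA\tC\t.\t.\t.\tGT\t0/1\t./.",
      "chr1\t300\t.\tG\tA,T\t.\t.\t.\tGT\t0/1\t0/0",   # multi-allelic
      "chr1\t400\t.\tGA\tG\t.\t.\t.\tGT\t0/1\t0/0",    # indel
      "chr1\t500\t.\tC\tG\t.\t.\t.\tGT\t1/1\t1|0"))))
  expect_message(G <- read_vcf(f), "excluded 2")
  expect_equal(attr(G, "excluded"), 2L)
  expect_equal(n_loci(G), 3)
  expect_equal(unname(G$dosages["s1", ]), c(0L, 1L, 2L))
  expect_equal(unname(G$dosages["s2", ]), c(0L, NA_integer_, 1L))
})

test_that("read_vcf reports malformed lines by number", {
  f <- write_lines_tmp(c(vcf_header(),
                         "chr1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/0\t0/0",
                         "chr1\t200\t.\tA\tT\t.\t.\t.\tGT\t0/0"))
  expect_error(read_vcf(f), "line 5")
  expect_error(read_vcf(tempfile()), "no such file")
})

test_that("write/read round-trip is exact on dosages, loci and ids", {
  set.seed(9)
  scn <- generate_scenario(demo_scenario_config(rng_seed = 9, n_loci = 120,
                                                n_per_pop = 2))
  G <- scn$genotypes
  f <- tempfile(fileext = ".vcf")
  write_vcf(G, f)
  G2 <- read_vcf(f, quiet = TRUE)
  expect_identical(unname(G2$dosages), unname(G$dosages))
  expect_equal(G2$loci, G$loci)
  expect_identical(G2$individual_ids, G$individual_ids)
  expect_identical(unname(G2$depth), unname(G$depth))
  expect_equal(G2$site_annotations$AB, G$site_annotations$AB, tolerance = 1e-8)

  # 1000-locus random matrix property round-trip
  d <- matrix(sample(c(0:2, NA), 5 * 1000, replace = TRUE), 5, 1000)
  Gr <- toy_genotypes(d, pos = sort(sample.int(1e7, 1000)))
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(Gr, f2)
  expect_identical(unname(read_vcf(f2)$dosages), unname(Gr$dosages))

  # empty matrix: header-only VCF still round-trips
  G0 <- toy_genotypes(matrix(integer(0), 2, 0))
  f3 <- tempfile(fileext = ".vcf")
  write_vcf(G0, f3)
  expect_equal(n_loci(read_vcf(f3)), 0)
  expect_identical(read_vcf(f3)$individual_ids, G0$individual_ids)
})

test_that("read_vcf agrees with VariantAnnotation on a written file", {
  scn <- generate_scenario(demo_scenario_config(rng_seed = 3, n_loci = 60,
                                                n_per_pop = 2))
  f <- tempfile(fileext = ".vcf")
  write_vcf(scn$genotypes, f)
  suppressPackageStartupMessages(requireNamespace("VariantAnnotation"))
  v <- VariantAnnotation::readVcf(f)
  gt <- VariantAnnotation::geno(v)$GT          # loci x samples
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA)
  oracle <- t(matrix(map[gt], nrow(gt), ncol(gt)))
  expect_identical(unname(oracle), unname(scn$genotypes$dosages))
})

test_that("site filter cascade matches the brute-force oracle and is idempotent", {
  set.seed(21)
  n <- 12; j <- 200
  d <- matrix(sample(c(0:2, NA), n * j, replace = TRUE,
                     prob = c(.35, .3, .3, .05)), n, j)
  dep <- matrix(rpois(n * j, 8), n, j)
  ann <- data.frame(AB = runif(j), ABHOM = runif(j), QD = runif(j, 0, 2),
                    MQR = runif(j, 0, 2.5))
  G <- toy_genotypes(d, ann = ann, depth = dep)
  cfg <- filter_config()
  res <- apply_site_filters(G, cfg)
  keep <- oracle_site_filters(G, cfg)
  expect_equal(n_loci(res$genotypes), sum(keep))
  expect_equal(res$genotypes$loci$pos, G$loci$pos[keep])
  # per-rule report adds up
  expect_equal(sum(res$report$sites_removed[-1]), j - sum(keep))
  # idempotence
  res2 <- apply_site_filters(res$genotypes, cfg)
  expect_identical(res2$genotypes$dosages, res$genotypes$dosages)
  expect_true(all(res2$report$sites_removed[-1] == 0))
})

test_that("simple threshold cases of the site filters", {
  # monomorphic site removed by MAC >= 1; 20% missing removed at 10%
  d <- rbind(c(0L, 0L, NA), c(0L, 1L, NA), c(0L, 2L, 0L),
             c(0L, 0L, 1L), c(0L, 1L, 0L), c(0L, 2L, 2L),
             c(0L, 0L, 1L), c(0L, 1L, 0L), c(0L, 2L, 2L), c(0L, 0L, 1L))
  G <- toy_genotypes(d)
  res <- suppressWarnings(apply_site_filters(G, filter_config()))
  expect_equal(n_loci(res$genotypes), 1)
  expect_equal(res$genotypes$loci$pos, G$loci$pos[2])
  rep <- res$report
  expect_equal(rep$sites_removed[rep$rule == "minor_allele_count"], 1)
  expect_equal(rep$sites_removed[rep$rule == "site_missingness"], 1)
})

test_that("genotypes below the depth floor are masked before missingness", {
  d <- matrix(rep(0:2, length.out = 50), 10, 5)
  d[1, ] <- 1L
  dep <- matrix(10L, 10, 5)
  dep[2:3, 1] <- 1L        # pushes site 1 to 20% missing
  G <- toy_genotypes(d, depth = dep)
  res <- suppressWarnings(apply_site_filters(G, filter_config()))
  expect_equal(res$report$sites_removed[res$report$rule == "genotype_depth_mask"], 2)
  expect_false(10000L %in% res$genotypes$loci$pos)   # site 1 gone
})

test_that("filter_individuals uses a strict 'more than' threshold", {
  d <- matrix(0L, 3, 100)
  d[1, 1:56] <- NA   # 56% missing: removed
  d[2, 1:55] <- NA   # exactly 55%: retained
  G <- toy_genotypes(d)
  out <- filter_individuals(G, 0.55)
  expect_identical(out$individual_ids, c("ind2", "ind3"))
  expect_identical(filter_individuals(G, 1)$individual_ids, G$individual_ids)
  dall <- matrix(NA_integer_, 2, 10)
  expect_error(filter_individuals(toy_genotypes(dall), 0.5), "empty cohort")
})

test_that("ld_thin keeps the greedy one-per-window set", {
  G <- toy_genotypes(matrix(0:2, 3, 3), pos = c(1L, 4999L, 5001L))
  expect_equal(ld_thin(G, 5000)$loci$pos, c(1L, 5001L))
  # same positions on two scaffolds thin independently
  G2 <- toy_genotypes(matrix(0L, 2, 6),
                      pos = rep(c(1L, 4999L, 5001L), 2),
                      chrom = rep(c("s1", "s2"), each = 3))
  expect_equal(ld_thin(G2, 5000)$loci$pos, rep(c(1L, 5001L), 2))

  set.seed(33)
  pos <- sort(sample.int(5e6, 1e4))
  pos <- pos[!duplicated(pos)]
  G3 <- toy_genotypes(matrix(0L, 2, length(pos)), pos = pos)
  thinned <- ld_thin(G3, 5000)
  expect_equal(thinned$loci$pos, pos[oracle_thin(pos, 5000)])
  expect_gte(min(diff(thinned$loci$pos)), 5000)
  # maximal-greedy: every removed site is < window from the last kept
  # site preceding it
  removed <- setdiff(pos, thinned$loci$pos)
  prev_kept <- vapply(removed, function(p)
    max(thinned$loci$pos[thinned$loci$pos < p]), 0)
  expect_true(all(removed - prev_kept < 5000))
})

test_that("replicate error rates count discordance by class, symmetrically", {
  # identical replicates
  z <- replicate_error_rates(list(list(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L))))
  expect_equal(c(z$global, z$homozygous, z$heterozygous), c(0, 0, 0))
  # 10 co-called sites, one het/hom discordance
  a <- c(1L, rep(0L, 9)); b <- rep(0L, 10)
  e <- replicate_error_rates(list(list(a = a, b = b)))
  expect_equal(e$global, 10)
  # ordering 1 (condition on a): hom 0/9 = 0, het 1/1 = 100
  # ordering 2 (condition on b): hom 1/10 = 10, het has no sites
  expect_equal(e$homozygous, mean(c(0, 10)))
  expect_equal(e$heterozygous, 100)
  # symmetry in pair order
  e2 <- replicate_error_rates(list(list(a = b, b = a)))
  expect_equal(e2$homozygous, e$homozygous)
  expect_equal(e2$heterozygous, e$heterozygous)
  # missing calls never compared; all-missing overlap errors out
  expect_equal(replicate_error_rates(list(list(
    a = c(NA, 0L, 1L), b = c(2L, 0L, NA))))$n_sites_compared, 1)
  expect_error(replicate_error_rates(list(list(a = c(NA, 1L), b = c(0L, NA)))),
               "zero co-called")
})
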