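# synthetic-data generator: frequency models, seed lots, scenarios

test_that("draw_ancestral_freqs honours bounds and sampling moments", {
  set.seed(1)
  expect_equal(draw_ancestral_freqs(5, c(0.5, 0.5)), rep(0.5, 5))
  expect_identical(draw_ancestral_freqs(0), numeric(0))
  x <- draw_ancestral_freqs(1e4, c(0.05, 0.95))
  se <- 0.26 / sqrt(1e4)                      # sd of U(0.05, 0.95)
  expect_lt(abs(mean(x) - 0.5), 3 * se)
  expect_true(all(x >= 0.05 & x <= 0.95))
  expect_error(draw_ancestral_freqs(5, c(0, 0.5)), "invalid config")
  expect_error(draw_ancestral_freqs(5, c(0.2, 1)), "invalid config")
})

test_that("draw_esu_freqs follows the Balding-Nichols moments", {
  set.seed(2)
  p <- rep(0.37, 2000)
  # near-zero drift: frequencies collapse onto the ancestral value
  P0 <- draw_esu_freqs(p, 1e-6)
  expect_lt(max(abs(P0 - 0.37)), 0.01)
  # extreme drift: Beta(0.005, 0.005) puts nearly all mass near 0/1
  P9 <- draw_esu_freqs(rep(0.5, 1e4), 0.99)
  expect_gte(mean(P9 < 0.1 | P9 > 0.9), 0.95)
  # Monte-Carlo mean and variance at moderate drift
  P3 <- draw_esu_freqs(rep(0.4, 1e4), 0.3)
  sd_th <- sqrt(0.3 * 0.4 * 0.6)
  expect_lt(abs(mean(P3) - 0.4), 3 * sd_th / sqrt(1e4))
  expect_lt(abs(stats::var(as.vector(P3)) - 0.3 * 0.4 * 0.6), 0.01)
  expect_error(draw_esu_freqs(p, 1), "invalid config")
  expect_error(draw_esu_freqs(p, 0), "invalid config")
})

test_that("make_seed_lot mixes then bottlenecks", {
  set.seed(3)
  src <- runif(500, 0.1, 0.9)
  expect_lt(max(abs(make_seed_lot(src, 1, 1e6) - src)), 0.005)
  expect_identical(make_seed_lot(rep(0, 10), 1, 25), rep(0, 10))
  expect_identical(make_seed_lot(src, 1, 0), src)       # no bottleneck
  # binomial founder variance at f = 0.5, 2N = 20
  lots <- replicate(1e4, make_seed_lot(0.5, 1, 10))
  v_th <- 0.5 * 0.5 / 20
  se_v <- v_th * sqrt(2 / (1e4 - 1))          # approx SE of a variance
  expect_lt(abs(stats::var(lots) - v_th), 3 * se_v)
  # mixture happens before the bottleneck
  mix <- make_seed_lot(rbind(rep(1, 4), rep(0, 4)), c(0.25, 0.75), 0)
  expect_equal(mix, rep(0.25, 4))
  expect_error(make_seed_lot(rbind(src, src), c(0.5, 0.4), 0), "sum to 1")
})

test_that("simulate_genotypes draws binomial dosages with missingness", {
  set.seed(4)
  G <- simulate_genotypes(matrix(1, 5, 1), matrix(1, 1, 50))
  expect_true(all(G$dosages == 2L))
  G2 <- simulate_genotypes(matrix(1, 10, 1), matrix(0.5, 1, 1000),
                           missing_rate = 0.5)
  p_missing <- mean(is.na(G2$dosages))
  expect_lt(abs(p_missing - 0.5), 3 * sqrt(0.25 / 1e4))
  # HWE heterozygosity 2pq at q = (1, 0), p = 0.5
  G3 <- simulate_genotypes(matrix(c(1, 0), 1, 2), rbind(rep(0.5, 1e4), 0),
                           missing_rate = 0)
  expect_lt(abs(mean(G3$dosages == 1L) - 0.5), 3 * sqrt(0.25 / 1e4))
  expect_error(simulate_genotypes(matrix(1, 2, 1), matrix(0.5, 2, 10)),
               "shape error")
})

test_that("generate_scenario is deterministic and structurally sound", {
  cfg <- demo_scenario_config(rng_seed = 11, n_loci = 300, n_per_pop = 4,
                              replicate_pairs = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_scenario(cfg, d1)
  s2 <- generate_scenario(cfg, d2)
  for (f in c("truth.tsv", "scenario.vcf", "metadata.tsv", "replicates.vcf"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  # truth structure
  expect_equal(ncol(s1$truth$true_Q), 3)
  expect_true(all(abs(rowSums(s1$truth$true_Q) - 1) < 1e-9))
  expect_true(all(s1$truth$true_P >= 0 & s1$truth$true_P <= 1))
  expect_true(all(vapply(s1$truth$pop_freqs,
                         function(f) all(f >= 0 & f <= 1), TRUE)))
  # truth file round-trips
  tr <- read_truth(file.path(d1, "truth.tsv"))
  expect_equal(tr$true_category, s1$truth$true_category)
  expect_equal(unname(tr$true_Q), unname(s1$truth$true_Q))
  # three populations share one seed lot
  expect_length(s1$truth$seed_lot_freqs, 3)   # lot_west + two private lots
})

test_that("zero injected error keeps replicate pairs identical where co-called", {
  cfg <- demo_scenario_config(rng_seed = 5, n_loci = 200, n_per_pop = 3,
                              replicate_pairs = 3, injected_error_rate = 0)
  s <- generate_scenario(cfg)
  for (r in seq_len(nrow(s$replicate_pairs))) {
    a <- s$genotypes$dosages[s$replicate_pairs$id[r], ]
    b <- s$replicates$dosages[s$replicate_pairs$replicate_id[r], ]
    co <- !is.na(a) & !is.na(b)
    expect_identical(a[co], b[co])
  }
})

test_that("seed-lot populations lose expected heterozygosity", {
  # founder bottleneck of 10 reduces E[2f(1-f)] by about 1/(2N) = 5%
  wins <- 0L
  for (rep in 1:20) {
    set.seed(100 + rep)
    esu <- draw_esu_freqs(draw_ancestral_freqs(500), 0.2)
    lot <- make_seed_lot(esu, 1, 10)
    eh <- function(f) mean(2 * f * (1 - f))
    wins <- wins + (eh(lot) < eh(esu))
  }
  expect_equal(wins, 20L)
})

test_that("population and scenario specs validate their invariants", {
  expect_error(population_spec("p", c(46, 8), 5, "natural",
                               c(A = 0.5, B = 0.5)), "one source")
  expect_error(population_spec("p", c(46, 8), 5, "seeded_admixed",
                               c(A = 0.6, B = 0.3)), "sum to 1")
  expect_error(esu_spec("e", 1.2, c(46, 8)), "invalid config")
  expect_error(esu_spec("e", 0.2, c(95, 8)), "invalid config")
  pops <- list(population_spec("p", c(46, 8), 5, "natural", c(X = 1)))
  expect_error(scenario_config(list(esu_spec("A", 0.2, c(46, 8))), pops),
               "unknown ESU")
})
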