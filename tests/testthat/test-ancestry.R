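# admixture model: likelihood, EM, CV, K choice, run alignment

test_that("admixture log-likelihood matches direct summation at K = 1", {
  set.seed(14)
  d <- matrix(sample(c(0:2, NA), 20 * 100, replace = TRUE), 20, 100)
  p <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  oracle <- 0
  for (i in 1:20) for (j in 1:100) if (!is.na(d[i, j]))
    oracle <- oracle + d[i, j] * log(p[j]) + (2 - d[i, j]) * log(1 - p[j])
  ll <- admixture_loglik(d, matrix(1, 20, 1), matrix(p, 1, 100))
  expect_equal(ll, oracle, tolerance = 1e-10)
})

test_that("log-likelihood limits and label-permutation invariance", {
  d <- matrix(2L, 5, 20)
  ll <- admixture_loglik(d, matrix(1, 5, 1), matrix(1 - 1e-6, 1, 20))
  expect_gt(ll, -0.001)                       # ~ 0 at the maximal config
  set.seed(15)
  Q <- .rdirichlet_test(6, 3); P <- matrix(runif(3 * 30), 3, 30)
  d2 <- matrix(sample(0:2, 6 * 30, TRUE), 6, 30)
  perm <- c(3, 1, 2)
  expect_equal(admixture_loglik(d2, Q, P),
               admixture_loglik(d2, Q[, perm], P[perm, ]))
  expect_error(admixture_loglik(d2, Q[, 1:2], P), "shape error")
})

test_that("em_step is a fixed point at the K = 1 MLE and monotone elsewhere", {
  set.seed(16)
  d <- matrix(sample(c(0:2, NA), 15 * 60, replace = TRUE), 15, 60)
  p <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  upd <- em_step(d, matrix(1, 15, 1), matrix(p, 1, 60))
  expect_lt(max(abs(upd$P - p)), 1e-10)
  expect_true(all(upd$Q == 1))

  # monotonicity over 100 steps from a random start
  Q <- .rdirichlet_test(15, 3); P <- matrix(runif(3 * 60, 0.1, 0.9), 3, 60)
  ll <- admixture_loglik(d, Q, P)
  for (it in 1:100) {
    upd <- em_step(d, Q, P); Q <- upd$Q; P <- upd$P
    ll_new <- admixture_loglik(d, Q, P)
    expect_gte(ll_new, ll - 1e-8)
    ll <- ll_new
  }
  expect_true(all(abs(rowSums(Q) - 1) < 1e-9))
  expect_true(all(P > 0 & P < 1))
})

test_that("EM resolves the fully separable two-population case", {
  P <- rbind(rep(1 - 1e-6, 200), rep(1e-6, 200))
  d <- rbind(matrix(2L, 6, 200), matrix(0L, 6, 200))
  Q <- matrix(c(0.6, 0.4), 12, 2, byrow = TRUE)
  for (it in 1:500) {
    upd <- em_step(d, Q, P); Q <- upd$Q      # P free to move too
    P <- upd$P
    if (max(abs(Q[1:6, 1] - 1)) < 1e-3 && max(abs(Q[7:12, 2] - 1)) < 1e-3) break
  }
  expect_lt(max(abs(Q[1:6, 1] - 1)), 1e-3)
  expect_lt(max(abs(Q[7:12, 2] - 1)), 1e-3)
  expect_lte(it, 500)
})

test_that("fit_admixture closed forms: K = 1 and fixed opposite alleles", {
  set.seed(17)
  d <- matrix(sample(0:2, 20 * 80, TRUE), 20, 80)
  fit <- fit_admixture(d, 1, n_restarts = 1, rng_seed = 1)
  expect_true(all(fit$Q == 1))
  pobs <- colSums(d) / (2 * nrow(d))
  expect_lt(max(abs(fit$P - pmin(pmax(pobs, 1e-6), 1 - 1e-6))), 1e-8)

  d2 <- rbind(matrix(0L, 5, 100), matrix(2L, 5, 100))
  fit2 <- fit_admixture(d2, 2, n_restarts = 2, rng_seed = 2)
  Qr <- round(fit2$Q)
  expect_true(all(rowSums(Qr) == 1))
  expect_equal(unname(Qr[1:5, ]), matrix(rep(Qr[1, ], 5), 5, 2, byrow = TRUE))
  expect_true(all(Qr[1:5, 1] != Qr[6:10, 1]))  # the two blocks separate
  expect_error(fit_admixture(d2, 11), "invalid config")
})

test_that("cross-validation is deterministic and structurally sound", {
  set.seed(18)
  d <- matrix(sample(c(0:2, NA), 10 * 50, replace = TRUE), 10, 50)
  cv1 <- cv_error(d, 2, folds = 2, rng_seed = 42, max_iter = 100)
  cv2 <- cv_error(d, 2, folds = 2, rng_seed = 42, max_iter = 100)
  expect_identical(cv1, cv2)
  expect_length(cv1$fold_errors, 2)
  expect_true(all(cv1$fold_errors >= 0))
  expect_error(cv_error(d, 2, folds = 1), "folds")
})

test_that("select_K implements the min and elbow rules", {
  cv <- data.frame(K = 1:5, error = c(10, 4, 3.8, 3.7, 3.65))
  expect_equal(select_K(cv, "elbow"), 2)
  expect_equal(select_K(data.frame(K = 1:3, error = c(5, 1, 4)), "min"), 2)
  expect_equal(select_K(data.frame(K = 2:4, error = c(4, 2, 2)), "min"), 3)
  expect_error(select_K(data.frame(K = 1:2, error = 1:2), "elbow"), ">= 3")
})

test_that("align_runs recovers planted permutations and measures agreement", {
  set.seed(19)
  for (k in 2:5) {
    Q <- .rdirichlet_test(30, k)
    perm <- sample(k)
    al <- align_runs(list(Q, Q[, perm]))
    expect_equal(al$aligned[[2]], Q, ignore_attr = TRUE)
    expect_equal(al$permutations[[2]], order(perm))    # inverse permutation
    expect_equal(max(abs(al$aligned[[2]] - al$aligned[[1]])), 0)
  }
  # K = 2 swap: permutation (2, 1) recovered
  Q <- .rdirichlet_test(10, 2)
  expect_equal(align_runs(list(Q, Q[, 2:1]))$permutations[[2]], c(2L, 1L))
  # ten jittered copies agree fully at threshold 0.05
  base <- .rdirichlet_test(25, 3)
  runs <- lapply(1:10, function(i) {
    x <- abs(base + matrix(rnorm(75, 0, 0.01), 25, 3)); x / rowSums(x)
  })
  expect_equal(align_runs(runs, agree_tol = 0.05)$agreement, 1)
  expect_error(align_runs(list(base, base[, 1:2])), "dimensions")
})

test_that("assign_esu applies the inclusive admixture threshold", {
  Q <- rbind(c(0.95, 0.05), c(0.85, 0.15), c(0.90, 0.10), c(0.5, 0.5))
  colnames(Q) <- c("E1", "E2"); rownames(Q) <- paste0("i", 1:4)
  a <- assign_esu(Q, tau = 0.10)
  expect_equal(a$admixed, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(a$esu, c("E1", "E1", "E1", "E1"))   # tie -> first column
  expect_equal(a$max_foreign_ancestry, c(0.05, 0.15, 0.10, 0.5))
  expect_error(assign_esu(unname(Q[, 1:2])), "labeled")
})
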