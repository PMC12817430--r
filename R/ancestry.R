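#' Binomial admixture log-likelihood
#'
#' The likelihood underlying model-based ancestry estimation: each
#' genotype is `g_ij ~ Binomial(2, f_ij)` with
#' `f_ij = sum_k q_ik p_kj`, giving
#' `l = sum over non-missing (i, j) of g_ij log f_ij +
#' (2 - g_ij) log(1 - f_ij)` (the binomial coefficient, constant in the
#' parameters, is omitted). `P` is clamped to `[1e-6, 1 - 1e-6]`.
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @param Q individuals x K ancestry matrix.
#' @param P K x loci frequency matrix.
#' @return log-likelihood (finite scalar).
#' @export
admixture_loglik <- function(G, Q, P) {
  d <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  Q <- as.matrix(Q); P <- as.matrix(P)
  if (nrow(Q) != nrow(d) || ncol(Q) != nrow(P) || ncol(P) != ncol(d))
    .stopf("shape error: G %dx%d, Q %dx%d, P %dx%d", nrow(d), ncol(d),
           nrow(Q), ncol(Q), nrow(P), ncol(P))
  eps <- 1e-6
  f <- Q %*% pmin(pmax(P, eps), 1 - eps)
  f <- pmin(pmax(f, eps), 1 - eps)
  g0 <- d; g0[is.na(d)] <- 0L
  ll <- g0 * log(f) + (2L - g0) * log1p(-f)
  ll[is.na(d)] <- 0
  sum(ll)
}

# one EM update; inputs/outputs plain matrices, P pre-clamped
.em_step_mats <- function(d, Q, P, eps = 1e-6) {
  pre <- .em_precompute(d)
  .em_update(pre, Q, P, eps)
}

.em_precompute <- function(d) {
  W <- !is.na(d)
  g0 <- d; g0[!W] <- 0L; storage.mode(g0) <- "double"
  g2 <- 2L - d; g2[!W] <- 0L; storage.mode(g2) <- "double"
  list(g0 = g0, g2 = g2, Ji = pmax(rowSums(W), 1L))
}

.em_update <- function(pre, Q, P, eps = 1e-6) {
  f <- Q %*% P
  f[f < eps] <- eps; f[f > 1 - eps] <- 1 - eps
  R1 <- pre$g0 / f          # zero where missing because g0 = 0
  R2 <- pre$g2 / (1 - f)
  Pnum <- P * crossprod(Q, R1)
  Pden <- Pnum + (1 - P) * crossprod(Q, R2)
  Pnew <- Pnum / Pden
  bad <- Pden <= 0
  if (any(bad)) Pnew[bad] <- P[bad]         # zero denominator: keep old
  Pnew[Pnew < eps] <- eps; Pnew[Pnew > 1 - eps] <- 1 - eps
  Qnew <- Q * (R1 %*% t(P) + R2 %*% t(1 - P)) / (2 * pre$Ji)
  Qnew <- Qnew / rowSums(Qnew)
  list(Q = Qnew, P = Pnew)
}

# evaluate the likelihood from precomputed masks (missing entries
# contribute 0 because g0 = g2 = 0 there... except g2 = 2 - NA; masked
# above, both are zeroed)
.em_loglik <- function(pre, Q, P, eps = 1e-6) {
  f <- Q %*% P
  f[f < eps] <- eps; f[f > 1 - eps] <- 1 - eps
  sum(pre$g0 * log(f)) + sum(pre$g2 * log1p(-f))
}

# EM to convergence from a given start; one likelihood pass per iteration
.em_run <- function(pre, Q, P, max_iter, tol, trace = FALSE) {
  prev <- -Inf; it <- 0L; converged <- FALSE
  tr <- if (trace) numeric(0)
  repeat {
    ll <- .em_loglik(pre, Q, P)
    if (trace) tr <- c(tr, ll)
    if (it > 0L && abs(ll - prev) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    prev <- ll
    upd <- .em_update(pre, Q, P)
    Q <- upd$Q; P <- upd$P
    it <- it + 1L
  }
  list(Q = Q, P = P, loglik = ll, n_iter = it, converged = converged,
       loglik_trace = tr)
}

#' Single EM step for the admixture model
#'
#' Classical EM for the binomial admixture likelihood:
#' responsibilities `alpha_ijk = g_ij q_ik p_kj / f_ij` and
#' `beta_ijk = (2 - g_ij) q_ik (1 - p_kj) / (1 - f_ij)` give
#' `p'_kj = sum_i alpha / sum_i (alpha + beta)` and
#' `q'_ik = sum_j (alpha + beta) / (2 J_i)` with `J_i` the individual's
#' non-missing locus count. The update never decreases the
#' log-likelihood and preserves the simplex/box constraints.
#'
#' @inheritParams admixture_loglik
#' @return list with updated `Q` and `P`.
#' @export
em_step <- function(G, Q, P) {
  d <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  Q <- as.matrix(Q); P <- as.matrix(P)
  if (nrow(Q) != nrow(d) || ncol(Q) != nrow(P) || ncol(P) != ncol(d))
    .stopf("shape error in em_step")
  eps <- 1e-6
  .em_step_mats(d, Q, pmin(pmax(P, eps), 1 - eps))
}

#' Fit the admixture model by EM with random restarts
#'
#' Each restart initialises `Q` with symmetric Dirichlet(1) rows and
#' `P` as the observed allele frequency plus Uniform(-0.05, 0.05)
#' jitter (clamped), then iterates EM. The binomial admixture
#' likelihood is multimodal, so restarts follow the short-runs-then-
#' refine strategy common to model-based clustering tools: every
#' restart runs at most `short_iter` EM iterations, and only the
#' restart with the highest likelihood is continued until the
#' improvement drops below `tol` or `max_iter` is reached (set
#' `short_iter = Inf` to refine every restart fully). Deterministic
#' given `rng_seed`.
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @param K number of ancestral clusters (1 <= K <= individuals).
#' @param n_restarts independent random restarts.
#' @param max_iter,tol convergence controls (absolute log-likelihood
#'   change).
#' @param short_iter iteration budget of the exploratory restart phase.
#' @param rng_seed integer seed; `NULL` uses the current RNG state.
#' @return an `ancestry_fit`: `Q`, `P`, `loglik`, `K`, `n_iter`,
#'   `converged`, `rng_seed`, `loglik_trace`, and `restarts` (list of
#'   per-restart `Q` and `loglik`, for run alignment).
#' @export
fit_admixture <- function(G, K, n_restarts = 8, max_iter = 2000, tol = 1e-6,
                          short_iter = 100, rng_seed = NULL) {
  d <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  n <- nrow(d); j <- ncol(d)
  if (K < 1 || K > n) .stopf("invalid config: K must be in [1, %d]", n)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  eps <- 1e-6
  pre <- .em_precompute(d)
  pobs <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  pobs[!is.finite(pobs)] <- 0.5
  best <- NULL; best_r <- 1L; restarts <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    Q <- .rdirichlet1(n, K)
    P <- matrix(rep(pobs, each = K), K, j) +
      matrix(stats::runif(K * j, -0.05, 0.05), K, j)
    P <- pmin(pmax(P, eps), 1 - eps)
    if (K == 1) Q[] <- 1
    run <- .em_run(pre, Q, P, min(short_iter, max_iter), tol, trace = TRUE)
    restarts[[r]] <- list(Q = run$Q, loglik = run$loglik)
    if (is.null(best) || run$loglik > best$loglik) { best <- run; best_r <- r }
  }
  if (!best$converged && best$n_iter < max_iter) {
    more <- .em_run(pre, best$Q, best$P, max_iter - best$n_iter, tol,
                    trace = TRUE)
    more$n_iter <- more$n_iter + best$n_iter
    more$loglik_trace <- c(best$loglik_trace,
                           more$loglik_trace[-1])  # first entry repeats
    best <- more
    restarts[[best_r]] <- list(Q = best$Q, loglik = best$loglik)
  }
  rownames(best$Q) <- rownames(d)
  colnames(best$Q) <- rownames(best$P) <- paste0("K", seq_len(K))
  structure(c(best, list(K = K, rng_seed = rng_seed, restarts = restarts)),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat(sprintf("ancestry_fit: K = %d, loglik = %.2f, %d iteration(s)%s\n",
              x$K, x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Masked cross-validation error for one K
#'
#' Non-missing genotype entries are partitioned at random into `folds`
#' folds; per fold the entries are masked, the model refitted, and each
#' masked dosage predicted as `2 * f_hat`. The fold error is the mean
#' squared deviation `(g - 2 f_hat)^2` over masked entries; the
#' K-level error is the mean over folds. Deterministic given
#' `rng_seed`.
#'
#' @inheritParams fit_admixture
#' @param folds number of folds (>= 2).
#' @param n_restarts,max_iter,tol passed to the per-fold refits.
#' @return list: `K`, `folds`, `fold_errors`, `error`.
#' @export
cv_error <- function(G, K, folds = 10, rng_seed = 1, n_restarts = 1,
                     max_iter = 500, tol = 1e-4) {
  if (folds < 2) .stopf("invalid config: folds >= 2 required")
  d <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  set.seed(rng_seed)
  obs <- which(!is.na(d))
  fold_id <- rep_len(seq_len(folds), length(obs))[sample.int(length(obs))]
  fit_seeds <- sample.int(.Machine$integer.max - 1L, folds)
  fold_errors <- numeric(folds)
  for (f in seq_len(folds)) {
    mask <- obs[fold_id == f]
    if (!length(mask)) .stopf("fold %d has zero masked entries", f)
    dm <- d; dm[mask] <- NA_integer_
    fit <- fit_admixture(dm, K, n_restarts = n_restarts,
                         max_iter = max_iter, tol = tol,
                         rng_seed = fit_seeds[f])
    fhat <- fit$Q %*% fit$P
    fold_errors[f] <- mean((d[mask] - 2 * fhat[mask])^2)
  }
  list(K = K, folds = folds, fold_errors = fold_errors,
       error = mean(fold_errors))
}

#' Choose K from cross-validation errors
#'
#' `rule = "min"` returns the K with smallest error (ties go to the
#' smallest K). `rule = "elbow"` returns the interior K maximising the
#' second difference `e(K-1) - 2 e(K) + e(K+1)` (the sharpest bend of
#' the error curve), requiring at least three K values.
#'
#' @param cv data.frame with columns `K` and `error` (e.g. assembled
#'   from [cv_error()] results).
#' @param rule `"min"` or `"elbow"`.
#' @return selected K (integer).
#' @export
select_K <- function(cv, rule = c("min", "elbow")) {
  rule <- match.arg(rule)
  cv <- cv[order(cv$K), ]
  if (rule == "min") {
    if (nrow(cv) < 1) .stopf("select_K: no K values")
    return(cv$K[which.min(cv$error)])
  }
  if (nrow(cv) < 3) .stopf("select_K: elbow rule needs >= 3 K values")
  e <- cv$error
  sd2 <- e[seq_len(nrow(cv) - 2)] - 2 * e[seq(2, nrow(cv) - 1)] +
    e[seq(3, nrow(cv))]
  cv$K[which.max(sd2) + 1L]
}

# exact minimum-cost column assignment by DP over column subsets
.solve_assignment <- function(cost) {
  k <- nrow(cost)
  nmask <- bitwShiftL(1L, k)
  dp <- rep(Inf, nmask); dp[1] <- 0
  choice <- matrix(NA_integer_, nmask, 1)
  parent <- rep(NA_integer_, nmask)
  for (mask in seq_len(nmask - 1)) {
    row <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) > 0)  # popcount
    for (col in seq_len(k)) {
      bit <- bitwShiftL(1L, col - 1L)
      if (bitwAnd(mask, bit) > 0) {
        prev <- bitwXor(mask, bit)
        cand <- dp[prev + 1] + cost[row, col]
        if (cand < dp[mask + 1]) {
          dp[mask + 1] <- cand
          choice[mask + 1, 1] <- col
          parent[mask + 1] <- prev
        }
      }
    }
  }
  perm <- integer(k)
  mask <- nmask - 1L
  while (mask > 0) {
    row <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) > 0)
    perm[row] <- choice[mask + 1, 1]
    mask <- parent[mask + 1]
  }
  perm
}

#' Align ancestry runs across label permutations
#'
#' EM restarts are identified only up to a permutation of cluster
#' labels. Each run's columns are permuted to minimise the total
#' absolute difference to the reference (first) run via an exact
#' assignment solve. The modal run is the aligned run with the largest
#' number of runs within `agree_tol` mean absolute Q difference of it;
#' the agreement fraction is that share.
#'
#' @param runs list of Q matrices with identical dimensions.
#' @param agree_tol mean-absolute-Q distance defining agreement
#'   (default 0.05).
#' @return list: `aligned` (list of permuted Q), `permutations`,
#'   `modal_run` (index), `distances` (to the modal run), `agreement`.
#' @export
align_runs <- function(runs, agree_tol = 0.05) {
  if (!length(runs)) .stopf("align_runs: empty run list")
  dims <- vapply(runs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    .stopf("align_runs: runs differ in dimensions")
  k <- dims[2, 1]
  ref <- runs[[1]]
  perms <- vector("list", length(runs))
  aligned <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    cost <- matrix(0, k, k)
    for (a in seq_len(k)) for (b in seq_len(k))
      cost[a, b] <- sum(abs(ref[, a] - runs[[r]][, b]))
    perm <- .solve_assignment(cost)
    perms[[r]] <- perm
    aligned[[r]] <- runs[[r]][, perm, drop = FALSE]
    colnames(aligned[[r]]) <- colnames(ref)
  }
  nr <- length(runs)
  dmat <- matrix(0, nr, nr)
  for (a in seq_len(nr)) for (b in seq_len(nr))
    dmat[a, b] <- mean(abs(aligned[[a]] - aligned[[b]]))
  within <- rowSums(dmat <= agree_tol)
  modal <- which.max(within)
  list(aligned = aligned, permutations = perms, modal_run = modal,
       distances = dmat[modal, ], agreement = within[modal] / nr)
}

#' Assign individuals to ESUs with an admixture flag
#'
#' Each individual is assigned to the cluster/ESU with the largest
#' ancestry proportion; `max_foreign_ancestry` is the largest ancestry
#' from any other cluster, and the individual is flagged admixed when
#' that value is greater than or equal to the threshold `tau`
#' (inclusive, default 0.10). Exact argmax ties go to the first column
#' in label order.
#'
#' @param Q individuals x K ancestry matrix with cluster/ESU column
#'   names (or an [fit_admixture()] result).
#' @param esu_labels optional column labels overriding `colnames(Q)`.
#' @param tau admixture threshold in (0, 1).
#' @return data.frame: `individual_id`, `esu`, `max_foreign_ancestry`,
#'   `admixed`.
#' @export
assign_esu <- function(Q, esu_labels = NULL, tau = 0.10) {
  if (inherits(Q, "ancestry_fit")) Q <- Q$Q
  Q <- as.matrix(Q)
  labels <- esu_labels %||% colnames(Q)
  if (is.null(labels) || any(!nzchar(labels)))
    .stopf("assign_esu: Q columns must be labeled with ESU names")
  .check_prob(tau, "tau", open = TRUE)
  top <- apply(Q, 1, which.max)            # first max on ties
  foreign <- vapply(seq_len(nrow(Q)), function(i) max(Q[i, -top[i]], 0), 0)
  data.frame(individual_id = rownames(Q) %||% as.character(seq_len(nrow(Q))),
             esu = labels[top],
             max_foreign_ancestry = foreign,
             admixed = foreign >= tau,
             row.names = NULL, stringsAsFactors = FALSE)
}
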