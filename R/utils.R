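# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Percentages in seeding summaries are printed to one decimal using
#' round-half-away-from-zero (so 48.35 -> 48.4), unlike base [round()]
#' which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_prob <- function(x, name, lo = 0, hi = 1, open = FALSE) {
  bad <- if (open) any(x <= lo | x >= hi) else any(x < lo | x > hi)
  if (any(!is.finite(x)) || bad)
    .stopf("invalid config: %s must lie in %s%g, %g%s", name,
           if (open) "(" else "[", lo, hi, if (open) ")" else "]")
  invisible(x)
}

# rows ~ symmetric Dirichlet(1) on the K-simplex
.rdirichlet1 <- function(n, k) {
  x <- matrix(stats::rexp(n * k), n, k)
  x / rowSums(x)
}
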