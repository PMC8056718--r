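# small in-code fixtures shared across test files

# 2 cells x 2 features, fully observed
toy_dataset <- function() {
  Y <- matrix(c(1, 2, 0, 3), nrow = 2,
              dimnames = list(c("c1", "c2"), c("f1", "f2")))
  n <- matrix(c(3, 4, 2, 5), nrow = 2,
              dimnames = list(c("c1", "c2"), c("f1", "f2")))
  methylation_dataset(Y, n)
}

# fit configuration with a reduced draw count for fast unit tests
quick_fit <- function(seed = 1L, ...) {
  fit_config(seed = seed, n_draws = 1000L, ...)
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# independent quadrature oracle for the beta-binomial pmf: integrates
# Binomial(y | n, theta) against the beta mixing density. The substitution
# theta = qbeta(u, alpha, beta) absorbs the density (and its endpoint
# singularities when alpha or beta < 1) into the quantile map, leaving a
# smooth integrand on [0, 1].
bb_pmf_quadrature <- function(y, n, mu, gamma) {
  lambda <- (1 - gamma) / gamma
  a <- mu * lambda
  b <- (1 - mu) * lambda
  f <- function(u) stats::dbinom(y, n, stats::qbeta(u, a, b))
  for (tol in c(1e-11, 1e-10, 1e-9)) {
    out <- tryCatch(stats::integrate(f, 0, 1, rel.tol = tol,
                                     abs.tol = 1e-300,
                                     subdivisions = 500L)$value,
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  # the extrapolation table can flag roundoff even when the estimate is at
  # machine accuracy; accept it if its own error bound is tight enough
  out <- stats::integrate(f, 0, 1, rel.tol = 1e-9, abs.tol = 1e-300,
                          subdivisions = 500L, stop.on.error = FALSE)
  if (out$abs.error < 1e-9 * max(out$value, 1e-12)) return(out$value)
  stop("quadrature oracle failed to converge")
}
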