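#' Beta shape parameters from mean and overdispersion
#'
#' Converts the (mean, overdispersion) parameterization of the beta-binomial
#' model to standard beta shape parameters. The parameterization is chosen so
#' that `E[theta] = mu` and the intraclass correlation `1/(alpha+beta+1)`
#' equals `gamma`, which makes the beta-binomial variance decompose into a
#' binomial (technical) part and an extra-binomial (biological) part
#' proportional to `gamma` (see [bb_variance()]).
#'
#' @param mu mean methylation, in (0, 1). Vectorized.
#' @param gamma overdispersion (intraclass correlation), in (0, 1). Vectorized.
#' @return list with numeric components `alpha` and `beta`.
#' @examples
#' beta_shape_from_mean_disp(0.5, 0.5) # alpha = beta = 0.5
#' @export
beta_shape_from_mean_disp <- function(mu, gamma) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1))
    stop("mu must lie strictly inside (0, 1)")
  if (any(!is.finite(gamma)) || any(gamma <= 0) || any(gamma >= 1))
    stop("gamma must lie strictly inside (0, 1)")
  lambda <- (1 - gamma) / gamma
  list(alpha = mu * lambda, beta = (1 - mu) * lambda)
}

#' Beta-binomial log likelihood
#'
#' Log pmf of the marginal beta-binomial distribution for methylated-CpG
#' counts, with shapes from [beta_shape_from_mean_disp()]. `mu` and `gamma`
#' are clamped to `[1e-6, 1 - 1e-6]` so the gamma -> 0 limit recovers the
#' binomial log pmf numerically.
#'
#' @param y methylated count(s), `0 <= y <= n`.
#' @param n covered count(s), `n >= 1`.
#' @param mu mean methylation in (0, 1).
#' @param gamma overdispersion in (0, 1); values at the clamp boundary are
#'   permitted and treated as near-binomial.
#' @return numeric vector of log probabilities.
#' @examples
#' bb_loglik(1, 1, 0.3, 0.2) # log(0.3): a single trial depends only on mu
#' @export
bb_loglik <- function(y, n, mu, gamma) {
  m <- max(length(y), length(n), length(mu), length(gamma))
  y <- rep_len(as.numeric(y), m)
  n <- rep_len(as.numeric(n), m)
  mu <- rep_len(as.numeric(mu), m)
  gamma <- rep_len(as.numeric(gamma), m)
  if (any(n < 1)) stop("n must be >= 1")
  if (any(y < 0) || any(y > n)) stop("y must satisfy 0 <= y <= n")
  if (any(y != floor(y)) || any(n != floor(n)))
    stop("y and n must be integer-valued")
  cpp_bb_logpmf(y, n, mu, gamma)
}

#' Beta-binomial variance decomposition
#'
#' Variance of the methylated-CpG count `Y ~ BB(n, mu, gamma)`, split into a
#' binomial sampling ("technical") term `n mu (1-mu)` and the extra-binomial
#' ("biological") term `n mu (1-mu) (n-1) gamma`. With `gamma = 0` the model
#' is binomial; with `gamma = 1` all trials are perfectly correlated and the
#' variance reaches `n^2 mu (1-mu)`.
#'
#' @param n covered count, `n >= 1`. Vectorized.
#' @param mu mean methylation. Vectorized.
#' @param gamma overdispersion. Vectorized.
#' @return data.frame with columns `technical`, `biological`, `total`.
#' @export
bb_variance <- function(n, mu, gamma) {
  if (any(n < 1)) stop("n must be >= 1")
  tech <- n * mu * (1 - mu)
  bio <- tech * (n - 1) * gamma
  data.frame(technical = tech, biological = bio, total = tech + bio)
}

#' Radial basis for the mean-overdispersion trend
#'
#' Defines the design used for the nonlinear regression of logit
#' overdispersion on mean methylation: an intercept plus `L - 1` Gaussian
#' kernels. By default the kernel centers are equally spaced at `l / L` for
#' `l = 1, ..., L-1` (so `L = 4` gives 0.25, 0.5, 0.75) and the bandwidth
#' equals the center spacing.
#'
#' @param L total number of coefficients (intercept + `L - 1` kernels).
#' @param centers optional kernel locations in (0, 1), strictly increasing.
#' @param bandwidth optional positive kernel bandwidth.
#' @return an object of class `rbf_basis`.
#' @export
rbf_basis <- function(L = 4L, centers = NULL, bandwidth = NULL) {
  L <- as.integer(L)
  if (L < 2) stop("L must be at least 2 (intercept plus one kernel)")
  if (is.null(centers)) centers <- seq_len(L - 1) / L
  if (length(centers) != L - 1) stop("need exactly L - 1 centers")
  if (is.unsorted(centers, strictly = TRUE))
    stop("centers must be strictly increasing")
  if (any(centers <= 0) || any(centers >= 1))
    stop("centers must lie in (0, 1)")
  if (is.null(bandwidth))
    bandwidth <- if (L > 2) centers[2] - centers[1] else 1 / L
  if (bandwidth <= 0) stop("bandwidth must be positive")
  structure(list(L = L, centers = as.numeric(centers),
                 bandwidth = as.numeric(bandwidth)),
            class = "rbf_basis")
}

#' Evaluate the radial-basis design matrix
#'
#' @param mu_values vector of mean-methylation values in (0, 1).
#' @param basis an [rbf_basis()].
#' @return numeric matrix, `length(mu_values)` x `L`; column 1 is the
#'   intercept, column `l >= 2` is `exp(-(mu - c_{l-1})^2 / (2 h^2))`.
#' @export
rbf_design <- function(mu_values, basis = rbf_basis()) {
  stopifnot(inherits(basis, "rbf_basis"))
  if (any(mu_values <= 0) || any(mu_values >= 1))
    stop("mu values must lie strictly inside (0, 1)")
  out <- matrix(1, nrow = length(mu_values), ncol = basis$L)
  for (l in seq_len(basis$L - 1)) {
    d <- mu_values - basis$centers[l]
    out[, l + 1] <- exp(-d^2 / (2 * basis$bandwidth^2))
  }
  colnames(out) <- c("intercept", paste0("rbf", seq_len(basis$L - 1)))
  out
}

#' Prior configuration for the hierarchical model
#'
#' Weakly-informative defaults on the logit scale: independent normal priors
#' on every regression coefficient and half-normal priors on the two
#' logit-scale standard deviations.
#'
#' @param w_mu_mean,w_mu_sd location/scale of the normal prior on each
#'   component of the mean-regression coefficients.
#' @param w_gamma_mean,w_gamma_sd same for the trend coefficients.
#' @param s_mu_scale,s_gamma_scale scales of the half-normal priors on the
#'   logit-scale standard deviations.
#' @return an object of class `prior_config`.
#' @export
prior_config <- function(w_mu_mean = 0, w_mu_sd = 2,
                         w_gamma_mean = 0, w_gamma_sd = 2,
                         s_mu_scale = 1, s_gamma_scale = 1) {
  if (w_mu_sd <= 0 || w_gamma_sd <= 0 || s_mu_scale <= 0 || s_gamma_scale <= 0)
    stop("all prior scales must be positive")
  structure(list(w_mu_mean = w_mu_mean, w_mu_sd = w_mu_sd,
                 w_gamma_mean = w_gamma_mean, w_gamma_sd = w_gamma_sd,
                 s_mu_scale = s_mu_scale, s_gamma_scale = s_gamma_scale),
            class = "prior_config")
}
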