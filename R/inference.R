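#' Fit configuration
#'
#' Controls for [fit_model()]. The default `"vb"` method locates the joint
#' posterior mode with L-BFGS (analytic gradients) and draws from the full
#' Gaussian approximation at the mode; `"mcmc"` runs a Metropolis-within-
#' Gibbs sampler initialized at the mode, with proposals shaped by the same
#' Gaussian approximation.
#'
#' @param method `"vb"` (Gaussian approximation, default) or `"mcmc"`.
#' @param max_iter optimizer iteration cap.
#' @param elbo_tol convergence tolerance on the objective improvement
#'   between iterations.
#' @param n_draws number of posterior draws extracted under `"vb"`.
#' @param mcmc_chains,mcmc_warmup,mcmc_iter MCMC chain count, warmup sweeps
#'   and kept sweeps per chain.
#' @param seed integer seed governing draw extraction / sampling.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(method = c("vb", "mcmc"), max_iter = 50000L,
                       elbo_tol = 1e-4, n_draws = 4000L, mcmc_chains = 4L,
                       mcmc_warmup = 500L, mcmc_iter = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (max_iter <= 0 || n_draws <= 0) stop("max_iter and n_draws must be > 0")
  structure(list(method = method, max_iter = as.integer(max_iter),
                 elbo_tol = elbo_tol, n_draws = as.integer(n_draws),
                 mcmc_chains = as.integer(mcmc_chains),
                 mcmc_warmup = as.integer(mcmc_warmup),
                 mcmc_iter = as.integer(mcmc_iter), seed = as.integer(seed)),
            class = "fit_config")
}

# flatten observed entries into the layout the C++ objective expects
assemble_model_data <- function(dataset, priors, basis) {
  Y <- dataset$Y; n <- dataset$n
  J <- ncol(Y)
  yv <- nv <- vector("list", J)
  for (j in seq_len(J)) {
    obs <- which(!is.na(Y[, j]))
    yv[[j]] <- Y[obs, j]
    nv[[j]] <- n[obs, j]
  }
  lens <- vapply(yv, length, integer(1))
  list(yv = unlist(yv, use.names = FALSE),
       nv = unlist(nv, use.names = FALSE),
       fptr = as.integer(c(0, cumsum(lens))),
       X = unname(dataset$X),
       centers = basis$centers, h = basis$bandwidth,
       hyper = c(priors$w_mu_mean, priors$w_mu_sd, priors$w_gamma_mean,
                 priors$w_gamma_sd, priors$s_mu_scale, priors$s_gamma_scale))
}

# starting values in the non-centered parameterization: standardized
# empirical logit means, flat residuals, least-squares w_mu
initial_par <- function(dataset, md, L) {
  rate <- colMeans(dataset$Y / dataset$n, na.rm = TRUE)
  z0 <- qlogis(pmin(pmax(rate, 0.02), 0.98))
  w_mu0 <- tryCatch(qr.solve(md$X, z0), error = function(e)
    c(mean(z0), rep(0, ncol(md$X) - 1)))
  ls_mu0 <- 0
  zeta0 <- (z0 - as.vector(md$X %*% w_mu0)) / exp(ls_mu0)
  c(zeta0, rep(0, ncol(dataset$Y)), w_mu0, c(-2, rep(0, L - 1)), ls_mu0,
    log(0.5))
}

chol_with_ridge <- function(H) {
  ridge <- 0
  for (k in 0:8) {
    R <- tryCatch(chol(H + diag(ridge, nrow(H))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    ridge <- if (ridge == 0) 1e-8 * max(diag(H)) else ridge * 10
  }
  stop("Hessian could not be regularized to positive definite")
}

#' Fit the hierarchical beta-binomial model
#'
#' Jointly infers per-feature mean methylation `mu_j`, overdispersion
#' `gamma_j` and residual overdispersion `epsilon_j`, together with the
#' covariate regression `w_mu`, the mean-overdispersion trend `w_gamma` and
#' the logit-scale standard deviations `s_mu`, `s_gamma`. Inference works on
#' `logit(mu_j)` and `epsilon_j`; `gamma_j` is reconstructed through the
#' trend, so the identity `logit(gamma) = f_gamma(mu; w_gamma) + epsilon`
#' holds exactly in every draw. Missing entries contribute nothing to the
#' likelihood. Identical seed and configuration give identical draws.
#'
#' @param dataset a [methylation_dataset()], typically after [apply_qc()].
#' @param priors a [prior_config()].
#' @param basis an [rbf_basis()].
#' @param config a [fit_config()].
#' @return an object of class `posterior_draws` with draw matrices `mu`,
#'   `gamma`, `epsilon` (draws x features), `w_mu`, `w_gamma`, `s_mu`,
#'   `s_gamma`, the feature ids, basis, covariates and fitting metadata.
#' @export
fit_model <- function(dataset, priors = prior_config(), basis = rbf_basis(),
                      config = fit_config()) {
  validate_dataset(dataset)
  obs_cells <- colSums(!is.na(dataset$Y))
  dropped <- dataset$feature_ids[obs_cells < 2]
  if (length(dropped)) {
    warning(length(dropped),
            " feature(s) observed in < 2 cells dropped before fitting")
    keep <- dataset$feature_ids[obs_cells >= 2]
    dataset <- subset_features(dataset, keep)
  }
  J <- ncol(dataset$Y)
  L <- basis$L
  if (J < L + 1)
    stop("need at least L + 1 = ", L + 1,
         " features to identify the trend regression; got ", J)
  md <- assemble_model_data(dataset, priors, basis)
  P <- ncol(md$X)
  fitted <- if (config$method == "vb") fit_vb(dataset, md, basis, config)
            else fit_mcmc(dataset, md, basis, config)
  fitted$dropped_features <- dropped
  fitted
}

# default fit: Laplace-marginal estimation of the globals (per-feature
# latents integrated out by 2-d Laplace blocks), then Gaussian posterior
# draws from the global curvature and the per-feature conditional Laplace
fit_vb <- function(dataset, md, basis, config) {
  J <- ncol(dataset$Y)
  P <- ncol(md$X)
  L <- basis$L
  G <- P + L + 2
  rate <- colMeans(dataset$Y / dataset$n, na.rm = TRUE)
  z0 <- qlogis(pmin(pmax(rate, 0.02), 0.98))
  w_mu0 <- tryCatch(qr.solve(md$X, z0), error = function(e)
    c(mean(z0), rep(0, P - 1)))
  warm <- cbind(z0, mom_logit_gamma(dataset))
  g0 <- c(w_mu0, -2, rep(0, L - 1), 0, log(0.5))
  hy <- md$hyper
  glob_lp <- function(g) {
    s_mu <- exp(g[P + L + 1]); s_g <- exp(g[P + L + 2])
    sum(-0.5 * ((g[seq_len(P)] - hy[1]) / hy[2])^2) +
      sum(-0.5 * ((g[P + seq_len(L)] - hy[3]) / hy[4])^2) +
      (-0.5 * (s_mu / hy[5])^2 + g[P + L + 1]) +
      (-0.5 * (s_g / hy[6])^2 + g[P + L + 2])
  }
  laplace_pass <- function(g) cpp_feature_laplace(
    g, md$yv, md$nv, md$fptr, md$X, md$centers, md$h, md$hyper, warm)
  fl <- laplace_pass(g0)
  obj <- -(sum(fl[, 6]) + glob_lp(g0))
  if (!is.finite(obj)) stop("non-finite objective at the starting values")
  # EM-style block updates: E-step = per-feature Laplace moments, M-step =
  # closed-form ridge/variance updates; monitored on the exact marginal
  # objective, keeping the best point seen
  g <- g0
  best <- list(g = g0, obj = obj, fl = fl)
  half_normal_var <- function(S, scale2) {
    # argmax of -J log s - S/(2 s^2) - s^2/(2 scale2) + log s over s^2
    scale2 * (-(J - 1) + sqrt((J - 1)^2 + 4 * S / scale2)) / 2
  }
  for (iter in seq_len(min(config$max_iter, 300L))) {
    zhat <- fl[, 1]; that <- fl[, 2]
    vz <- fl[, 3]; czt <- fl[, 4]; vt <- fl[, 5]
    s_mu2 <- exp(2 * g[P + L + 1]); s_g2 <- exp(2 * g[P + L + 2])
    A <- crossprod(md$X) / s_mu2 + diag(1 / hy[2]^2, P)
    w_mu <- solve(A, crossprod(md$X, zhat) / s_mu2 + rep(hy[1] / hy[2]^2, P))
    S_mu <- sum((zhat - md$X %*% w_mu)^2 + vz)
    s_mu2_new <- half_normal_var(S_mu, hy[5]^2)
    mu_hat <- plogis(zhat)
    mu_hat <- pmin(pmax(mu_hat, 1e-6), 1 - 1e-6)
    Gd <- rbf_design(mu_hat, basis)
    Ag <- crossprod(Gd) / s_g2 + diag(1 / hy[4]^2, L)
    w_g <- solve(Ag, crossprod(Gd, that) / s_g2 + rep(hy[3] / hy[4]^2, L))
    fhat <- as.vector(Gd %*% w_g)
    dfdz <- rbf_trend_deriv(mu_hat, w_g, basis) * mu_hat * (1 - mu_hat)
    S_g <- sum((that - fhat)^2 + vt - 2 * dfdz * czt + dfdz^2 * vz)
    s_g2_new <- half_normal_var(S_g, hy[6]^2)
    g_new <- c(as.vector(w_mu), as.vector(w_g), 0.5 * log(s_mu2_new),
               0.5 * log(s_g2_new))
    fl <- laplace_pass(g_new)
    obj_new <- -(sum(fl[, 6]) + glob_lp(g_new))
    if (is.finite(obj_new) && obj_new < best$obj)
      best <- list(g = g_new, obj = obj_new, fl = fl)
    delta <- obj - obj_new
    g <- g_new
    obj <- obj_new
    if (is.finite(delta) && abs(delta) < config$elbo_tol) break
  }
  # short simplex polish of the exact marginal objective around the best
  # point (the EM M-step is approximate, so the fixed point can sit slightly
  # off the optimum)
  fn <- function(gp) {
    flp <- laplace_pass(gp)
    -(sum(flp[, 6]) + glob_lp(gp))
  }
  opt <- optim(best$g, fn, method = "Nelder-Mead",
               control = list(maxit = 300,
                              reltol = config$elbo_tol / max(1, abs(best$obj))))
  if (is.finite(opt$value) && opt$value < best$obj) {
    ghat <- opt$par
    best_obj <- opt$value
  } else {
    ghat <- best$g
    best_obj <- best$obj
  }
  opt <- list(value = best_obj, convergence = 0L,
              counts = c(em = iter, polish = opt$counts[[1]]))
  Hg <- optimHess(ghat, fn)
  fl <- laplace_pass(ghat)
  Rg <- chol_with_ridge((Hg + t(Hg)) / 2)
  D <- config$n_draws
  # 2x2 lower-Cholesky factors of the feature covariances
  a11 <- sqrt(pmax(fl[, 3], 1e-12))
  a21 <- fl[, 4] / a11
  a22 <- sqrt(pmax(fl[, 5] - a21^2, 1e-12))
  draws <- with_preserved_seed(config$seed, {
    gd <- t(ghat + backsolve(Rg, matrix(rnorm(D * G), nrow = G)))
    U1 <- matrix(rnorm(D * J), D, J)
    U2 <- matrix(rnorm(D * J), D, J)
    zd <- rep(fl[, 1], each = D) + U1 * rep(a11, each = D)
    td <- rep(fl[, 2], each = D) + U1 * rep(a21, each = D) +
      U2 * rep(a22, each = D)
    list(gd = gd, zd = zd, td = td)
  })
  w_mu <- draws$gd[, seq_len(P), drop = FALSE]
  w_gamma <- draws$gd[, P + seq_len(L), drop = FALSE]
  mu <- plogis(draws$zd)
  gamma <- plogis(draws$td)
  eps <- qlogis(gamma) - trend_matrix(mu, w_gamma, basis)
  colnames(mu) <- colnames(gamma) <- colnames(eps) <- dataset$feature_ids
  structure(list(
    feature_ids = dataset$feature_ids,
    mu = mu, gamma = gamma, epsilon = eps,
    w_mu = w_mu, w_gamma = w_gamma,
    s_mu = exp(draws$gd[, P + L + 1]), s_gamma = exp(draws$gd[, P + L + 2]),
    basis = basis, X = dataset$X, method = "vb",
    map = ghat, objective = opt$value, convergence = opt$convergence,
    n_obj_evals = opt$counts, mcmc_diag = NULL),
    class = "posterior_draws")
}

# method-of-moments logit overdispersion used as inner-mode warm start
mom_logit_gamma <- function(dataset) {
  vapply(seq_len(ncol(dataset$Y)), function(j) {
    obs <- !is.na(dataset$Y[, j])
    r <- dataset$Y[obs, j] / dataset$n[obs, j]
    m <- min(max(mean(r), 0.02), 0.98)
    v <- if (sum(obs) > 1) var(r) else 0
    vtech <- mean(m * (1 - m) / dataset$n[obs, j])
    g <- (v - vtech) / (m * (1 - m))
    qlogis(min(max(ifelse(is.finite(g), g, 0.1), 0.01), 0.9))
  }, numeric(1))
}

# MCMC fit in the non-centered joint space: initialized at the joint mode,
# with proposal covariances from the joint curvature; the sampler, not the
# mode, determines the reported posterior
fit_mcmc <- function(dataset, md, basis, config) {
  J <- ncol(dataset$Y)
  P <- ncol(md$X)
  L <- basis$L
  par0 <- initial_par(dataset, md, L)
  fn <- function(p) cpp_joint_nlp(p, md$yv, md$nv, md$fptr, md$X, md$centers,
                                  md$h, md$hyper)
  gr <- function(p) cpp_joint_grad(p, md$yv, md$nv, md$fptr, md$X, md$centers,
                                   md$h, md$hyper)
  opt <- tryCatch(
    optim(par0, fn, gr, method = "L-BFGS-B",
          control = list(maxit = config$max_iter, factr = 1e7)),
    error = function(e) stop("initialization diverged: ",
                             conditionMessage(e)))
  par_map <- opt$par
  H <- cpp_joint_hessian(par_map, md$yv, md$nv, md$fptr, md$X, md$centers,
                         md$h, md$hyper)
  gidx <- (2 * J + 1):length(par_map)
  feat_chol <- matrix(0, J, 3)
  for (j in seq_len(J)) {
    Hj <- H[c(j, J + j), c(j, J + j)]
    Cj <- tryCatch(solve(Hj), error = function(e) NULL)
    if (is.null(Cj) || any(!is.finite(Cj)) || any(diag(Cj) <= 0))
      Cj <- diag(c(0.05, 0.05))
    Lj <- tryCatch(t(chol(Cj)), error = function(e) diag(sqrt(abs(diag(Cj)))))
    feat_chol[j, ] <- c(Lj[1, 1], Lj[2, 1], Lj[2, 2])
  }
  Hg <- H[gidx, gidx]
  Cg <- tryCatch(solve(Hg), error = function(e) diag(0.01, length(gidx)))
  Lg <- tryCatch(t(chol((Cg + t(Cg)) / 2)),
                 error = function(e) diag(sqrt(abs(diag(Cg)))))
  n_keep <- min(ceiling(config$n_draws / config$mcmc_chains),
                config$mcmc_iter)
  chains <- with_preserved_seed(config$seed, {
    lapply(seq_len(config$mcmc_chains), function(ch) {
      cpp_mwg(par_map, md$yv, md$nv, md$fptr, md$X, md$centers, md$h,
              md$hyper, feat_chol, Lg, 1.5, 0.8, config$mcmc_warmup,
              n_keep, 1L)
    })
  })
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  zeta <- draws[, seq_len(J), drop = FALSE]
  eta <- draws[, J + seq_len(J), drop = FALSE]
  w_mu <- draws[, 2 * J + seq_len(P), drop = FALSE]
  w_gamma <- draws[, 2 * J + P + seq_len(L), drop = FALSE]
  s_mu <- exp(draws[, 2 * J + P + L + 1])
  s_gamma <- exp(draws[, 2 * J + P + L + 2])
  m_draws <- w_mu %*% t(md$X)
  mu <- plogis(m_draws + s_mu * zeta)
  eps <- s_gamma * eta
  gamma <- plogis(trend_matrix(mu, w_gamma, basis) + eps)
  colnames(mu) <- colnames(gamma) <- colnames(eps) <- dataset$feature_ids
  structure(list(
    feature_ids = dataset$feature_ids,
    mu = mu, gamma = gamma, epsilon = eps,
    w_mu = w_mu, w_gamma = w_gamma, s_mu = s_mu, s_gamma = s_gamma,
    basis = basis, X = dataset$X, method = "mcmc",
    map = par_map, objective = opt$value, convergence = opt$convergence,
    n_obj_evals = opt$counts,
    mcmc_diag = list(
      accept_feature = vapply(chains, `[[`, numeric(1), "accept_feature"),
      accept_global = vapply(chains, `[[`, numeric(1), "accept_global"))),
    class = "posterior_draws")
}

# derivative of the trend f_gamma with respect to mu
rbf_trend_deriv <- function(mu, w_gamma, basis) {
  out <- numeric(length(mu))
  for (l in seq_len(basis$L - 1)) {
    d <- mu - basis$centers[l]
    out <- out + w_gamma[l + 1] * exp(-d^2 / (2 * basis$bandwidth^2)) *
      (-d / basis$bandwidth^2)
  }
  out
}

# f_gamma evaluated at per-draw mu with per-draw coefficients
trend_matrix <- function(mu, w_gamma, basis) {
  out <- matrix(w_gamma[, 1], nrow(mu), ncol(mu))
  for (l in seq_len(basis$L - 1)) {
    g <- exp(-(mu - basis$centers[l])^2 / (2 * basis$bandwidth^2))
    out <- out + w_gamma[, l + 1] * g
  }
  out
}

subset_features <- function(dataset, keep) {
  methylation_dataset(dataset$Y[, keep, drop = FALSE],
                      dataset$n[, keep, drop = FALSE],
                      X = dataset$X[keep, , drop = FALSE],
                      cell_ids = dataset$cell_ids, feature_ids = keep,
                      group = dataset$group)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d draws x %d features (method %s)\n",
              nrow(x$mu), length(x$feature_ids), x$method))
  invisible(x)
}

#' Residual overdispersion draws
#'
#' Recomputes `epsilon = logit(gamma) - f_gamma(mu; w_gamma)` from the
#' stored draws, evaluating the trend at each draw's own `mu` and
#' coefficients. For fits produced by [fit_model()] this reproduces the
#' stored `epsilon` exactly, since `gamma` is constructed through the trend.
#'
#' @param draws a `posterior_draws` object.
#' @return draws x features matrix of residual overdispersion values.
#' @export
residual_overdispersion <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!is.null(draws$parts)) {
    out <- do.call(cbind, lapply(draws$parts, residual_overdispersion))
    return(out[, draws$feature_ids, drop = FALSE])
  }
  qlogis(draws$gamma) - trend_matrix(draws$mu, draws$w_gamma, draws$basis)
}

#' Per-feature posterior summary
#'
#' Posterior medians and standard deviations of `mu`, `gamma` and
#' `epsilon`, with a flag for features whose residual-overdispersion
#' uncertainty is high (posterior sd above 0.5), indicating that coverage is
#' too sparse for reliable variability calls.
#'
#' @param draws a `posterior_draws` object with at least two draws.
#' @return data.frame keyed by `feature_id`.
#' @export
posterior_summary <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (nrow(draws$mu) < 2) stop("need at least 2 draws")
  med <- function(M) apply(M, 2, median)
  sds <- function(M) apply(M, 2, sd)
  out <- data.frame(
    feature_id = draws$feature_ids,
    mu_median = med(draws$mu), mu_sd = sds(draws$mu),
    gamma_median = med(draws$gamma), gamma_sd = sds(draws$gamma),
    epsilon_median = med(draws$epsilon), epsilon_sd = sds(draws$epsilon),
    row.names = NULL)
  out$uncertain_epsilon <- out$epsilon_sd > 0.5
  out
}

#' Combine independent fits over feature partitions
#'
#' Concatenates the per-feature draw matrices of fits run on disjoint
#' feature sets (e.g. one fit per chromosome). Global parameters remain
#' partition-specific and are kept in `$parts`; downstream HVF and
#' differential calls operate on the concatenated per-feature draws.
#'
#' @param fits list of `posterior_draws` objects over disjoint features
#'   with equal draw counts.
#' @return a `posterior_draws` object spanning the union of features.
#' @export
combine_fits <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "posterior_draws")))
  if (length(fits) == 1) return(fits[[1]])
  D <- vapply(fits, function(f) nrow(f$mu), integer(1))
  if (length(unique(D)) != 1) stop("fits must have equal draw counts")
  ids <- unlist(lapply(fits, `[[`, "feature_ids"))
  if (anyDuplicated(ids)) stop("fits must cover disjoint feature sets")
  structure(list(
    feature_ids = ids,
    mu = do.call(cbind, lapply(fits, `[[`, "mu")),
    gamma = do.call(cbind, lapply(fits, `[[`, "gamma")),
    epsilon = do.call(cbind, lapply(fits, `[[`, "epsilon")),
    basis = fits[[1]]$basis, method = fits[[1]]$method,
    parts = fits),
    class = "posterior_draws")
}
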