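#' Simulation configuration
#'
#' Defines the generative conditions for synthetic single-cell methylation
#' data. Defaults mirror the study conditions used throughout the package's
#' benchmarks: 300 features, a per-feature cell-coverage probability and
#' CpG-coverage probability drawn uniformly from (0.4, 0.8), three CpG
#' density regimes (`rich` N = 50, `moderate` N = 15, `poor` N = 8), mean
#' methylation drawn logit-normally from a CpG-density regression with
#' weights (-0.5, -1.5) and sd 1 (the negative density weight reproduces
#' the known negative association between mean methylation and CpG
#' density), and overdispersion drawn logit-normally around the radial-basis
#' trend with weights (-1.2, -0.3, 1.1, -0.9) and sd 0.25.
#'
#' @param J number of features.
#' @param I number of cells.
#' @param density_regime `"rich"`, `"moderate"` or `"poor"`, or a positive
#'   integer N giving the CpG count per feature-cell directly.
#' @param p_range range of the per-feature cell-coverage probability.
#' @param q_range range of the per-feature CpG-coverage probability.
#' @param w_mu mean-regression weights (intercept, CpG density).
#' @param s_mu logit-scale sd of mean methylation around the regression.
#' @param w_gamma trend coefficients (length `basis$L`).
#' @param s_gamma logit-scale sd of overdispersion around the trend.
#' @param basis the [rbf_basis()] shared by generation and inference.
#' @param seed integer seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(J = 300L, I = 200L,
                       density_regime = c("moderate", "rich", "poor"),
                       p_range = c(0.4, 0.8), q_range = c(0.4, 0.8),
                       w_mu = c(-0.5, -1.5), s_mu = 1,
                       w_gamma = c(-1.2, -0.3, 1.1, -0.9), s_gamma = 0.25,
                       basis = rbf_basis(), seed = 1L) {
  if (is.numeric(density_regime)) {
    N <- as.integer(density_regime)
  } else {
    density_regime <- match.arg(density_regime)
    N <- c(rich = 50L, moderate = 15L, poor = 8L)[[density_regime]]
  }
  if (J <= 0 || I <= 0 || N <= 0) stop("J, I and N must be positive")
  if (any(p_range <= 0) || any(p_range >= 1) || any(q_range <= 0) ||
      any(q_range >= 1))
    stop("p_range and q_range must lie inside (0, 1)")
  if (length(w_gamma) != basis$L)
    stop("w_gamma must have one coefficient per basis column")
  structure(list(J = as.integer(J), I = as.integer(I), N = N,
                 p_range = p_range, q_range = q_range, w_mu = w_mu,
                 s_mu = s_mu, w_gamma = w_gamma, s_gamma = s_gamma,
                 basis = basis, seed = as.integer(seed)),
            class = "sim_config")
}

# counts for given feature parameters; assumes the RNG is already seeded
simulate_counts <- function(mu, gamma, p, q, N, I, cell_prefix) {
  J <- length(mu)
  Y <- n <- matrix(NA_real_, I, J)
  shapes <- beta_shape_from_mean_disp(pmin(pmax(mu, 1e-6), 1 - 1e-6),
                                      pmin(pmax(gamma, 1e-6), 1 - 1e-6))
  for (j in seq_len(J)) {
    Ij <- rbinom(1, I, p[j])
    if (Ij == 0) next
    cells <- sample.int(I, Ij)
    nij <- rbinom(Ij, N, q[j])
    while (any(nij == 0)) {
      z <- nij == 0
      nij[z] <- rbinom(sum(z), N, q[j])  # a covered cell has >= 1 CpG
    }
    theta <- rbeta(Ij, shapes$alpha[j], shapes$beta[j])
    theta <- pmin(pmax(theta, 1e-12), 1 - 1e-12)
    Y[cbind(cells, j)] <- rbinom(Ij, nij, theta)
    n[cbind(cells, j)] <- nij
  }
  list(Y = Y, n = n,
       cell_ids = paste0(cell_prefix, seq_len(I)))
}

#' Simulate a single-cell methylation dataset
#'
#' Generates feature parameters and counts under the hierarchical
#' beta-binomial model: per feature, a cell-coverage probability `p_j` and
#' CpG-coverage probability `q_j` are drawn uniformly; the CpG-density
#' covariate `C_j` is the standardized `q_j`; `mu_j` is logit-normal around
#' the covariate regression; `gamma_j` is logit-normal around the
#' radial-basis trend at `mu_j`; `I_j ~ Binomial(I, p_j)` cells (chosen
#' uniformly) observe the feature with `n_ij ~ Binomial(N, q_j)` covered
#' CpGs (zeros redrawn) and `Y_ij` beta-binomial counts. Deterministic
#' given the seed.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [methylation_dataset()]) and `truth`
#'   (data.frame of class `simulation_truth` with the generative per-feature
#'   parameters; generative weights are attributes).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(config$seed, {
    pars <- simulate_feature_params(config)
    cnt <- simulate_counts(pars$mu, pars$gamma, pars$p, pars$q, config$N,
                           config$I, "cell_")
    finish_simulation(cnt, pars, config, group = NULL)
  })
}

simulate_feature_params <- function(config) {
  J <- config$J
  p <- runif(J, config$p_range[1], config$p_range[2])
  q <- runif(J, config$q_range[1], config$q_range[2])
  C <- standardize_pop(q, "simulated CpG density")
  X <- cbind(1, C)
  mu <- plogis(rnorm(J, X %*% config$w_mu, config$s_mu))
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  G <- rbf_design(mu, config$basis)
  trend <- as.vector(G %*% config$w_gamma)
  eps <- rnorm(J, 0, config$s_gamma)
  gamma <- plogis(trend + eps)
  list(p = p, q = q, C = C, X = X, mu = mu, gamma = gamma, eps = eps,
       trend = trend)
}

finish_simulation <- function(cnt, pars, config, group) {
  feature_ids <- paste0("feature_", seq_len(config$J))
  X <- pars$X
  colnames(X) <- c("intercept", "cpg_density")
  ds <- methylation_dataset(cnt$Y, cnt$n, X = X, cell_ids = cnt$cell_ids,
                            feature_ids = feature_ids, group = group)
  truth <- data.frame(feature_id = feature_ids, mu = pars$mu,
                      gamma = pars$gamma, epsilon = pars$eps,
                      trend = pars$trend, cpg_density = pars$C,
                      p = pars$p, q = pars$q,
                      n_cells_observed = colSums(!is.na(cnt$Y)),
                      perturbation = "null", lor_offset = 0,
                      row.names = NULL, stringsAsFactors = FALSE)
  attr(truth, "w_mu") <- config$w_mu
  attr(truth, "w_gamma") <- config$w_gamma
  attr(truth, "s_mu") <- config$s_mu
  attr(truth, "s_gamma") <- config$s_gamma
  class(truth) <- c("simulation_truth", "data.frame")
  list(dataset = ds, truth = truth)
}

#' Simulate two cell groups with differential perturbations
#'
#' Group A is generated exactly as in [simulate_dataset()]. Group B shares
#' every feature parameter except for a randomly selected fraction of
#' features whose target parameter (`mu` or `gamma`) is shifted on the
#' logit scale by `lor_offset`, with sign chosen by a fair coin per
#' feature; counts are redrawn independently for each group. Shifting
#' `logit(gamma)` with `mu` untouched shifts the true residual
#' overdispersion by exactly the same offset.
#'
#' @param config a [sim_config()].
#' @param prop_perturbed fraction of features perturbed (default 0.15).
#' @param lor_offset logit-scale shift magnitude (> 0).
#' @param target `"mu"` (differential mean) or `"gamma"` (differential
#'   variability).
#' @return list with `datasetA`, `datasetB` and `truth`; the truth table
#'   labels perturbed features (`DM` or `DV`) and records the signed
#'   offset, plus group-B parameter columns.
#' @export
simulate_two_groups <- function(config = sim_config(), prop_perturbed = 0.15,
                                lor_offset = 5, target = c("gamma", "mu")) {
  stopifnot(inherits(config, "sim_config"))
  target <- match.arg(target)
  if (prop_perturbed <= 0 || prop_perturbed >= 1)
    stop("prop_perturbed must lie in (0, 1)")
  if (lor_offset <= 0) stop("lor_offset must be positive")
  with_preserved_seed(config$seed, {
    pars <- simulate_feature_params(config)
    J <- config$J
    n_pert <- round(prop_perturbed * J)
    pert <- sample.int(J, n_pert)
    sign <- sample(c(-1, 1), n_pert, replace = TRUE)
    offset <- numeric(J)
    offset[pert] <- sign * lor_offset
    parsB <- pars
    if (target == "mu") {
      parsB$mu <- plogis(qlogis(pars$mu) + offset)
      parsB$mu <- pmin(pmax(parsB$mu, 1e-6), 1 - 1e-6)
      # gamma values carry over unchanged; the trend position moves with mu
      GB <- rbf_design(parsB$mu, config$basis)
      parsB$trend <- as.vector(GB %*% config$w_gamma)
      parsB$eps <- qlogis(parsB$gamma) - parsB$trend
    } else {
      parsB$gamma <- plogis(qlogis(pars$gamma) + offset)
      parsB$eps <- pars$eps + offset
    }
    cntA <- simulate_counts(pars$mu, pars$gamma, pars$p, pars$q, config$N,
                            config$I, "cellA_")
    cntB <- simulate_counts(parsB$mu, parsB$gamma, parsB$p, parsB$q,
                            config$N, config$I, "cellB_")
    simA <- finish_simulation(cntA, pars, config, group = NULL)
    simB <- finish_simulation(cntB, parsB, config, group = NULL)
    truth <- simA$truth
    truth$mu_B <- parsB$mu
    truth$gamma_B <- parsB$gamma
    truth$epsilon_B <- parsB$eps
    truth$perturbation[pert] <- if (target == "mu") "DM" else "DV"
    truth$lor_offset <- offset
    list(datasetA = simA$dataset, datasetB = simB$dataset, truth = truth)
  })
}

#' Score per-feature calls against simulation truth
#'
#' @param calls logical vector of per-feature decisions, named by feature
#'   id or aligned with the truth table.
#' @param truth a `simulation_truth` table from [simulate_two_groups()].
#' @return list with `power` (called fraction among perturbed features),
#'   `fdp` (false discovery proportion among calls; 0 when nothing is
#'   called) and `type_I_error` (called fraction among null features).
#' @export
evaluate_calls <- function(calls, truth) {
  if (!is.null(names(calls))) {
    if (!all(names(calls) %in% truth$feature_id))
      stop("calls contain features absent from the truth table")
    v <- setNames(rep(FALSE, nrow(truth)), truth$feature_id)
    v[names(calls)] <- calls
    calls <- v
  } else if (length(calls) != nrow(truth)) {
    stop("unnamed calls must match the truth table length")
  }
  perturbed <- truth$perturbation != "null"
  n_called <- sum(calls)
  list(power = if (any(perturbed)) sum(calls & perturbed) / sum(perturbed)
       else NA_real_,
       fdp = if (n_called > 0) sum(calls & !perturbed) / n_called else 0,
       type_I_error = if (any(!perturbed))
         sum(calls & !perturbed) / sum(!perturbed) else NA_real_)
}

#' Down-sampling stability experiment
#'
#' Fits the hierarchical model and the per-feature beta-binomial MLE on the
#' full dataset, then on random cell subsets of the given sizes (several
#' replicates each, small-data QC with a 5-cell minimum), recording how
#' well the subset overdispersion estimates track the full-data fit.
#'
#' @param dataset a [methylation_dataset()].
#' @param sizes cell subset sizes, all smaller than the number of cells.
#' @param reps replicates per size (default 5).
#' @param seed integer seed.
#' @param config a [fit_config()] used for every model fit.
#' @return data.frame with one row per (size, rep, method):
#'   correlation and RMSE of the subset gamma estimates against the same
#'   method's full-data estimates, over features retained in both.
#' @export
downsample_experiment <- function(dataset, sizes = c(20, 50, 100, 200),
                                  reps = 5L, seed = 1L,
                                  config = fit_config()) {
  validate_dataset(dataset)
  I <- nrow(dataset$Y)
  if (any(sizes >= I)) stop("all sizes must be smaller than the cell count")
  qc_small <- qc_config(min_cells_per_feature = 5L)
  full_fit <- fit_model(dataset, config = config)
  full_sum <- posterior_summary(full_fit)
  full_mle <- bb_mle_fit(dataset)
  rows <- list()
  with_preserved_seed(seed, {
    for (size in sizes) for (r in seq_len(reps)) {
      cells <- sort(sample.int(I, size))
      sub <- methylation_dataset(
        dataset$Y[cells, , drop = FALSE], dataset$n[cells, , drop = FALSE],
        X = dataset$X, cell_ids = dataset$cell_ids[cells],
        feature_ids = dataset$feature_ids)
      sub <- apply_qc(sub, qc_small)$dataset
      fit <- fit_model(sub, config = config)
      ssum <- posterior_summary(fit)
      m <- match(ssum$feature_id, full_sum$feature_id)
      rows[[length(rows) + 1]] <- data.frame(
        size = size, rep = r, method = "hierarchical",
        correlation = cor(ssum$gamma_median, full_sum$gamma_median[m]),
        rmse = sqrt(mean((ssum$gamma_median - full_sum$gamma_median[m])^2)))
      smle <- bb_mle_fit(sub)
      ok <- !is.na(smle$gamma_hat)
      m2 <- match(smle$feature_id[ok], full_mle$feature_id)
      both <- !is.na(full_mle$gamma_hat[m2])
      rows[[length(rows) + 1]] <- data.frame(
        size = size, rep = r, method = "bb_mle",
        correlation = cor(smle$gamma_hat[ok][both],
                          full_mle$gamma_hat[m2][both]),
        rmse = sqrt(mean((smle$gamma_hat[ok][both] -
                            full_mle$gamma_hat[m2][both])^2)))
    }
  })
  do.call(rbind, rows)
}
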