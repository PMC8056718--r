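#' Per-feature beta-binomial maximum-likelihood estimation
#'
#' Fits `(mu, gamma)` independently per feature by maximizing the
#' beta-binomial log likelihood over the observed cells, on the
#' unconstrained `(logit mu, logit gamma)` scale with three starting points
#' (a moment-matched start plus two jittered copies) to guard against flat
#' likelihood regions. A `gamma` estimate at the lower boundary (the data
#' look binomial) is reported with the `boundary` flag rather than hidden.
#' Features observed in a single cell are not fitted.
#'
#' @param dataset a [methylation_dataset()].
#' @return data.frame of class `mle_fit`: feature_id, mu_hat, gamma_hat,
#'   loglik, converged, boundary, n_cells.
#' @export
bb_mle_fit <- function(dataset) {
  validate_dataset(dataset)
  J <- ncol(dataset$Y)
  out <- data.frame(feature_id = dataset$feature_ids,
                    mu_hat = NA_real_, gamma_hat = NA_real_,
                    loglik = NA_real_, converged = FALSE, boundary = FALSE,
                    n_cells = colSums(!is.na(dataset$Y)), row.names = NULL)
  for (j in seq_len(J)) {
    obs <- which(!is.na(dataset$Y[, j]))
    if (length(obs) < 2) next
    y <- dataset$Y[obs, j]; n <- dataset$n[obs, j]
    fit <- bb_mle_one(y, n)
    out$mu_hat[j] <- fit$mu
    out$gamma_hat[j] <- fit$gamma
    out$loglik[j] <- fit$loglik
    out$converged[j] <- fit$converged
    out$boundary[j] <- fit$boundary
  }
  class(out) <- c("mle_fit", "data.frame")
  out
}

# moment-matched starting values: sample mean rate and a method-of-moments
# overdispersion from the across-cell variance of rates
bb_mle_start <- function(y, n) {
  rate <- y / n
  mu0 <- min(max(mean(rate), 0.02), 0.98)
  v <- var(rate)
  vtech <- mean(mu0 * (1 - mu0) / n)
  g0 <- (v - vtech) / (mu0 * (1 - mu0))
  g0 <- min(max(ifelse(is.finite(g0), g0, 0.1), 0.01), 0.9)
  c(qlogis(mu0), qlogis(g0))
}

bb_mle_one <- function(y, n) {
  nll <- function(p) -cpp_bb_loglik_sum(y, n, plogis(p[1]), plogis(p[2]))
  p0 <- bb_mle_start(y, n)
  starts <- list(p0, p0 + c(0.5, -1.5), p0 + c(-0.5, 1.5))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(optim(s, nll, method = "BFGS",
                          control = list(maxit = 500)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(list(mu = NA_real_, gamma = NA_real_, loglik = NA_real_,
                converged = FALSE, boundary = FALSE))
  gam <- plogis(best$par[2])
  list(mu = plogis(best$par[1]), gamma = gam, loglik = -best$value,
       converged = best$convergence == 0,
       boundary = gam < 1e-4 || all(n == 1))
}

#' Baseline highly-variable-feature rankings
#'
#' The four comparison strategies for HVF selection, all operating on the
#' empirical methylation rates `theta = Y/n` over observed cells:
#' * `binomial`: mean of `theta (1 - theta)` (blind to bimodal features,
#'   whose rates sit at the extremes where `theta (1 - theta) = 0`);
#' * `gaussian`: sample standard deviation of `theta`;
#' * `normdisp`: dispersion (`var/mean` of `theta`) normalized as the
#'   absolute deviation from the bin-median dispersion divided by the bin
#'   MAD, over `bins` equal-count bins of mean methylation;
#' * `random`: a seeded uniform permutation.
#'
#' @param dataset a [methylation_dataset()].
#' @param method one of `"binomial"`, `"gaussian"`, `"normdisp"`,
#'   `"random"`.
#' @param bins bin count for `normdisp` (default 20).
#' @param seed seed for `random`.
#' @return data.frame: feature_id, method, score, rank (ranked by
#'   decreasing score; ties broken by feature id).
#' @export
rank_hvf_baseline <- function(dataset, method = c("binomial", "gaussian",
                                                  "normdisp", "random"),
                              bins = 20L, seed = 1L) {
  method <- match.arg(method)
  validate_dataset(dataset)
  theta <- dataset$Y / dataset$n
  feats <- dataset$feature_ids
  score <- switch(
    method,
    binomial = colMeans(theta * (1 - theta), na.rm = TRUE),
    gaussian = apply(theta, 2, sd, na.rm = TRUE),
    normdisp = normdisp_score(theta, bins),
    random = with_preserved_seed(seed, runif(length(feats))))
  score[is.na(score)] <- 0
  ord <- order(-score, feats)
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  data.frame(feature_id = feats, method = method, score = unname(score),
             rank = rank, row.names = NULL, stringsAsFactors = FALSE)
}

normdisp_score <- function(theta, bins) {
  m <- colMeans(theta, na.rm = TRUE)
  v <- apply(theta, 2, var, na.rm = TRUE)
  disp <- v / m
  disp[!is.finite(disp)] <- 0
  # equal-count bins by mean methylation
  bin <- ceiling(rank(m, ties.method = "first") / (length(m) / bins))
  score <- numeric(length(m))
  degenerate <- FALSE
  for (b in unique(bin)) {
    in_b <- bin == b
    md <- median(disp[in_b])
    bmad <- mad(disp[in_b])
    if (bmad == 0) {
      score[in_b] <- 0
      degenerate <- TRUE
    } else {
      score[in_b] <- abs(disp[in_b] - md) / bmad
    }
  }
  if (degenerate)
    warning("degenerate bin (zero MAD): scores in that bin set to 0")
  score
}

#' Write a baseline ranking table to TSV
#'
#' @param ranking a [rank_hvf_baseline()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking_table <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
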