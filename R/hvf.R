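#' Expected false discovery rate of a tail-probability decision rule
#'
#' For tail posterior probabilities `pi_j` and evidence threshold `alpha`,
#' the posterior-expected fraction of false discoveries among discoveries:
#' `EFDR(alpha) = sum((1 - pi_j) * [pi_j > alpha]) / sum([pi_j > alpha])`.
#'
#' @param tail_probs vector of tail posterior probabilities in `[0, 1]`.
#' @param alpha evidence threshold.
#' @return the EFDR, or `NA` with attribute `undefined = TRUE` when no
#'   feature exceeds `alpha` (empty discovery set).
#' @export
compute_efdr <- function(tail_probs, alpha) {
  if (!length(tail_probs)) stop("empty tail-probability vector")
  if (any(tail_probs < 0 | tail_probs > 1))
    stop("tail probabilities must lie in [0, 1]")
  called <- tail_probs > alpha
  if (!any(called))
    return(structure(NA_real_, undefined = TRUE))
  sum(1 - tail_probs[called]) / sum(called)
}

#' Calibrate the posterior evidence threshold to a target EFDR
#'
#' Searches a grid of candidate thresholds inside (0.6, 1) and returns the
#' one whose EFDR is closest to the target, preferring thresholds that
#' achieve EFDR at or below the target; ties go to the larger (more
#' conservative) threshold. When every grid point yields an empty discovery
#' set, the fallback 0.9 is returned with a warning.
#'
#' @param tail_probs vector of tail posterior probabilities.
#' @param target_efdr desired EFDR level.
#' @param grid candidate thresholds in (0.6, 1).
#' @return the calibrated threshold, with attribute `achieved_efdr`.
#' @export
calibrate_threshold <- function(tail_probs, target_efdr,
                                grid = seq(0.6, 0.995, by = 0.005)) {
  if (!length(grid)) stop("empty threshold grid")
  efdr <- vapply(grid, function(a) as.numeric(compute_efdr(tail_probs, a)),
                 numeric(1))
  defined <- !is.na(efdr)
  if (!any(defined)) {
    warning("no threshold on the grid yields any discovery; ",
            "falling back to alpha = 0.9")
    return(structure(0.9, achieved_efdr = NA_real_))
  }
  cand <- which(defined & efdr <= target_efdr)
  if (!length(cand)) cand <- which(defined)
  dist <- abs(efdr[cand] - target_efdr)
  best <- cand[dist == min(dist)]
  pick <- best[which.max(grid[best])]  # conservative tie-break
  structure(grid[pick], achieved_efdr = efdr[pick])
}

#' Detect highly variable features
#'
#' Labels features whose residual overdispersion credibly exceeds a
#' population-percentile threshold. The exceedance threshold `epsilon_0` is
#' the `delta_e` quantile of per-feature posterior medians of `epsilon`
#' (or of the pooled draws with `use_pooled = TRUE`); each feature's tail
#' probability is the fraction of posterior draws above `epsilon_0`; the
#' evidence threshold is EFDR-calibrated via [calibrate_threshold()].
#'
#' @param draws a `posterior_draws` object.
#' @param delta_e percentile (default 0.9) defining `epsilon_0`.
#' @param target_efdr EFDR level for threshold calibration (default 0.1).
#' @param use_pooled compute `epsilon_0` from pooled draws instead of
#'   per-feature medians.
#' @return object of class `hvf_result`: a data.frame (feature_id,
#'   tail_prob, epsilon_median, epsilon_sd, is_hvf, rank) with the globals
#'   `epsilon0`, `alpha`, `achieved_efdr`, `delta_e`, `target_efdr` as
#'   attributes.
#' @export
detect_hvf <- function(draws, delta_e = 0.9, target_efdr = 0.1,
                       use_pooled = FALSE) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (delta_e <= 0 || delta_e >= 1) stop("delta_e must lie in (0, 1)")
  eps <- draws$epsilon
  J <- ncol(eps)
  if (J < 10)
    warning("fewer than 10 features: the percentile threshold is unstable")
  med <- apply(eps, 2, median)
  eps0 <- if (use_pooled) quantile(as.vector(eps), delta_e, names = FALSE)
          else quantile(med, delta_e, names = FALSE)
  tail_prob <- colMeans(eps > eps0)
  alpha <- calibrate_threshold(tail_prob, target_efdr)
  out <- data.frame(feature_id = draws$feature_ids,
                    tail_prob = unname(tail_prob),
                    epsilon_median = unname(med),
                    epsilon_sd = unname(apply(eps, 2, sd)),
                    row.names = NULL)
  out$is_hvf <- out$tail_prob > as.numeric(alpha)
  ord <- order(-out$tail_prob, -out$epsilon_median, out$feature_id)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  attr(out, "epsilon0") <- eps0
  attr(out, "alpha") <- as.numeric(alpha)
  attr(out, "achieved_efdr") <- attr(alpha, "achieved_efdr")
  attr(out, "delta_e") <- delta_e
  attr(out, "target_efdr") <- target_efdr
  class(out) <- c("hvf_result", "data.frame")
  out
}

#' Write an HVF table to TSV
#'
#' @param hvf an `hvf_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hvf_table <- function(hvf, path) {
  write.table(as.data.frame(hvf), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
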