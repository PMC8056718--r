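# shared machinery for the two-group posterior tests
align_draws <- function(drawsA, drawsB, seed) {
  common <- intersect(drawsA$feature_ids, drawsB$feature_ids)
  if (!length(common)) stop("the two fits share no features")
  dA <- nrow(drawsA$mu); dB <- nrow(drawsB$mu)
  D <- min(dA, dB)
  idx <- list(idxA = seq_len(dA), idxB = seq_len(dB))
  if (dA != dB) {
    # subsample the larger fit to match draw counts, reproducibly
    idx <- with_preserved_seed(seed, list(
      idxA = if (dA > D) sort(sample.int(dA, D)) else seq_len(dA),
      idxB = if (dB > D) sort(sample.int(dB, D)) else seq_len(dB)))
  }
  list(common = common, idxA = idx$idxA, idxB = idx$idxB)
}

differential_frame <- function(drawsA, drawsB, feature_union, common) {
  data.frame(feature_id = feature_union,
             tested = feature_union %in% common,
             row.names = NULL)
}

#' Differential mean methylation test
#'
#' Compares mean methylation between two independently fitted groups of
#' cells. Per feature, the log-odds-ratio draws are
#' `logit(mu^A) - logit(mu^B)` with draws paired by index; the tail
#' probability is the fraction of draws with `|LOR| > psi_m`, and the
#' evidence threshold is EFDR-calibrated over all tested features. Features
#' absent from either fit are reported as `not-tested`.
#'
#' @param drawsA,drawsB `posterior_draws` for the two groups.
#' @param psi_m minimum effect size (LOR scale); default `log(2)`, a
#'   two-fold change in odds.
#' @param target_efdr EFDR level for calibration (default 0.05).
#' @param seed seed used when draw counts must be subsampled to match.
#' @return object of class `differential_result`: data.frame with columns
#'   feature_id, tested, mu_median_A, mu_median_B, lor_mu_median,
#'   dm_tail_prob, dm_call (`A+`, `B+`, `no-diff`, `not-tested`); the
#'   calibrated `alpha`, `achieved_efdr`, `psi` and `target_efdr` are
#'   attributes.
#' @export
dm_test <- function(drawsA, drawsB, psi_m = log(2), target_efdr = 0.05,
                    seed = 1L) {
  al <- align_draws(drawsA, drawsB, seed)
  cm <- al$common
  muA <- drawsA$mu[al$idxA, cm, drop = FALSE]
  muB <- drawsB$mu[al$idxB, cm, drop = FALSE]
  lor <- qlogis(muA) - qlogis(muB)
  tail_prob <- colMeans(abs(lor) > psi_m)
  lor_med <- apply(lor, 2, median)
  alpha <- calibrate_threshold(tail_prob, target_efdr)
  univ <- union(drawsA$feature_ids, drawsB$feature_ids)
  out <- data.frame(feature_id = univ, tested = univ %in% cm,
                    mu_median_A = NA_real_, mu_median_B = NA_real_,
                    lor_mu_median = NA_real_, dm_tail_prob = NA_real_,
                    dm_call = "not-tested", stringsAsFactors = FALSE)
  m <- match(cm, univ)
  out$mu_median_A[m] <- apply(muA, 2, median)
  out$mu_median_B[m] <- apply(muB, 2, median)
  out$lor_mu_median[m] <- lor_med
  out$dm_tail_prob[m] <- tail_prob
  sig <- tail_prob > as.numeric(alpha)
  out$dm_call[m] <- ifelse(sig, ifelse(lor_med > 0, "A+", "B+"), "no-diff")
  attr(out, "alpha") <- as.numeric(alpha)
  attr(out, "achieved_efdr") <- attr(alpha, "achieved_efdr")
  attr(out, "psi") <- psi_m
  attr(out, "target_efdr") <- target_efdr
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Differential variability test
#'
#' Compares cell-to-cell methylation variability between two groups through
#' residual overdispersion, which is unconfounded by mean methylation. Per
#' feature, the test statistic draws are `epsilon^A - epsilon^B` (draws
#' paired by index); the tail probability is the fraction of draws with
#' `|epsilon^A - epsilon^B| > psi_e`, EFDR-calibrated as in [dm_test()].
#' The overdispersion log-odds ratio `logit(gamma^A) - logit(gamma^B)`
#' decomposes exactly into a trend ("mean contribution") part and this
#' residual change; the median of both parts is reported.
#'
#' @param drawsA,drawsB `posterior_draws` for the two groups.
#' @param psi_e minimum residual change; default `log(1.5)`.
#' @param target_efdr EFDR level (default 0.05).
#' @param seed seed for draw-count matching.
#' @return object of class `differential_result`: data.frame with columns
#'   feature_id, tested, eps_median_A, eps_median_B, eps_diff_median,
#'   gamma_lor_median, gamma_lor_trend_median, dv_tail_prob, dv_call.
#' @export
dv_test <- function(drawsA, drawsB, psi_e = log(1.5), target_efdr = 0.05,
                    seed = 1L) {
  al <- align_draws(drawsA, drawsB, seed)
  cm <- al$common
  epsA <- drawsA$epsilon[al$idxA, cm, drop = FALSE]
  epsB <- drawsB$epsilon[al$idxB, cm, drop = FALSE]
  diff <- epsA - epsB
  # per-group trend values via the exact identity trend = logit(gamma) - eps
  trendA <- qlogis(drawsA$gamma[al$idxA, cm, drop = FALSE]) - epsA
  trendB <- qlogis(drawsB$gamma[al$idxB, cm, drop = FALSE]) - epsB
  gamma_lor <- (trendA + epsA) - (trendB + epsB)
  tail_prob <- colMeans(abs(diff) > psi_e)
  diff_med <- apply(diff, 2, median)
  alpha <- calibrate_threshold(tail_prob, target_efdr)
  univ <- union(drawsA$feature_ids, drawsB$feature_ids)
  out <- data.frame(feature_id = univ, tested = univ %in% cm,
                    eps_median_A = NA_real_, eps_median_B = NA_real_,
                    eps_diff_median = NA_real_, gamma_lor_median = NA_real_,
                    gamma_lor_trend_median = NA_real_,
                    dv_tail_prob = NA_real_, dv_call = "not-tested",
                    stringsAsFactors = FALSE)
  m <- match(cm, univ)
  out$eps_median_A[m] <- apply(epsA, 2, median)
  out$eps_median_B[m] <- apply(epsB, 2, median)
  out$eps_diff_median[m] <- diff_med
  out$gamma_lor_median[m] <- apply(gamma_lor, 2, median)
  out$gamma_lor_trend_median[m] <- apply(trendA - trendB, 2, median)
  out$dv_tail_prob[m] <- tail_prob
  sig <- tail_prob > as.numeric(alpha)
  out$dv_call[m] <- ifelse(sig, ifelse(diff_med > 0, "A+", "B+"), "no-diff")
  attr(out, "alpha") <- as.numeric(alpha)
  attr(out, "achieved_efdr") <- attr(alpha, "achieved_efdr")
  attr(out, "psi") <- psi_e
  attr(out, "target_efdr") <- target_efdr
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Fisher's exact test baseline for differential mean methylation
#'
#' Pools counts within each group per feature into a 2x2 table of
#' methylated/unmethylated CpGs and applies a two-sided Fisher's exact test
#' with Benjamini-Hochberg adjustment across features. A feature is called
#' differentially methylated when the pooled |log-odds ratio| exceeds
#' `lor_thresh` and the adjusted p-value is below `fdr`. The reported LOR
#' uses the Haldane-Anscombe +0.5 correction so boundary tables stay
#' finite; the p-value is exact without continuity correction.
#'
#' @param dataset a [methylation_dataset()] whose `group` has two levels.
#' @param lor_thresh minimum pooled |LOR|; default `log(1.5)`.
#' @param fdr BH-adjusted p-value cutoff; default 0.10.
#' @return data.frame: feature_id, met_A, unmet_A, met_B, unmet_B, lor,
#'   p_value, p_adjusted, dm_call (`DM`, `no-diff`, `not-tested`).
#' @export
fisher_dm <- function(dataset, lor_thresh = log(1.5), fdr = 0.10) {
  validate_dataset(dataset)
  if (is.null(dataset$group) || nlevels(dataset$group) != 2)
    stop("dataset must carry a two-level group label")
  ga <- levels(dataset$group)[1]
  inA <- dataset$group == ga
  J <- ncol(dataset$Y)
  met_A <- colSums(dataset$Y[inA, , drop = FALSE], na.rm = TRUE)
  tot_A <- colSums(dataset$n[inA, , drop = FALSE], na.rm = TRUE)
  met_B <- colSums(dataset$Y[!inA, , drop = FALSE], na.rm = TRUE)
  tot_B <- colSums(dataset$n[!inA, , drop = FALSE], na.rm = TRUE)
  unmet_A <- tot_A - met_A
  unmet_B <- tot_B - met_B
  testable <- tot_A > 0 & tot_B > 0
  p <- rep(NA_real_, J)
  for (j in which(testable)) {
    tab <- matrix(c(met_A[j], unmet_A[j], met_B[j], unmet_B[j]), 2)
    p[j] <- fisher.test(tab)$p.value
  }
  lor <- log((met_A + 0.5) / (unmet_A + 0.5)) -
         log((met_B + 0.5) / (unmet_B + 0.5))
  padj <- rep(NA_real_, J)
  padj[testable] <- p.adjust(p[testable], method = "BH")
  call <- ifelse(!testable, "not-tested",
                 ifelse(abs(lor) > lor_thresh & padj < fdr, "DM", "no-diff"))
  data.frame(feature_id = dataset$feature_ids,
             met_A = met_A, unmet_A = unmet_A,
             met_B = met_B, unmet_B = unmet_B,
             lor = lor, p_value = p, p_adjusted = padj, dm_call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a differential-test table to TSV
#'
#' @param result a `differential_result` or [fisher_dm()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(result, path) {
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
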