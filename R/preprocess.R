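#' Quality-control configuration
#'
#' Thresholds for the censoring and feature-filtering steps of [apply_qc()].
#' The defaults follow common practice for sparse single-cell bisulphite
#' data: entries with fewer than 3 covered CpGs are unreliable and censored;
#' features need coverage in at least 15 cells; features with across-cell
#' mean methylation below 0.1 or above 0.9 carry no heterogeneity signal.
#'
#' @param min_cpgs_per_entry censor entries with `n < min_cpgs_per_entry`.
#' @param min_cells_per_feature drop features observed in fewer cells.
#' @param mean_lower,mean_upper bounds on the across-cell mean of `Y/n`.
#' @param mean_coverage_threshold minimum mean observed `n` per feature, or
#'   `"auto"`: 3 when the dataset has more than 100 cells, 5 when fewer than
#'   50, and the midpoint 4 in between.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(min_cpgs_per_entry = 3L, min_cells_per_feature = 15L,
                      mean_lower = 0.1, mean_upper = 0.9,
                      mean_coverage_threshold = "auto") {
  if (mean_lower < 0 || mean_upper > 1 || mean_lower >= mean_upper)
    stop("need 0 <= mean_lower < mean_upper <= 1")
  if (min_cpgs_per_entry < 0 || min_cells_per_feature < 0)
    stop("thresholds must be non-negative")
  if (!identical(mean_coverage_threshold, "auto") &&
      (!is.numeric(mean_coverage_threshold) || mean_coverage_threshold < 0))
    stop("mean_coverage_threshold must be 'auto' or a non-negative number")
  structure(list(min_cpgs_per_entry = as.integer(min_cpgs_per_entry),
                 min_cells_per_feature = as.integer(min_cells_per_feature),
                 mean_lower = mean_lower, mean_upper = mean_upper,
                 mean_coverage_threshold = mean_coverage_threshold),
            class = "qc_config")
}

#' Apply quality control to a methylation dataset
#'
#' Steps, in order: (1) censor entries with fewer than
#' `min_cpgs_per_entry` covered CpGs; (2) drop features observed in fewer
#' than `min_cells_per_feature` cells; (3) drop features whose across-cell
#' (unweighted) mean of `Y/n` lies outside `[mean_lower, mean_upper]`;
#' (4) drop features whose mean observed coverage falls below the
#' mean-coverage threshold. Later statistics are computed on the censored
#' data, and the operation is idempotent.
#'
#' @param dataset a [methylation_dataset()].
#' @param config a [qc_config()].
#' @return list with the filtered `dataset` and a `report` data.frame
#'   (class `qc_report`) with per-step removal counts.
#' @export
apply_qc <- function(dataset, config = qc_config()) {
  validate_dataset(dataset)
  Y <- dataset$Y; n <- dataset$n
  n_in <- ncol(Y)
  # step 1: censor low-coverage entries
  censor <- !is.na(n) & n < config$min_cpgs_per_entry
  Y[censor] <- NA; n[censor] <- NA
  # step 2: minimum cells per feature
  obs_cells <- colSums(!is.na(n))
  keep2 <- obs_cells >= config$min_cells_per_feature
  removed2 <- sum(!keep2)
  if (!any(keep2))
    stop("empty dataset after QC: every feature removed at the ",
         "minimum-cells step")
  Y <- Y[, keep2, drop = FALSE]; n <- n[, keep2, drop = FALSE]
  # step 3: mean methylation bounds (unweighted mean of per-cell rates)
  mean_rate <- colMeans(Y / n, na.rm = TRUE)
  keep3 <- mean_rate >= config$mean_lower & mean_rate <= config$mean_upper
  keep3[is.na(keep3)] <- FALSE
  removed3 <- sum(!keep3)
  if (!any(keep3))
    stop("empty dataset after QC: every feature removed at the ",
         "mean-methylation step")
  Y <- Y[, keep3, drop = FALSE]; n <- n[, keep3, drop = FALSE]
  # step 4: mean coverage across covered cells
  thr <- config$mean_coverage_threshold
  if (identical(thr, "auto")) {
    I <- nrow(Y)
    thr <- if (I > 100) 3 else if (I < 50) 5 else 4
  }
  mean_cov <- colMeans(n, na.rm = TRUE)
  keep4 <- mean_cov >= thr
  removed4 <- sum(!keep4)
  if (!any(keep4))
    stop("empty dataset after QC: every feature removed at the ",
         "mean-coverage step")
  Y <- Y[, keep4, drop = FALSE]; n <- n[, keep4, drop = FALSE]
  feats <- colnames(Y)
  out <- methylation_dataset(
    Y, n, X = dataset$X[feats, , drop = FALSE],
    cell_ids = dataset$cell_ids, feature_ids = feats, group = dataset$group)
  report <- data.frame(
    step = c("censor_low_coverage_entries", "min_cells_per_feature",
             "mean_methylation_bounds", "mean_coverage"),
    entries_censored = c(sum(censor), 0L, 0L, 0L),
    features_removed = c(0L, removed2, removed3, removed4))
  attr(report, "features_in") <- n_in
  attr(report, "features_out") <- length(feats)
  attr(report, "mean_coverage_threshold_used") <- thr
  class(report) <- c("qc_report", "data.frame")
  list(dataset = out, report = report)
}

#' Build the feature covariate matrix
#'
#' Constructs the design matrix used by the mean-methylation regression: an
#' intercept column plus the CpG density of each feature (catalog CpG sites
#' per base pair), optionally standardized across features (population
#' standard deviation). A zero-variance density column is zeroed with a
#' warning rather than rejected.
#'
#' @param annotations a [make_feature_annotations()] result.
#' @param cpg_positions data.frame with columns `chrom` and `position`
#'   (1-based) cataloguing CpG sites.
#' @param standardize center and scale the density column (default `TRUE`).
#' @param extra optional additional covariate columns (features x k),
#'   appended unchanged.
#' @return numeric matrix, features x P, first column all ones.
#' @export
build_covariates <- function(annotations, cpg_positions, standardize = TRUE,
                             extra = NULL) {
  len <- annotations$end - annotations$start
  if (any(len <= 0)) stop("zero-length feature")
  miss_chrom <- setdiff(annotations$chrom, unique(cpg_positions$chrom))
  if (length(miss_chrom))
    stop("CpG catalog missing chromosome(s): ",
         paste(miss_chrom, collapse = ", "))
  ann_gr <- GenomicRanges::GRanges(
    seqnames = annotations$chrom,
    ranges = IRanges::IRanges(start = annotations$start + 1,
                              end = annotations$end))
  site_gr <- GenomicRanges::GRanges(
    seqnames = cpg_positions$chrom,
    ranges = IRanges::IRanges(start = cpg_positions$position, width = 1))
  counts <- GenomicRanges::countOverlaps(ann_gr, site_gr)
  dens <- counts / len
  if (standardize) dens <- standardize_pop(dens, "CpG density")
  X <- cbind(intercept = 1, cpg_density = dens)
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  rownames(X) <- annotations$feature_id
  X
}

# population-sd standardization; constant columns zeroed with a warning
standardize_pop <- function(x, label = "covariate") {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) {
    warning(label, " is constant across features; standardized to all zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}
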