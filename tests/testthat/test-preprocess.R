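make_qc_fixture <- function() {
  # 20 cells x 4 features engineered to trip specific QC steps
  I <- 20
  Y <- matrix(NA_real_, I, 4,
              dimnames = list(paste0("c", 1:I), paste0("f", 1:4)))
  n <- Y
  # f1: healthy -- observed in all cells, moderate methylation
  n[, 1] <- 10; Y[, 1] <- 5
  # f2: observed in 14 cells only
  n[1:14, 2] <- 10; Y[1:14, 2] <- 4
  # f3: nearly fully methylated (rates 1.0, 0.95, 0.9 pattern)
  n[, 3] <- 20; Y[, 3] <- 19
  Y[1:7, 3] <- 20; Y[8:14, 3] <- 19; Y[15:20, 3] <- 18
  # f4: entries with n = 2 in half the cells (censoring target), observed
  # in all, but after censoring only 10 cells remain
  n[, 4] <- c(rep(2, 10), rep(10, 10)); Y[, 4] <- c(rep(1, 10), rep(5, 10))
  methylation_dataset(Y, n)
}

test_that("QC applies censoring and filters in the documented order", {
  ds <- make_qc_fixture()
  res <- apply_qc(ds, qc_config(min_cpgs_per_entry = 3,
                                min_cells_per_feature = 15,
                                mean_coverage_threshold = 0))
  kept <- res$dataset$feature_ids
  expect_identical(kept, "f1")
  rep <- res$report
  # f4 loses its 10 shallow entries at censoring, then falls below 15 cells
  expect_equal(rep$entries_censored[1], 10)
  # f2 (14 cells) and f4 (10 after censoring) at the min-cells step
  expect_equal(rep$features_removed[rep$step == "min_cells_per_feature"], 2)
  # f3 mean rate (20 + 19 + 18 pattern)/20 = 0.95 > 0.9
  expect_equal(rep$features_removed[rep$step == "mean_methylation_bounds"], 1)
  expect_equal(sum(rep$features_removed),
               attr(rep, "features_in") - attr(rep, "features_out"))
})

test_that("entries below the CpG floor are censored", {
  Y <- matrix(c(1, 2, 1, 3), 2, dimnames = list(c("c1", "c2"), c("f1", "f2")))
  n <- matrix(c(2, 5, 3, 6), 2, dimnames = list(c("c1", "c2"), c("f1", "f2")))
  ds <- methylation_dataset(Y, n)
  res <- apply_qc(ds, qc_config(min_cpgs_per_entry = 3,
                                min_cells_per_feature = 1,
                                mean_coverage_threshold = 0))
  expect_true(is.na(res$dataset$Y["c1", "f1"])) # n = 2 censored
  expect_equal(res$dataset$Y["c2", "f1"], 2)
})

test_that("QC is idempotent and never alters surviving counts", {
  ds <- make_qc_fixture()
  cfg <- qc_config(mean_coverage_threshold = 0)
  once <- apply_qc(ds, cfg)
  twice <- apply_qc(once$dataset, cfg)
  expect_identical(once$dataset$Y, twice$dataset$Y)
  expect_identical(once$dataset$n, twice$dataset$n)
  expect_equal(sum(twice$report$features_removed), 0)
  kept <- once$dataset$feature_ids
  expect_identical(once$dataset$Y[, kept], ds$Y[, kept])
})

test_that("auto mean-coverage threshold tracks the dataset size", {
  mk <- function(I) {
    Y <- matrix(1, I, 20); n <- matrix(4, I, 20)
    methylation_dataset(Y, n)
  }
  # threshold 3 for I > 100, 5 for I < 50, midpoint 4 between: a feature
  # with mean coverage 4 survives at I = 150 and I = 75, dies at I = 30
  cfg <- qc_config(min_cells_per_feature = 1, mean_lower = 0.2,
                   mean_upper = 0.3)
  expect_equal(ncol(apply_qc(mk(150), cfg)$dataset$Y), 20)
  expect_equal(ncol(apply_qc(mk(75), cfg)$dataset$Y), 20)
  expect_error(apply_qc(mk(30), cfg), "mean-coverage")
})

test_that("QC errors name the exhausting step on an empty result", {
  Y <- matrix(1, 5, 2); n <- matrix(10, 5, 2)
  ds <- methylation_dataset(Y, n)
  expect_error(apply_qc(ds, qc_config(min_cells_per_feature = 10)),
               "minimum-cells")
  Y2 <- matrix(0, 5, 2); n2 <- matrix(10, 5, 2)
  expect_error(apply_qc(methylation_dataset(Y2, n2),
                        qc_config(min_cells_per_feature = 1)),
               "mean-methylation")
})

test_that("covariates: density definition and population standardization", {
  ann <- data.frame(feature_id = c("a", "b"), chrom = "chr1",
                    start = c(0, 1000), end = c(1000, 2000), strand = "*")
  sites <- data.frame(chrom = "chr1",
                      position = c(1:10, seq(1001, 1060, by = 2)))
  X <- build_covariates(ann, sites, standardize = FALSE)
  expect_equal(unname(X[, 2]), c(10 / 1000, 30 / 1000))
  Xs <- build_covariates(ann, sites, standardize = TRUE)
  expect_equal(unname(Xs[, 2]), c(-1, 1)) # population-sd standardization
  expect_equal(unname(Xs[, 1]), c(1, 1))
})

test_that("constant covariate is zeroed with a warning; errors are caught", {
  ann <- data.frame(feature_id = c("a", "b"), chrom = "chr1",
                    start = c(0, 1000), end = c(1000, 2000), strand = "*")
  sites <- data.frame(chrom = "chr1", position = c(1:5, 1001:1005))
  expect_warning(X <- build_covariates(ann, sites), "constant")
  expect_equal(unname(X[, 2]), c(0, 0))
  ann_bad <- data.frame(feature_id = "a", chrom = "chr9", start = 0,
                        end = 100, strand = "*")
  expect_error(build_covariates(ann_bad, sites), "chr9")
})
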