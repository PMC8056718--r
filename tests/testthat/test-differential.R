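fake_group <- function(mu, eps, gamma = NULL, ids = colnames(mu)) {
  basis <- rbf_basis()
  if (is.null(gamma)) {
    # construct gamma through the trend so the identity holds exactly
    w <- c(-1.2, -0.3, 1.1, -0.9)
    trend <- matrix(NA_real_, nrow(mu), ncol(mu))
    for (d in seq_len(nrow(mu)))
      trend[d, ] <- as.vector(rbf_design(mu[d, ], basis) %*% w)
    gamma <- plogis(trend + eps)
  }
  structure(list(feature_ids = ids, mu = mu, gamma = gamma, epsilon = eps,
                 basis = basis),
            class = "posterior_draws")
}

test_that("self-comparison yields zero effect draws and no calls", {
  set.seed(21)
  D <- 50
  mu <- matrix(plogis(rnorm(D * 8)), D, 8,
               dimnames = list(NULL, paste0("f", 1:8)))
  eps <- matrix(rnorm(D * 8, sd = 0.3), D, 8,
                dimnames = list(NULL, paste0("f", 1:8)))
  g <- fake_group(mu, eps)
  suppressWarnings({
    dm <- dm_test(g, g)
    dv <- dv_test(g, g)
  })
  expect_true(all(dm$dm_tail_prob == 0))
  expect_true(all(dm$dm_call == "no-diff"))
  expect_true(all(dv$dv_tail_prob == 0))
  expect_true(all(dv$dv_call == "no-diff"))
})

test_that("constant logit shifts saturate the tail probabilities", {
  set.seed(22)
  D <- 50
  mu <- matrix(plogis(rnorm(D * 6)), D, 6,
               dimnames = list(NULL, paste0("f", 1:6)))
  eps <- matrix(rnorm(D * 6, sd = 0.2), D, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
  gA <- fake_group(plogis(qlogis(mu) + 2 * log(2)), eps)
  gB <- fake_group(mu, eps)
  suppressWarnings(dm <- dm_test(gA, gB, psi_m = log(2)))
  expect_true(all(dm$dm_tail_prob == 1))
  expect_true(all(dm$dm_call == "A+"))
  # DV: epsilon shifted by 2 log 1.5 in every draw
  gA2 <- fake_group(mu, eps + 2 * log(1.5))
  gB2 <- fake_group(mu, eps)
  suppressWarnings(dv <- dv_test(gA2, gB2, psi_e = log(1.5)))
  expect_true(all(dv$dv_tail_prob == 1))
  expect_true(all(dv$dv_call == "A+"))
})

test_that("the log-odds ratio follows logit arithmetic", {
  D <- 20
  mu_a <- matrix(2 / 3, D, 4, dimnames = list(NULL, paste0("f", 1:4)))
  mu_b <- matrix(1 / 3, D, 4, dimnames = list(NULL, paste0("f", 1:4)))
  eps <- matrix(0, D, 4, dimnames = list(NULL, paste0("f", 1:4)))
  suppressWarnings(dm <- dm_test(fake_group(mu_a, eps),
                                 fake_group(mu_b, eps)))
  expect_equal(dm$lor_mu_median, rep(2 * log(2), 4), tolerance = 1e-12)
  expect_true(all(dm$dm_tail_prob == 1)) # 2 ln 2 > log 2
})

test_that("the overdispersion LOR decomposes exactly into trend and residual", {
  set.seed(23)
  D <- 40
  mu_a <- matrix(plogis(rnorm(D * 10)), D, 10,
                 dimnames = list(NULL, paste0("f", 1:10)))
  mu_b <- matrix(plogis(rnorm(D * 10)), D, 10,
                 dimnames = list(NULL, paste0("f", 1:10)))
  eps_a <- matrix(rnorm(D * 10, sd = 0.4), D, 10,
                  dimnames = list(NULL, paste0("f", 1:10)))
  eps_b <- matrix(rnorm(D * 10, sd = 0.4), D, 10,
                  dimnames = list(NULL, paste0("f", 1:10)))
  gA <- fake_group(mu_a, eps_a)
  gB <- fake_group(mu_b, eps_b)
  # per-draw additivity: trend contribution + residual change = gamma LOR
  trendA <- qlogis(gA$gamma) - gA$epsilon
  trendB <- qlogis(gB$gamma) - gB$epsilon
  lhs <- (trendA - trendB) + (gA$epsilon - gB$epsilon)
  rhs <- qlogis(gA$gamma) - qlogis(gB$gamma)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  suppressWarnings(dv <- dv_test(gA, gB))
  # the reported gamma LOR medians summarize the per-draw sums
  expect_equal(dv$gamma_lor_median,
               apply(rhs, 2, median)[dv$feature_id], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("group swap flips signs and directional labels", {
  set.seed(24)
  D <- 60
  mu_a <- matrix(plogis(rnorm(D * 12, 0.3)), D, 12,
                 dimnames = list(NULL, paste0("f", 1:12)))
  mu_b <- matrix(plogis(rnorm(D * 12, -0.4)), D, 12,
                 dimnames = list(NULL, paste0("f", 1:12)))
  eps_a <- matrix(rnorm(D * 12, 0.3, 0.3), D, 12,
                  dimnames = list(NULL, paste0("f", 1:12)))
  eps_b <- matrix(rnorm(D * 12, -0.3, 0.3), D, 12,
                  dimnames = list(NULL, paste0("f", 1:12)))
  gA <- fake_group(mu_a, eps_a)
  gB <- fake_group(mu_b, eps_b)
  suppressWarnings({
    ab_dm <- dm_test(gA, gB); ba_dm <- dm_test(gB, gA)
    ab_dv <- dv_test(gA, gB); ba_dv <- dv_test(gB, gA)
  })
  expect_equal(ab_dm$lor_mu_median, -ba_dm$lor_mu_median)
  expect_equal(ab_dm$dm_tail_prob, ba_dm$dm_tail_prob)
  swap <- c("A+" = "B+", "B+" = "A+", "no-diff" = "no-diff",
            "not-tested" = "not-tested")
  expect_identical(unname(swap[ab_dm$dm_call]), ba_dm$dm_call)
  expect_equal(ab_dv$eps_diff_median, -ba_dv$eps_diff_median)
  expect_identical(unname(swap[ab_dv$dv_call]), ba_dv$dv_call)
})

test_that("features absent from one fit are reported not-tested", {
  D <- 20
  mk <- function(ids) {
    mu <- matrix(0.5, D, length(ids), dimnames = list(NULL, ids))
    eps <- matrix(0, D, length(ids), dimnames = list(NULL, ids))
    fake_group(mu, eps)
  }
  suppressWarnings(dm <- dm_test(mk(c("f1", "f2", "f3")), mk(c("f2", "f3", "f4"))))
  expect_setequal(dm$feature_id, c("f1", "f2", "f3", "f4"))
  expect_equal(dm$dm_call[dm$feature_id %in% c("f1", "f4")],
               rep("not-tested", 2))
  expect_error(dm_test(mk("f1"), mk("f2")), "no features")
})

test_that("fisher baseline matches hypergeometric enumeration", {
  # 2x2 table (9,1 / 1,9): two-sided exact p from first principles
  p_oracle <- sum(dhyper(c(0:1, 9:10), 10, 10, 10))
  Y <- matrix(c(rep(9, 1), rep(1, 1)), nrow = 2, ncol = 1)
  n <- matrix(10, 2, 1)
  ds <- methylation_dataset(Y, n, group = c("A", "B"),
                            feature_ids = "f1", cell_ids = c("a1", "b1"))
  out <- fisher_dm(ds)
  expect_equal(out$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(out$p_value, 1.0e-3, tolerance = 0.15)
  expect_gt(abs(out$lor), log(1.5))
  expect_equal(out$dm_call, "DM")
})

test_that("fisher baseline handles symmetric and boundary tables", {
  Y <- matrix(c(10, 10, 0, 10), nrow = 2,
              dimnames = list(c("a1", "b1"), c("sym", "extreme")))
  n <- matrix(c(20, 20, 10, 10), nrow = 2,
              dimnames = list(c("a1", "b1"), c("sym", "extreme")))
  ds <- methylation_dataset(Y, n, group = c("A", "B"))
  out <- fisher_dm(ds)
  sym <- out[out$feature_id == "sym", ]
  expect_equal(sym$p_value, 1)
  expect_equal(sym$lor, 0)
  expect_equal(sym$dm_call, "no-diff")
  ext <- out[out$feature_id == "extreme", ]
  expect_true(is.finite(ext$lor)) # Haldane-Anscombe correction
  expect_equal(ext$dm_call, "DM")
  # a feature with no counts in one group is not tested
  Y2 <- matrix(c(3, NA), 2, 1); n2 <- matrix(c(5, NA), 2, 1)
  ds2 <- methylation_dataset(Y2, n2, group = c("A", "B"),
                             feature_ids = "f", cell_ids = c("a1", "b1"))
  expect_equal(fisher_dm(ds2)$dm_call, "not-tested")
})
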