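test_that("simulation is seed-deterministic and satisfies dataset invariants", {
  cfg <- sim_config(J = 50, I = 40, seed = 51)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$Y, s2$dataset$Y)
  expect_identical(s1$truth, s2$truth)
  expect_silent(validate_dataset(s1$dataset))
  # truth table internal consistency: epsilon is the trend residual
  expect_equal(qlogis(s1$truth$gamma), s1$truth$trend + s1$truth$epsilon,
               tolerance = 1e-9)
})

test_that("simulated coverage follows the configured regimes", {
  cfg <- sim_config(J = 80, I = 100, density_regime = "moderate", seed = 52)
  sim <- simulate_dataset(cfg)
  expect_lte(max(sim$dataset$n, na.rm = TRUE), 15)
  expect_gte(min(sim$dataset$n, na.rm = TRUE), 1)
  # observed fraction per feature tracks p_j; overall within the envelope
  obs_frac <- colMeans(!is.na(sim$dataset$Y))
  expect_gt(cor(obs_frac, sim$truth$p), 0.8)
  expect_gt(mean(obs_frac), 0.35)
  expect_lt(mean(obs_frac), 0.85)
  rich <- simulate_dataset(sim_config(J = 30, I = 30,
                                      density_regime = "rich", seed = 53))
  expect_lte(max(rich$dataset$n, na.rm = TRUE), 50)
  expect_gt(max(rich$dataset$n, na.rm = TRUE), 15)
})

test_that("empirical feature means track the generative parameters", {
  sim <- simulate_dataset(sim_config(J = 300, I = 200, seed = 54))
  emp <- colMeans(sim$dataset$Y / sim$dataset$n, na.rm = TRUE)
  expect_gte(cor(emp, sim$truth$mu), 0.9)
})

test_that("simulated data reproduce a mean-overdispersion trend", {
  sim <- simulate_dataset(sim_config(J = 300, I = 200, seed = 55))
  theta <- sim$dataset$Y / sim$dataset$n
  m <- colMeans(theta, na.rm = TRUE)
  v <- apply(theta, 2, var, na.rm = TRUE)
  ok <- m > 0.02 & m < 0.98 & is.finite(v)
  fit <- lm(log(v[ok] + 1e-4) ~ poly(m[ok], 2))
  expect_gt(summary(fit)$r.squared, 0.1) # non-flat relationship
})

test_that("two-group perturbations hit the exact configured subset", {
  cfg <- sim_config(J = 300, I = 30, seed = 56)
  sim <- simulate_two_groups(cfg, prop_perturbed = 0.15, lor_offset = 2,
                             target = "gamma")
  pert <- sim$truth$perturbation == "DV"
  expect_equal(sum(pert), 45) # 15% of 300 exactly
  expect_equal(abs(qlogis(sim$truth$gamma_B[pert]) -
                     qlogis(sim$truth$gamma[pert])),
               rep(2, 45), tolerance = 1e-9)
  expect_equal(sim$truth$gamma_B[!pert], sim$truth$gamma[!pert])
  # gamma shifts move epsilon by the same signed offset
  expect_equal(sim$truth$epsilon_B - sim$truth$epsilon,
               sim$truth$lor_offset, tolerance = 1e-9)
  expect_true(all(sim$truth$lor_offset[pert] %in% c(-2, 2)))
  # mu-targeted perturbation shifts logit means instead
  sim_mu <- simulate_two_groups(cfg, prop_perturbed = 0.15, lor_offset = 3,
                                target = "mu")
  pm <- sim_mu$truth$perturbation == "DM"
  expect_equal(abs(qlogis(sim_mu$truth$mu_B[pm]) -
                     qlogis(sim_mu$truth$mu[pm])), rep(3, 45),
               tolerance = 1e-6)
  expect_equal(sim_mu$truth$gamma_B, sim_mu$truth$gamma)
  expect_error(simulate_two_groups(cfg, lor_offset = 0), "positive")
})

test_that("call evaluation reproduces hand-enumerated confusion ratios", {
  truth <- data.frame(feature_id = paste0("f", 1:60),
                      perturbation = c(rep("DV", 45), rep("null", 15)))
  truth$perturbation <- c(rep("DV", 45), rep("null", 15))
  # 30 true positives, 5 false positives
  calls <- setNames(rep(FALSE, 60), truth$feature_id)
  calls[1:30] <- TRUE
  calls[46:50] <- TRUE
  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$power, 30 / 45)
  expect_equal(ev$fdp, 5 / 35)
  expect_equal(ev$type_I_error, 5 / 15)
  # perfect and all-in callers
  perfect <- setNames(truth$perturbation == "DV", truth$feature_id)
  expect_equal(evaluate_calls(perfect, truth),
               list(power = 1, fdp = 0, type_I_error = 0))
  all_in <- setNames(rep(TRUE, 60), truth$feature_id)
  ev2 <- evaluate_calls(all_in, truth)
  expect_equal(ev2$power, 1)
  expect_equal(ev2$type_I_error, 1)
  expect_equal(ev2$fdp, 15 / 60)
  none <- setNames(rep(FALSE, 60), truth$feature_id)
  expect_equal(evaluate_calls(none, truth)$fdp, 0)
  expect_error(evaluate_calls(setNames(TRUE, "zzz"), truth), "absent")
})

test_that("down-sampling produces the expected table and tracks the full fit", {
  sim <- simulate_dataset(sim_config(J = 60, I = 80, seed = 57))
  tab <- downsample_experiment(sim$dataset, sizes = c(20, 60), reps = 2,
                               seed = 57, config = quick_fit(seed = 57))
  expect_equal(nrow(tab), 2 * 2 * 2) # sizes x reps x methods
  expect_setequal(unique(tab$method), c("hierarchical", "bb_mle"))
  # correlations should be non-trivial and improve with subset size
  hier <- tab[tab$method == "hierarchical", ]
  m20 <- mean(hier$correlation[hier$size == 20])
  m60 <- mean(hier$correlation[hier$size == 60])
  expect_gt(m60, m20)
  expect_error(downsample_experiment(sim$dataset, sizes = 80),
               "smaller than")
})
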