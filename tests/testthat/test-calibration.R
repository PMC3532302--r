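test_that("observed_round validates its series", {
  expect_error(observed_round(numeric(0), numeric(0)), "empty")
  expect_error(observed_round(c(0, 1), c(1, 2, 3)), "length")
  expect_error(observed_round(c(0, 0), c(1, 2)), "increasing")
  expect_error(observed_round(c(0, 1), c(-1, 2)), "R_obs")
  expect_error(observed_round(c(0, 1), c(1, 2), treatment = "X"), "treatment")
  obs <- observed_round(c(0, 5, 10), c(50, 52, 49), treatment = "CP")
  expect_s3_class(obs, "observed_round")
})

test_that("rmse matches its definition", {
  p <- cpr_params(phi_max = 16.5)
  traj <- integrate_round(p, dt_out = 5)
  obs <- observed_round(traj$t, traj$R)
  expect_equal(rmse(traj, obs), 0)
  obs_off <- observed_round(traj$t, traj$R + 3)
  expect_equal(rmse(traj, obs_off), 3, tolerance = 1e-12)
  # direct-formula oracle on a random small case
  set.seed(7)
  idx <- sort(sample(nrow(traj), 10))
  robs <- pmax(0, traj$R[idx] + rnorm(10))
  obs_r <- observed_round(traj$t[idx], robs)
  expect_equal(rmse(traj, obs_r), sqrt(mean((traj$R[idx] - robs)^2)),
               tolerance = 1e-12)
  expect_error(rmse(traj, observed_round(p$T + 10, 5)), "covered")
})

test_that("rmse is stable under output-grid refinement", {
  p <- cpr_params(phi_max = 12)
  obs <- generate_round(p, noise_sd = 2, seed = 5)
  r1 <- rmse(integrate_round(p, dt_out = 1), obs)
  r2 <- rmse(integrate_round(p, dt_out = 0.5), obs)
  expect_lt(abs(r1 - r2), 1e-3 * p$K)
})

test_that("one-parameter calibration recovers known discount factors", {
  base <- cpr_params()
  # noiseless recovery away from the boundary
  obs <- generate_round(cpr_params(phi_max = 20), noise_sd = 0, seed = 1)
  fit <- fit_phi_max(obs, base)
  expect_lt(abs(fit$estimates[["phi_max"]] - 20), 0.05)
  expect_lt(fit$rmse_at_optimum, 1e-6)
  expect_false(fit$ill_identified)
  expect_true(all(fit$rmse_at_optimum <= fit$trace$value + 1e-12, na.rm = TRUE))
  # collapse regime: generated at phi_max = 0, estimate below 1
  obs0 <- generate_round(cpr_params(phi_max = 0), noise_sd = 0, seed = 2)
  fit0 <- fit_phi_max(obs0, base)
  expect_lt(fit0$estimates[["phi_max"]], 1)
})

test_that("calibration is deterministic given identical inputs", {
  obs <- generate_round(cpr_params(phi_max = 9), noise_sd = 2, seed = 11)
  f1 <- fit_phi_max(obs, cpr_params())
  f2 <- fit_phi_max(obs, cpr_params())
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$trace, f2$trace)
})

test_that("three-parameter calibration recovers and dominates", {
  base <- cpr_params()
  # truth at the base decay shape: the triple is recovered within the
  # refined grid resolution
  obs <- generate_round(cpr_params(phi_max = 20), noise_sd = 0, seed = 3)
  fit3 <- fit_three_params(obs, base, n_grid = c(12, 7, 7))
  expect_lt(abs(fit3$estimates[["phi_max"]] - 20), 40 / 11)
  expect_lt(abs(fit3$estimates[["a"]] - base$a), 25 / 6)
  expect_lt(abs(fit3$estimates[["b"]] - base$b), 0.5 / 6)
  expect_lt(fit3$rmse_at_optimum, 1e-3)
  # truth off the base shape: phi_max and the decay timing trade off along
  # a collapse-time ridge, so only the fit quality (not the exact triple)
  # is asserted, together with nested-model dominance
  obs2 <- generate_round(update_params(base, phi_max = 20, a = 18, b = 0.72),
                         noise_sd = 0, seed = 3)
  fit3b <- fit_three_params(obs2, base, n_grid = c(12, 7, 7))
  fit1b <- fit_phi_max(obs2, base)
  expect_lte(fit3b$rmse_at_optimum, fit1b$rmse_at_optimum + 1e-9)
  expect_lt(fit3b$rmse_at_optimum, 0.5)
})

test_that("a constant saturated series is flagged ill-identified", {
  # R pinned at K carries no harvest signal: many parameter values fit alike
  obs <- observed_round(seq(0, 240, by = 5), rep(100, 49))
  fit <- fit_three_params(obs, cpr_params(), n_grid = c(10, 5, 5))
  expect_true(fit$ill_identified)
})

test_that("sensitivity scans dip at the fitted optimum and shift up elsewhere", {
  base <- cpr_params()
  obs <- generate_round(cpr_params(phi_max = 20), noise_sd = 0, seed = 4)
  fit3 <- fit_three_params(obs, base, n_grid = c(12, 7, 7))
  expect_error(sensitivity_scan(obs, fit_phi_max(obs, base), base), "three")
  sc <- sensitivity_scan(obs, fit3, base)
  expect_named(sc, c("phi_max", "a", "b"))
  for (pn in names(sc)) {
    expect_lte(min(sc[[pn]]$rmse, na.rm = TRUE), fit3$rmse_at_optimum + 0.01)
    i <- which.min(sc[[pn]]$rmse)
    expect_lt(abs(sc[[pn]][[pn]][i] - fit3$estimates[[pn]]), 1e-6)
  }
  # perturbing a held-fixed parameter shifts the phi_max curve upward
  res_pert <- fit3
  res_pert$estimates[["b"]] <- fit3$estimates[["b"]] + 0.1
  sc_pert <- sensitivity_scan(obs, res_pert, base,
                              grids = list(phi_max = seq(5, 35, by = 5)))
  sc_ref <- sensitivity_scan(obs, fit3, base,
                             grids = list(phi_max = seq(5, 35, by = 5)))
  common <- intersect(sc_pert$phi_max$phi_max, sc_ref$phi_max$phi_max)
  up <- sc_pert$phi_max$rmse[sc_pert$phi_max$phi_max %in% common]
  ref <- sc_ref$phi_max$rmse[sc_ref$phi_max$phi_max %in% common]
  expect_true(mean(up - ref, na.rm = TRUE) > 0)
})
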