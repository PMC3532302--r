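test_that("compiled integrator agrees with an R-level reference integration", {
  for (p in list(cpr_params(phi_max = 16.5, T = 40),
                 cpr_params(phi_max = 0, T = 40, punishment_on = TRUE))) {
    traj <- integrate_round(p, dt = 0.05, dt_out = 1)
    ref <- rk4_reference(p, dt = 0.05, T = p$T)
    i <- nrow(traj)
    expect_equal(traj$R[i], ref[["R"]], tolerance = 1e-10)
    expect_equal(traj$H[i], ref[["H"]], tolerance = 1e-10)
    expect_equal(traj$theta[i], ref[["theta"]], tolerance = 1e-10)
  }
})

test_that("trajectory structure and basic invariants hold", {
  p <- cpr_params(phi_max = 16.5)
  traj <- integrate_round(p)
  expect_s3_class(traj, "cpr_trajectory")
  expect_equal(traj$t[1], 0)
  expect_equal(traj$t[nrow(traj)], p$T)
  expect_true(all(traj$R >= 0))
  expect_true(all(traj$A >= 0 & traj$A <= 1))
  expect_true(all(traj$theta >= 0 & traj$theta <= 1))
  # omega non-increasing while the integrand is non-negative (R <= K)
  expect_true(all(diff(traj$omega) <= 1e-12))
  # harvest non-decreasing with punishment off
  expect_true(all(diff(traj$H) >= -1e-12))
  expect_error(integrate_round(p, dt = 2, dt_out = 1), "dt")
  expect_error(integrate_round(p, dt_out = 7), "divide")
})

test_that("an engineered equilibrium stays constant when adaptation is off", {
  # G(50, theta*) = g(50): 5*50/(k+50) = 0.75 -> k = 850/3 -> theta*
  theta_star <- sqrt((850 / 3 - 10) / 400)
  p <- cpr_params(delta = 0)
  traj <- integrate_round(p, init = list(R = 50, H = 0, theta = theta_star))
  expect_lt(max(abs(traj$R - 50)), 1e-8)
  expect_lt(max(abs(traj$theta - theta_star)), 1e-12)
})

test_that("conservation links production, stock and harvest", {
  for (phi in c(0, 16.5, 32.5)) {
    p <- cpr_params(phi_max = phi)
    traj <- integrate_round(p)
    gint <- attr(traj, "gint")
    dev <- max(abs(traj$R + traj$H - gint - traj$R[1]))
    expect_lt(dev, 1e-4 * p$K)
  }
})

test_that("cooperation series matches its definition and conventions", {
  p <- cpr_params()
  # theta at the floor: no restraint, A = 0
  traj0 <- integrate_round(cpr_params(phi_max = 0),
                           init = list(R = 50, H = 0, theta = 0))
  expect_lt(max(traj0$A), 1e-9)
  # frozen hand value: theta = 1, R = 50 -> 1 - (50/460)/(50/60) = 1 - 60/460
  A_hand <- 1 - (50 / 460) / (50 / 60)
  p1 <- cpr_params()
  expect_equal(cooperation_series(data.frame(R = 50, theta = 1), p1), A_hand,
               tolerance = 1e-12)
  # A defined as 0 at exhausted resource
  expect_equal(cooperation_series(data.frame(R = 0, theta = 0.5), p1), 0)
})

test_that("relative productivity integrates future growth", {
  p <- cpr_params(phi_max = 32.5)
  traj <- integrate_round(p)
  om <- relative_productivity(traj)
  expect_equal(om[length(om)], 0)
  expect_equal(om, traj$omega)
  # no productivity at carrying capacity: hold R = K via h_max -> 0, delta 0
  pK <- cpr_params(h_max = 1e-12, delta = 0)
  trajK <- integrate_round(pK, init = list(R = 100, H = 0, theta = 0.5))
  expect_lt(max(abs(relative_productivity(trajK))), 1e-8)
  # restrained harvesting buys more future productivity than myopia
  om0 <- relative_productivity(integrate_round(cpr_params(phi_max = 0)))
  expect_gt(om[1], om0[1])
  # trapezoid oracle on the output grid
  g <- logistic_growth(traj$R, p)
  om_hand <- rev(c(0, cumsum(rev(diff(traj$t) * (g[-length(g)] + g[-1]) / 2)))) / traj$R[1]
  expect_series_equal(om, om_hand, tol = 1e-12)
})

test_that("affinity inversion round-trips the Monod law and masks degeneracy", {
  p <- cpr_params(phi_max = 16.5)
  traj <- integrate_round(p)
  aff <- affinity_from_observed(traj$R, traj$G, p)
  ok <- !is.na(aff)
  expect_gt(sum(ok), 100)
  expect_series_equal(aff[ok], traj$affinity[ok], tol = 1e-9)
  # all-zero harvest: fully masked, with a warning
  expect_warning(aff0 <- affinity_from_observed(c(10, 20), c(0, 0), p), "masked")
  expect_true(all(is.na(aff0)))
  # half-saturation identity: G at half its maximum when R = k(theta)
  k <- half_saturation(0.6, p)
  expect_equal(affinity_from_observed(k, p$n * p$h_max / 2, p), 1 / k,
               tolerance = 1e-12)
  expect_error(affinity_from_observed(c(1, 2), c(1, 2, 3), p), "length")
})

test_that("total harvest equals the integrated net harvest rate", {
  expect_equal(total_harvest(integrate_round(cpr_params(h_max = 1e-300))), 0,
               tolerance = 1e-10)
  p <- cpr_params(phi_max = 16.5, punishment_on = TRUE)
  traj <- integrate_round(p, dt = 0.02, dt_out = 0.25)
  # independent quadrature of G - P on a fine output grid
  net <- traj$G - traj$P
  quad <- sum(diff(traj$t) * (net[-length(net)] + net[-1]) / 2)
  expect_equal(total_harvest(traj), quad, tolerance = 1e-3)
})

test_that("cooperation erodes at the end of every default round", {
  for (phi in c(0, 8.5, 16.5, 32.5)) {
    traj <- integrate_round(cpr_params(phi_max = phi))
    tail_idx <- traj$t >= 0.9 * cpr_params()$T
    expect_true(all(diff(traj$theta[tail_idx]) <= 1e-9))
  }
})
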