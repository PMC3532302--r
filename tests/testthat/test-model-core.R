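p0 <- cpr_params()

test_that("logistic growth has its fixed points and symmetric maximum", {
  expect_equal(logistic_growth(0, p0), 0)
  expect_equal(logistic_growth(p0$K, p0), 0)
  expect_equal(logistic_growth(p0$K / 2, p0), p0$r * p0$K / 4)  # = 0.75
  expect_error(logistic_growth(-1, p0), "R")
  # maximum at K/2 by grid scan
  R <- seq(0, p0$K, by = 0.5)
  expect_equal(R[which.max(logistic_growth(R, p0))], p0$K / 2)
})

test_that("half-saturation interpolates k_min..k_min+k_var and is increasing", {
  expect_equal(half_saturation(0, p0), p0$k_min)
  expect_equal(half_saturation(1, p0), p0$k_min + p0$k_var)
  # hand evaluation of the quadratic default form
  expect_equal(half_saturation(0.5, p0), 10 + 400 * 0.25)
  expect_error(half_saturation(1.5, p0), "theta")
  th <- seq(0, 1, by = 0.01)
  expect_true(all(diff(half_saturation(th, p0)) > 0))
})

test_that("harvest rate follows Monod kinetics", {
  expect_equal(harvest_rate(0, 0.3, p0), 0)
  # asymptote n*h_max as R grows large
  expect_lt(abs(harvest_rate(1e9, 0, p0) - p0$n * p0$h_max), 1e-5)
  # hand evaluation at the published example values (h_max = 0.25)
  p_ex <- cpr_params(h_max = 0.25)
  expect_equal(harvest_rate(50, 0, p_ex), 5 * 0.25 * 50 / 60, tolerance = 1e-12)
  # monotone increasing in R, decreasing in theta
  expect_true(all(diff(harvest_rate(seq(1, 100, 1), 0.5, p0)) > 0))
  expect_true(all(diff(harvest_rate(50, seq(0, 1, 0.05), p0)) < 0))
})

test_that("punishment is a Gaussian kernel gated by the treatment", {
  p_on <- cpr_params(punishment_on = TRUE)
  expect_equal(punishment_rate(0.3, p0), 0)  # off by default
  expect_equal(punishment_rate(p_on$theta_p, p_on), p_on$p)
  th <- p_on$theta_p + 3 * p_on$sigma_p
  expect_equal(punishment_rate(th, p_on), p_on$p * exp(-4.5), tolerance = 1e-12)
  # even about theta_p
  expect_equal(punishment_rate(p_on$theta_p + 0.1, p_on),
               punishment_rate(p_on$theta_p - 0.1, p_on))
})

test_that("discount factor is a trait-scaled logistic decay in time", {
  p <- cpr_params(phi_max = 16.5, a = 15, b = 0.8)
  expect_equal(discount_factor(0.7, 10, cpr_params(phi_max = 0)), 0)
  expect_equal(discount_factor(1, 0, p), 16.5 / (1 + exp(-12)), tolerance = 1e-12)
  expect_equal(discount_factor(1, p$T, p), 16.5 / (1 + exp(3)), tolerance = 1e-12)
  expect_equal(discount_factor(0, 100, p), 0)  # no weight at the trait floor
  expect_error(discount_factor(0.5, -1, p), "t must")
  expect_error(discount_factor(0.5, p$T + 1, p), "t must")
  # non-increasing in t, increasing in theta
  expect_true(all(diff(discount_factor(1, seq(0, p$T, 5), p)) < 0))
  expect_true(all(diff(discount_factor(seq(0, 1, 0.1), 0, p)) > 0))
})

test_that("future productivity multiplies the discount weight into g(R)", {
  p <- cpr_params(phi_max = 16.5)
  expect_equal(future_productivity(30, 0.4, 10, cpr_params(phi_max = 0)), 0)
  expect_equal(future_productivity(p$K, 0.9, 0, p), 0)
  f <- future_productivity(p$K / 2, 1, 0, p)
  expect_equal(f, discount_factor(1, 0, p) * 0.75, tolerance = 1e-12)
  expect_lt(abs(f - p$phi_max * 0.75), p$phi_max * 0.75 * 1e-4)
})

test_that("fitness assembles harvest, future productivity and punishment", {
  p_my <- cpr_params(phi_max = 0)
  expect_equal(fitness(50, 0.5, 0, p_my), harvest_rate(50, 0.5, p_my))
  p_on <- cpr_params(punishment_on = TRUE, phi_max = 16.5)
  expect_equal(fitness(0, 0.5, 0, p_on), -punishment_rate(0.5, p_on))
  # frozen term-by-term hand evaluation at phi_max = 16.5, t = 0:
  # G = 5*50/160 = 1.5625; F = 16.5*0.5*D(0)*0.75 with
  # D(0) = 1/(1+exp(-9.75)); P = 0
  p <- cpr_params(phi_max = 16.5)
  D0 <- 1 / (1 + exp(15 * (0 - 0.65)))
  expect_equal(fitness(50, 0.5, 0, p), 1.5625 + 16.5 * 0.5 * D0 * 0.75,
               tolerance = 1e-12)
})

test_that("analytic fitness gradient matches central finite differences", {
  set.seed(42)
  cfgs <- list(cpr_params(phi_max = 16.5),
               cpr_params(phi_max = 32.5, punishment_on = TRUE),
               cpr_params(phi_max = 0, punishment_on = TRUE),
               cpr_params(phi_max = 5, q_phi = 2, q_k = 3))
  h <- 1e-6
  for (p in cfgs) {
    R <- runif(250, 0, p$K)
    th <- runif(250, 0.01, 0.99)
    tt <- runif(250, 0, p$T)
    for (i in seq_len(250)) {
      fd <- (fitness(R[i], th[i] + h, tt[i], p) -
               fitness(R[i], th[i] - h, tt[i], p)) / (2 * h)
      an <- fitness_gradient(R[i], th[i], tt[i], p)
      expect_equal(an, fd, tolerance = 1e-5)
    }
  }
})

test_that("gradient sign structure drives the trade-off", {
  # myopic users: gradient is the (negative) harvest derivative
  p_my <- cpr_params(phi_max = 0)
  expect_lt(fitness_gradient(50, 0.5, 0, p_my), 0)
  # at the punishment peak the punishment term drops out of the gradient
  p_on <- cpr_params(phi_max = 0, punishment_on = TRUE)
  p_off <- cpr_params(phi_max = 0)
  expect_equal(fitness_gradient(50, p_on$theta_p, 0, p_on),
               fitness_gradient(50, p_off$theta_p, 0, p_off))
})

test_that("rhs assembles the three coupled equations", {
  p <- cpr_params(phi_max = 16.5)
  # extinct resource: nothing grows, nothing is harvested
  d0 <- rhs(c(R = 0, H = 3, theta = 0.5), 10, p)
  expect_equal(unname(d0[c("dR", "dH")]), c(0, 0))
  # interior state matches the component oracle term by term
  st <- c(R = 50, H = 0, theta = 0.8)
  d <- rhs(st, 0, p)
  expect_equal(d[["dR"]], logistic_growth(50, p) - harvest_rate(50, 0.8, p))
  expect_equal(d[["dH"]], harvest_rate(50, 0.8, p) - punishment_rate(0.8, p))
  expect_equal(d[["dtheta"]], p$delta * fitness_gradient(50, 0.8, 0, p))
  # projection: at the upper bound an outward (positive) gradient is zeroed
  expect_gt(fitness_gradient(50, 1, 0, p), 0)
  d_out <- rhs(c(R = 50, H = 0, theta = 1), 0, p)
  expect_equal(d_out[["dtheta"]], 0)
  # ...while an inward (negative) gradient passes through unchanged
  p_my <- cpr_params(phi_max = 0)
  expect_lt(fitness_gradient(50, 1, 0, p_my), 0)
  d_in <- rhs(c(R = 50, H = 0, theta = 1), 0, p_my)
  expect_equal(d_in[["dtheta"]], p_my$delta * fitness_gradient(50, 1, 0, p_my))
  expect_error(rhs(c(R = -1, H = 0, theta = 0.5), 0, p), "R")
  expect_error(rhs(c(R = 1, H = Inf, theta = 0.5), 0, p), "H")
})

test_that("myopic adaptation always intensifies harvesting", {
  p <- cpr_params(phi_max = 0)
  for (th in seq(0.05, 0.95, by = 0.1)) {
    d <- rhs(c(R = 30, H = 0, theta = th), 17, p)
    expect_lt(d[["dtheta"]], 0)
  }
})
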