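# Shared fixtures and independent oracles.

default_init <- list(R = 50, H = 0, theta = 0.8)

# Independent R-level RK4 integrator over the package's rhs(), used as the
# dual-route oracle for the compiled integrator. Deliberately simple and
# slow; keep horizons short.
rk4_reference <- function(params, init = default_init, dt = 0.05, T = params$T) {
  y <- c(R = init$R, H = init$H, theta = init$theta)
  clamp <- function(y) {
    y[["R"]] <- max(y[["R"]], 0)
    y[["theta"]] <- min(max(y[["theta"]], params$theta_min), params$theta_max)
    y
  }
  n <- round(T / dt)
  t <- 0
  for (i in seq_len(n)) {
    k1 <- rhs(y, t, params)
    k2 <- rhs(clamp(y + dt / 2 * k1), t + dt / 2, params)
    k3 <- rhs(clamp(y + dt / 2 * k2), t + dt / 2, params)
    k4 <- rhs(clamp(y + dt * k3), min(t + dt, params$T), params)
    y <- clamp(y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    t <- t + dt
  }
  y
}

# fast parameter set for tests that only need structure, not the full round
short_params <- function(...) cpr_params(T = 40, ...)

expect_series_equal <- function(a, b, tol = 1e-10) {
  expect_equal(length(a), length(b))
  expect_lt(max(abs(a - b)), tol)
}
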