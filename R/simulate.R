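#' Integrate one round of the adaptive harvest model
#'
#' Runs a fixed-step 4th-order Runge-Kutta integration of the coupled system
#' over `[0, T]` and attaches all derived diagnostic series: instantaneous
#' harvest rate `G`, discount factor `phi`, punishment rate `P`, cooperation
#' `A`, relative resource productivity `omega`, and resource affinity
#' `1/k(theta)`. The resource is floored at zero (absorbing collapse) and the
#' trait is projected onto its bounds.
#'
#' @param params A [cpr_params()] object.
#' @param init Named list or vector with initial state `R`, `H`, `theta`
#'   (default `R = 50`, `H = 0`, `theta = 0.8`).
#' @param dt Solver step (time units); must be `<= dt_out`.
#' @param dt_out Output grid step (time units); must divide `T`.
#' @return A `cpr_trajectory`: a data frame with columns
#'   `t, R, H, theta, G, phi, P, A, omega, affinity`, plus attributes
#'   `params` (the parameter snapshot), `H_T` (total harvest), and `gint`
#'   (cumulative gross production series, used by conservation checks).
#' @export
#' @examples
#' traj <- integrate_round(cpr_params(phi_max = 16.5))
#' total_harvest(traj)
integrate_round <- function(params, init = list(R = 50, H = 0, theta = 0.8),
                            dt = 0.05, dt_out = 1) {
  stopifnot(inherits(params, "cpr_params"))
  if (dt > dt_out + 1e-12)
    stop("dt must be <= dt_out", call. = FALSE)
  n_out <- params$T / dt_out
  if (abs(n_out - round(n_out)) > 1e-9)
    stop("dt_out must divide the round duration T", call. = FALSE)
  R0 <- init[["R"]]; H0 <- init[["H"]]; theta0 <- init[["theta"]]
  check_R(R0)
  theta0 <- check_theta(theta0, params)
  m <- .integrate_round_cpp(unclass(params), R0, H0, theta0, dt, dt_out)

  traj <- data.frame(t = m[, "t"], R = m[, "R"], H = m[, "H"],
                     theta = m[, "theta"])
  traj$G <- harvest_rate(traj$R, traj$theta, params)
  traj$phi <- discount_factor(traj$theta, traj$t, params)
  traj$P <- punishment_rate(traj$theta, params)
  traj$A <- cooperation_values(traj$R, traj$theta, params)
  traj$omega <- omega_values(traj$t, traj$R, R0, params)
  traj$affinity <- 1 / half_saturation(traj$theta, params)

  attr(traj, "params") <- params
  attr(traj, "H_T") <- traj$H[nrow(traj)]
  attr(traj, "gint") <- m[, "gint"]
  attr(traj, "dt") <- dt
  class(traj) <- c("cpr_trajectory", "data.frame")
  traj
}

#' @export
print.cpr_trajectory <- function(x, ...) {
  prm <- attr(x, "params")
  cat(sprintf(
    "CPR round trajectory: T = %g, %d output points, phi_max = %g\n",
    prm$T, nrow(x), prm$phi_max))
  cat(sprintf("  final state: R = %.3f, theta = %.3f; total harvest H_T = %.3f\n",
              x$R[nrow(x)], x$theta[nrow(x)], attr(x, "H_T")))
  invisible(x)
}

# cooperation A = (G_max - G) / G_max with G_max evaluated at theta_min;
# defined as 0 where R = 0 (no foregone harvest exists).
cooperation_values <- function(R, theta, params) {
  G_max <- params$n * params$h_max * R / (params$k_min + R)
  G <- harvest_rate(R, theta, params)
  A <- ifelse(R > 0, (G_max - G) / G_max, 0)
  pmin(pmax(A, 0), 1)
}

# omega(t) = int_t^T g(R(s)) ds / R(0), trapezoidal rule on the output grid
omega_values <- function(t, R, R0, params) {
  if (R0 <= 0) stop("relative productivity requires R(0) > 0", call. = FALSE)
  g <- logistic_growth(R, params)
  nt <- length(t)
  seg <- diff(t) * (g[-nt] + g[-1]) / 2
  rev(c(0, cumsum(rev(seg)))) / R0
}

#' Cooperation series of a trajectory
#'
#' Cooperation is the non-realized current harvest normalized to the maximum
#' possible harvest (the harvest rate the group would realize at the lower
#' trait bound): `A = (G_max(R) - G(R, theta)) / G_max(R)`, in `[0, 1]`.
#' Where the resource is exhausted (`R = 0`) cooperation is defined as 0.
#'
#' @param traj A `cpr_trajectory`.
#' @param params Parameter set; defaults to the trajectory's snapshot.
#' @return Numeric vector `A(t)` aligned with `traj$t`.
#' @export
cooperation_series <- function(traj, params = attr(traj, "params")) {
  cooperation_values(traj$R, traj$theta, params)
}

#' Relative resource productivity series
#'
#' `omega(t)` is the cumulated resource productivity from `t` to the end of
#' the round, normalized to the initial resource level:
#' `omega(t) = (int_t^T g(R(s)) ds) / R(0)`. Values above 1 indicate that
#' the remaining production exceeds the whole initial stock — only possible
#' under restrained harvesting.
#'
#' @inheritParams cooperation_series
#' @return Numeric vector `omega(t)` aligned with `traj$t`.
#' @export
relative_productivity <- function(traj, params = attr(traj, "params")) {
  omega_values(traj$t, traj$R, traj$R[1], params)
}

#' Resource affinity inferred from observed series
#'
#' Inverts the Monod harvest law on paired observations of resource level and
#' harvest rate: `k = R_obs * (n * h_max - G_obs) / G_obs`, affinity `= 1/k`.
#' Entries where the inversion is ill-posed (harvest at or below zero, at or
#' above saturation, or vanishing resource) are masked with `NA`.
#'
#' @param R_obs Observed resource series (resource units).
#' @param G_obs Observed harvest-rate series, aligned with `R_obs`.
#' @param params A [cpr_params()] object (supplies `n`, `h_max`).
#' @param eps Masking tolerance (default `1e-6`).
#' @return Numeric vector of affinities (1/resource units) with `NA` at
#'   masked entries; warns if every entry is masked.
#' @export
affinity_from_observed <- function(R_obs, G_obs, params, eps = 1e-6) {
  if (length(R_obs) != length(G_obs))
    stop("R_obs and G_obs must have the same length", call. = FALSE)
  if (any(R_obs < 0, na.rm = TRUE) || any(G_obs < 0, na.rm = TRUE))
    stop("observed series must be >= 0", call. = FALSE)
  sat <- params$n * params$h_max
  ok <- is.finite(R_obs) & is.finite(G_obs) &
    G_obs > eps & G_obs < sat * (1 - eps) & R_obs > eps
  k <- rep(NA_real_, length(R_obs))
  k[ok] <- R_obs[ok] * (sat - G_obs[ok]) / G_obs[ok]
  if (!any(ok)) warning("all entries masked in affinity inversion")
  1 / k
}

#' Total harvest of a round
#'
#' The cumulated net harvest at the end of the round, `H_T = H(T)`.
#'
#' @param traj A `cpr_trajectory`.
#' @return Scalar total harvest (resource units).
#' @export
total_harvest <- function(traj) {
  traj$H[nrow(traj)]
}
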