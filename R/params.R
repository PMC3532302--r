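#' Model parameters for the adaptive harvest model
#'
#' Constructs and validates the full parameter set of the coupled
#' resource/harvest/trait system. All arguments have defaults chosen to
#' reproduce the qualitative regimes of the model: immediate resource
#' collapse when future pay-offs are ignored (`phi_max = 0`), and delayed
#' collapse with larger total harvest as `phi_max` grows.
#'
#' @param r Maximum specific resource growth rate (1/time).
#' @param K Carrying capacity (resource units).
#' @param h_max Maximum specific harvest rate per user (resource units/time).
#' @param n Number of users (count).
#' @param k_min Minimum half-saturation constant (resource units).
#' @param k_var Variable half-saturation amplitude (resource units).
#' @param q_k Half-saturation trait exponent (dimensionless).
#' @param theta_min,theta_max Bounds of the harvest trait (dimensionless).
#' @param delta Adaptation rate constant (trait units^2 per fitness unit per
#'   time); the speed of learning of the group.
#' @param p Specific punishment rate (fitness units/time).
#' @param theta_p Trait value at which punishment is maximal.
#' @param sigma_p Punishment standard deviation (trait units).
#' @param phi_max Maximum discount factor (dimensionless weight on future
#'   productivity); the only parameter varied between rounds in the
#'   one-parameter calibration mode.
#' @param a,b Shape parameters of the logistic decay of the discount factor
#'   over the round (dimensionless; `a` sets the speed, `b` the timing as a
#'   fraction of the round).
#' @param q_phi Discount trait exponent (dimensionless).
#' @param T Round duration (time units).
#' @param punishment_on Logical; whether punishment is available in the round.
#'
#' @return An object of class `cpr_params` (a named list).
#' @export
#' @examples
#' p <- cpr_params()
#' p$phi_max
#' p2 <- cpr_params(phi_max = 16.5, punishment_on = TRUE)
cpr_params <- function(r = 0.03, K = 100, h_max = 1, n = 5,
                       k_min = 10, k_var = 400, q_k = 2,
                       theta_min = 0, theta_max = 1, delta = 0.5,
                       p = 0.05, theta_p = 0.5, sigma_p = 0.15,
                       phi_max = 0, a = 15, b = 0.65, q_phi = 1,
                       T = 240, punishment_on = FALSE) {
  prm <- list(r = r, K = K, h_max = h_max, n = n,
              k_min = k_min, k_var = k_var, q_k = q_k,
              theta_min = theta_min, theta_max = theta_max, delta = delta,
              p = p, theta_p = theta_p, sigma_p = sigma_p,
              phi_max = phi_max, a = a, b = b, q_phi = q_phi,
              T = T, punishment_on = isTRUE(punishment_on))
  validate_cpr_params(prm)
  class(prm) <- "cpr_params"
  prm
}

validate_cpr_params <- function(prm) {
  num1 <- function(key, positive = FALSE, nonneg = FALSE) {
    v <- prm[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", key, "' must be a finite numeric scalar", call. = FALSE)
    if (positive && v <= 0)
      stop("parameter '", key, "' must be > 0", call. = FALSE)
    if (nonneg && v < 0)
      stop("parameter '", key, "' must be >= 0", call. = FALSE)
    invisible(v)
  }
  for (key in c("r", "K", "h_max", "k_min", "sigma_p", "T"))
    num1(key, positive = TRUE)
  # delta = 0 switches adaptation off (a legitimate degenerate regime)
  for (key in c("delta", "k_var", "phi_max", "p", "q_k", "q_phi"))
    num1(key, nonneg = TRUE)
  for (key in c("theta_min", "theta_max", "theta_p", "a", "b")) num1(key)
  if (prm$n < 1 || prm$n != round(prm$n))
    stop("parameter 'n' must be a positive integer", call. = FALSE)
  if (prm$theta_min >= prm$theta_max)
    stop("parameter 'theta_min' must be < theta_max", call. = FALSE)
  invisible(prm)
}

#' @export
print.cpr_params <- function(x, ...) {
  cat("Adaptive CPR model parameters\n")
  cat(sprintf("  resource: r = %g, K = %g\n", x$r, x$K))
  cat(sprintf("  harvest:  h_max = %g, n = %d, k = %g + %g * theta^%g\n",
              x$h_max, as.integer(x$n), x$k_min, x$k_var, x$q_k))
  cat(sprintf("  trait:    theta in [%g, %g], delta = %g\n",
              x$theta_min, x$theta_max, x$delta))
  cat(sprintf("  discount: phi_max = %g, a = %g, b = %g, q_phi = %g\n",
              x$phi_max, x$a, x$b, x$q_phi))
  cat(sprintf("  punish:   %s (p = %g, theta_p = %g, sigma_p = %g)\n",
              if (x$punishment_on) "on" else "off", x$p, x$theta_p, x$sigma_p))
  cat(sprintf("  round:    T = %g\n", x$T))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced and the
#' invariants re-checked.
#'
#' @param params A `cpr_params` object.
#' @param ... Named fields to replace.
#' @return A new `cpr_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "cpr_params"))
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  bad <- setdiff(names(repl), names(unclass(params)))
  if (length(bad) > 0L)
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  prm <- unclass(params)
  prm[names(repl)] <- repl
  validate_cpr_params(prm)
  class(prm) <- "cpr_params"
  prm
}

check_theta <- function(theta, params) {
  if (any(!is.finite(theta)))
    stop("theta must be finite", call. = FALSE)
  eps <- 1e-12
  if (any(theta < params$theta_min - eps) || any(theta > params$theta_max + eps))
    stop("theta outside [theta_min, theta_max]", call. = FALSE)
  pmin(pmax(theta, params$theta_min), params$theta_max)
}

check_R <- function(R) {
  if (any(!is.finite(R)) || any(R < 0))
    stop("resource level R must be finite and >= 0", call. = FALSE)
  R
}
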