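#' Implied exponential discount rate from a maximum discount factor
#'
#' Under exponential discounting, a weight `phi_max` placed on the whole
#' remaining horizon `T` corresponds to the rate `rho` solving
#' `(1 - exp(-rho * T)) / rho = phi_max` (the integral of `exp(-rho * t)`
#' over the round). Solved by bisection to an interval tolerance of `1e-10`.
#' For `phi_max` much smaller than `T` the solution approaches
#' `1 / phi_max`; as `phi_max` approaches `T` it approaches 0
#' (no discounting).
#'
#' @param phi_max Maximum discount factor, `0 < phi_max <= T`. Vectorized.
#' @param T Round duration (time units).
#' @return Discount rate `rho` (1/time), decreasing in `phi_max`.
#' @export
#' @examples
#' discount_rate_from_weight(16.5, 240)  # ~ 1/16.5
discount_rate_from_weight <- function(phi_max, T) {
  if (length(phi_max) > 1L)
    return(vapply(phi_max, discount_rate_from_weight, numeric(1), T = T))
  if (!is.finite(phi_max) || phi_max <= 0)
    stop("phi_max must be > 0", call. = FALSE)
  if (phi_max >= T) {
    if (phi_max > T) warning("phi_max exceeds the horizon T; returning rho = 0")
    return(0)
  }
  f <- function(rho) (1 - exp(-rho * T)) / rho - phi_max
  lo <- .Machine$double.eps
  hi <- max(1, 10 / phi_max)
  while (f(hi) > 0) hi <- hi * 2  # f decreasing; push hi until sign change
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break  # interval below double spacing
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Least-squares logistic fit of discount rate against previous harvest
#'
#' Fits the four-parameter logistic
#' `y = L + (U - L) / (1 + exp(s * (x - m)))` by least squares with
#' multi-start Nelder-Mead (starts built from data quantiles), mirroring the
#' sigmoid value-function relating a round's discount rate to the total
#' harvest realized in the preceding round of the same treatment.
#'
#' @param x Previous-round total harvests.
#' @param y Current-round discount rates.
#' @param n_starts Number of multi-start initializations (default 5).
#' @return A `feedback_fit` list: `par` (named `L`, `U`, `m`, `s`), `rmse`,
#'   `fitted`, `degenerate` flag (flat response: slope unidentified), and
#'   the convergence trace of all starts.
#' @export
fit_logistic_response <- function(x, y, n_starts = 5) {
  if (length(x) != length(y)) stop("x and y must align", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 points", call. = FALSE)

  yr <- range(y); xr <- range(x)
  if (diff(yr) < 1e-12 * max(1, abs(yr[2]))) {
    # constant response: asymptotes collapse, slope is unidentified
    par <- c(L = yr[1], U = yr[2], m = mean(xr), s = 0)
    return(structure(list(par = par, rmse = 0,
                          fitted = rep(mean(y), length(y)),
                          degenerate = TRUE, trace = NULL),
                     class = "feedback_fit"))
  }
  model <- function(p, x) p[1] + (p[2] - p[1]) / (1 + exp(p[4] * (x - p[3])))
  sse <- function(p) {
    if (p[4] < -50 || p[4] > 50) return(Inf)
    r <- y - model(p, x)
    sum(r * r)
  }
  qs <- quantile(x, c(0.2, 0.35, 0.5, 0.65, 0.8), names = FALSE)
  slope0 <- 4 / max(diff(xr), 1e-9)
  starts <- lapply(seq_len(n_starts), function(i) {
    c(yr[1], yr[2], qs[(i - 1) %% length(qs) + 1],
      slope0 * c(1, -1, 2, -2, 0.5)[(i - 1) %% 5 + 1])
  })
  fits <- lapply(starts, function(s0) {
    tryCatch(optim(s0, sse, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
             error = function(e) NULL)
  })
  ok_fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (length(ok_fits) == 0L)
    stop("logistic fit failed to converge from every start", call. = FALSE)
  best <- ok_fits[[which.min(vapply(ok_fits, `[[`, numeric(1), "value"))]]
  p <- best$par
  # orient so that L is the lower and U the upper asymptote
  if (p[1] > p[2]) p <- c(p[2], p[1], p[3], -p[4])
  names(p) <- c("L", "U", "m", "s")
  fitted <- model(c(p[["L"]], p[["U"]], p[["m"]], p[["s"]]), x)
  structure(list(par = p, rmse = sqrt(mean((y - fitted)^2)), fitted = fitted,
                 degenerate = FALSE,
                 trace = data.frame(
                   start = seq_along(fits),
                   value = vapply(fits, function(f)
                     if (is.null(f)) NA_real_ else f$value, numeric(1)))),
            class = "feedback_fit")
}

#' @export
print.feedback_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate logistic fit (flat response); slope unidentified\n")
  } else {
    cat(sprintf(
      "Logistic fit: L = %.4g, U = %.4g, midpoint = %.4g, slope = %.4g (rmse %.4g)\n",
      x$par[["L"]], x$par[["U"]], x$par[["m"]], x$par[["s"]], x$rmse))
  }
  invisible(x)
}

#' Sustainability threshold from the between-round regression intersection
#'
#' Regresses the previous round's maximum discount factor on the current
#' round's (`previous = alpha + beta * current`) and intersects the
#' regression line with the identity line. The fixed point
#' `phi* = alpha / (1 - beta)` separates rounds whose discount factor grows
#' round over round (above) from rounds caught in a downward spiral (below).
#'
#' @param current Current-round `phi_max` values.
#' @param previous Same-treatment previous-round `phi_max` values.
#' @return List with `threshold` (`phi*`), `alpha`, `beta`, and `expansive`
#'   (`TRUE` when `beta < 1`, i.e. the between-round map is contracting
#'   toward the fixed point from above).
#' @export
sustainability_threshold <- function(current, previous) {
  ok <- is.finite(current) & is.finite(previous)
  current <- current[ok]; previous <- previous[ok]
  if (length(current) < 3) stop("need at least 3 pairs", call. = FALSE)
  fit <- lm(previous ~ current)
  alpha <- unname(coef(fit)[1]); beta <- unname(coef(fit)[2])
  if (abs(1 - beta) < 1e-6)
    stop("regression line parallel to the identity: no intersection",
         call. = FALSE)
  list(threshold = alpha / (1 - beta), alpha = alpha, beta = beta,
       expansive = beta < 1)
}

#' Link calibrated rounds to their same-treatment predecessors
#'
#' Builds the between-round analysis table: each round of rounds 2, 3, 5 and
#' 6 (the rounds preceded by a round with the identical treatment, given the
#' treatment switch after round 3) is linked to its predecessor's fitted
#' `phi_max` and total harvest. Rounds 1 and 4 open a new treatment and are
#' excluded. Rounds whose predecessor is missing from the report are skipped
#' with a message.
#'
#' @param report Data frame with one row per calibrated round: columns
#'   `session_id`, `round_index`, `treatment`, `phi_max`, `H_T` (as written
#'   by [calibrate_study()]).
#' @return Data frame of round outcomes with columns `session_id`,
#'   `round_index`, `treatment`, `phi_max_fit`, `H_T`, `previous_phi_max`,
#'   `previous_H_T`.
#' @export
build_round_outcomes <- function(report) {
  need <- c("session_id", "round_index", "treatment", "phi_max", "H_T")
  miss <- setdiff(need, names(report))
  if (length(miss) > 0)
    stop("report lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(report))) {
    row <- report[i, ]
    if (!row$round_index %in% c(2L, 3L, 5L, 6L)) next
    prev <- report[report$session_id == row$session_id &
                     report$round_index == row$round_index - 1L &
                     report$treatment == row$treatment, ]
    if (nrow(prev) != 1L) {
      message(sprintf("round %s/%d: no same-treatment predecessor; skipped",
                      row$session_id, row$round_index))
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      session_id = row$session_id, round_index = row$round_index,
      treatment = row$treatment, phi_max_fit = row$phi_max, H_T = row$H_T,
      previous_phi_max = prev$phi_max, previous_H_T = prev$H_T)
  }
  if (length(out) == 0L)
    return(data.frame(session_id = character(), round_index = integer(),
                      treatment = character(), phi_max_fit = numeric(),
                      H_T = numeric(), previous_phi_max = numeric(),
                      previous_H_T = numeric()))
  do.call(rbind, out)
}

#' Between-round feedback analysis
#'
#' Convenience wrapper running the full between-round analysis on a
#' calibration report: builds eligible round outcomes, estimates the
#' sustainability threshold from the regression intersection, converts
#' fitted discount factors to exponential discount rates, and fits the
#' logistic value function of rate against previous total harvest.
#'
#' @param report Calibration report data frame (see [build_round_outcomes()]).
#' @param T Round duration used for the discount-rate inversion.
#' @param phi_floor Floor applied to fitted `phi_max` before the rate
#'   inversion (default 0.5): the implied rate diverges as the weight
#'   approaches zero, so fully myopic rounds are assigned the rate at the
#'   floor.
#' @return List with `outcomes`, `threshold` (from
#'   [sustainability_threshold()]), and `logistic` (from
#'   [fit_logistic_response()]).
#' @export
analyze_feedback <- function(report, T = 240, phi_floor = 0.5) {
  outcomes <- build_round_outcomes(report)
  if (nrow(outcomes) < 5)
    stop("too few eligible rounds for feedback analysis", call. = FALSE)
  thr <- sustainability_threshold(outcomes$phi_max_fit,
                                  outcomes$previous_phi_max)
  rho <- discount_rate_from_weight(pmax(outcomes$phi_max_fit, phi_floor), T)
  lg <- fit_logistic_response(outcomes$previous_H_T, rho)
  list(outcomes = outcomes, threshold = thr, logistic = lg, rho = rho)
}
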