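#' Construct an observed round
#'
#' Container for one round's (possibly noisy) resource time series, as
#' produced by averaging experimental replicates or by the synthetic
#' generator.
#'
#' @param t_obs Sampling times, strictly increasing, within `[0, T]`.
#' @param R_obs Observed resource series, `>= 0`, same length as `t_obs`.
#' @param session_id Session identifier (character).
#' @param round_index Round number within the session (1-6).
#' @param treatment Treatment label: one of `"C"`, `"P"`, `"CP"`, `"NCP"`.
#' @param G_obs Optional observed harvest-rate series.
#' @return An `observed_round` object.
#' @export
observed_round <- function(t_obs, R_obs, session_id = "s1", round_index = 1L,
                           treatment = "NCP", G_obs = NULL) {
  if (length(t_obs) == 0L) stop("empty observation series", call. = FALSE)
  if (length(t_obs) != length(R_obs))
    stop("t_obs and R_obs must have the same length", call. = FALSE)
  if (any(diff(t_obs) <= 0)) stop("t_obs must be strictly increasing", call. = FALSE)
  if (any(!is.finite(R_obs)) || any(R_obs < 0))
    stop("R_obs must be finite and >= 0", call. = FALSE)
  if (!treatment %in% c("C", "P", "CP", "NCP"))
    stop("treatment must be one of C, P, CP, NCP", call. = FALSE)
  if (!is.null(G_obs) && length(G_obs) != length(t_obs))
    stop("G_obs must align with t_obs", call. = FALSE)
  structure(list(session_id = as.character(session_id),
                 round_index = as.integer(round_index),
                 treatment = treatment,
                 t_obs = as.numeric(t_obs), R_obs = as.numeric(R_obs),
                 G_obs = if (is.null(G_obs)) NULL else as.numeric(G_obs)),
            class = "observed_round")
}

#' @export
print.observed_round <- function(x, ...) {
  cat(sprintf("Observed round %s/%d (%s): %d samples, t in [%g, %g]\n",
              x$session_id, x$round_index, x$treatment, length(x$t_obs),
              x$t_obs[1], x$t_obs[length(x$t_obs)]))
  invisible(x)
}

#' Root-mean-square error between a model trajectory and observations
#'
#' Interpolates the modelled resource series linearly onto the observation
#' times and returns `sqrt(mean((R_model - R_obs)^2))`.
#'
#' @param traj A `cpr_trajectory` from [integrate_round()].
#' @param obs An [observed_round()].
#' @return RMSE (resource units).
#' @export
rmse <- function(traj, obs) {
  stopifnot(inherits(obs, "observed_round"))
  if (length(obs$t_obs) == 0L) stop("empty observation series", call. = FALSE)
  tmax <- traj$t[nrow(traj)]
  if (obs$t_obs[length(obs$t_obs)] > tmax + 1e-9 || obs$t_obs[1] < traj$t[1] - 1e-9)
    stop("observation times not covered by the trajectory grid", call. = FALSE)
  Rm <- approx(traj$t, traj$R, xout = obs$t_obs)$y
  sqrt(mean((Rm - obs$R_obs)^2))
}

# objective: rmse of the resource series for a given parameter set.
# Bypasses the full trajectory assembly (diagnostic series are not needed
# for the objective), calling the integrator and interpolating R only.
round_objective <- function(obs, params_base, init, dt, dt_out) {
  force(obs)
  base <- unclass(params_base)
  R0 <- init[["R"]]; H0 <- init[["H"]]; theta0 <- init[["theta"]]
  function(phi_max, a = base$a, b = base$b) {
    prm <- base
    prm$phi_max <- phi_max; prm$a <- a; prm$b <- b
    out <- tryCatch({
      m <- .integrate_round_cpp(prm, R0, H0, theta0, dt, dt_out)
      Rm <- approx(m[, "t"], m[, "R"], xout = obs$t_obs)$y
      sqrt(mean((Rm - obs$R_obs)^2))
    }, error = function(e) NA_real_)
    if (!is.finite(out)) NA_real_ else out
  }
}

# golden-section minimization on [lo, hi]; fn must be unimodal-ish there.
# Returns list(x, fx, trace).
golden_section <- function(fn, lo, hi, tol = 0.01) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- fn(x1); f2 <- fn(x2)
  trace <- data.frame(x = c(x1, x2), value = c(f1, f2))
  while ((hi - lo) > tol) {
    if (!is.na(f1) && (is.na(f2) || f1 < f2)) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- fn(x1)
      trace <- rbind(trace, data.frame(x = x1, value = f1))
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- fn(x2)
      trace <- rbind(trace, data.frame(x = x2, value = f2))
    }
  }
  xs <- c(trace$x, (lo + hi) / 2)
  fs <- c(trace$value, fn((lo + hi) / 2))
  best <- which.min(fs)
  list(x = xs[best], fx = fs[best], trace = trace)
}

new_calibration_result <- function(estimates, rmse_at_optimum, trace, mode,
                                   obs, ill_identified = FALSE) {
  structure(list(estimates = estimates, rmse_at_optimum = rmse_at_optimum,
                 evaluations = nrow(trace), trace = trace, mode = mode,
                 session_id = obs$session_id, round_index = obs$round_index,
                 treatment = obs$treatment, ill_identified = ill_identified),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  est <- paste(sprintf("%s = %.4g", names(x$estimates), x$estimates),
               collapse = ", ")
  cat(sprintf("Calibration (%s-parameter) of round %s/%d (%s)\n", x$mode,
              x$session_id, x$round_index, x$treatment))
  cat(sprintf("  %s; rmse = %.4g (%d evaluations)%s\n", est,
              x$rmse_at_optimum, x$evaluations,
              if (x$ill_identified) " [ill-identified]" else ""))
  invisible(x)
}

# near-optimum trace spread exceeding 25% of the bound range flags a flat,
# ill-identified objective
flag_ill_identified <- function(trace, best_rmse, bounds_range, frac = 0.05,
                                spread_frac = 0.25) {
  near <- trace[is.finite(trace$value) &
                  trace$value <= best_rmse * (1 + frac), , drop = FALSE]
  par_cols <- setdiff(names(trace), "value")
  any(vapply(seq_along(par_cols), function(i) {
    v <- near[[par_cols[i]]]
    length(v) > 1 && (max(v) - min(v)) > spread_frac * bounds_range[i]
  }, logical(1)))
}

#' Calibrate the maximum discount factor to one observed round
#'
#' One-parameter mode: minimizes the resource-series RMSE over `phi_max`
#' with all other parameters fixed, using a coarse grid (step 0.5 over
#' `bounds`) followed by golden-section refinement to a tolerance of 0.01.
#'
#' @param obs An [observed_round()].
#' @param params_base A [cpr_params()] object supplying all fixed parameters
#'   (including `punishment_on` for the round's treatment).
#' @param bounds Search interval for `phi_max` (default `c(0, 40)`).
#' @param init Initial state of the round.
#' @param dt,dt_out Solver and output steps used for candidate trajectories.
#' @param grid_step Coarse grid step (default 0.5).
#' @return A `calibration_result` with fields `estimates` (named vector),
#'   `rmse_at_optimum`, `evaluations`, `trace`, `mode`, round metadata and an
#'   `ill_identified` flag (near-optimal trace spread > 25% of the bounds).
#' @export
fit_phi_max <- function(obs, params_base, bounds = c(0, 40),
                        init = list(R = 50, H = 0, theta = 0.8),
                        dt = 0.05, dt_out = 1, grid_step = 0.5) {
  stopifnot(inherits(obs, "observed_round"))
  obj <- round_objective(obs, params_base, init, dt, dt_out)
  grid <- seq(bounds[1], bounds[2], by = grid_step)
  vals <- vapply(grid, obj, numeric(1))
  trace <- data.frame(phi_max = grid, value = vals)
  if (all(is.na(vals))) stop("objective non-finite everywhere", call. = FALSE)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  ref <- golden_section(obj, lo, hi, tol = 0.01)
  trace <- rbind(trace, data.frame(phi_max = ref$trace$x, value = ref$trace$value))
  best_x <- if (ref$fx <= vals[i]) ref$x else grid[i]
  best_f <- min(ref$fx, vals[i])
  ill <- flag_ill_identified(trace, best_f, diff(bounds))
  new_calibration_result(c(phi_max = best_x), best_f, trace, "one", obs, ill)
}

#' Calibrate the discount factor and its decay shape to one observed round
#'
#' Three-parameter mode: full-factorial grid over `(phi_max, a, b)` followed
#' by cyclic one-dimensional golden-section refinement. The one-parameter
#' optimum (at the base `a`, `b`) is injected as a refinement start, so the
#' returned RMSE can never exceed that of [fit_phi_max()] on the same round
#' (nested-model dominance).
#'
#' @inheritParams fit_phi_max
#' @param bounds List with elements `phi_max`, `a`, `b`, each `c(lo, hi)`.
#' @param n_grid Grid resolution per parameter, `c(phi_max, a, b)`
#'   (default `c(30, 15, 15)`).
#' @param n_sweeps Number of cyclic refinement sweeps (default 2).
#' @return A `calibration_result` with a 3-element `estimates` vector.
#' @export
fit_three_params <- function(obs, params_base,
                             bounds = list(phi_max = c(0, 40), a = c(5, 30),
                                           b = c(0.4, 0.9)),
                             n_grid = c(30, 15, 15),
                             init = list(R = 50, H = 0, theta = 0.8),
                             dt = 0.05, dt_out = 1, n_sweeps = 2) {
  stopifnot(inherits(obs, "observed_round"))
  obj <- round_objective(obs, params_base, init, dt, dt_out)
  gphi <- seq(bounds$phi_max[1], bounds$phi_max[2], length.out = n_grid[1])
  ga <- seq(bounds$a[1], bounds$a[2], length.out = n_grid[2])
  gb <- seq(bounds$b[1], bounds$b[2], length.out = n_grid[3])
  full <- expand.grid(phi_max = gphi, a = ga, b = gb)
  full$value <- mapply(obj, full$phi_max, full$a, full$b)
  if (all(is.na(full$value))) stop("objective non-finite everywhere", call. = FALSE)

  one <- fit_phi_max(obs, params_base, bounds = bounds$phi_max, init = init,
                     dt = dt, dt_out = dt_out)
  cand <- rbind(full,
                data.frame(phi_max = one$estimates[["phi_max"]],
                           a = params_base$a, b = params_base$b,
                           value = one$rmse_at_optimum))
  i <- which.min(cand$value)
  cur <- c(phi_max = cand$phi_max[i], a = cand$a[i], b = cand$b[i])
  cur_f <- cand$value[i]
  trace <- cand

  widths <- vapply(bounds, diff, numeric(1))
  steps <- widths / (pmax(n_grid - 1, 1))
  for (sweep in seq_len(n_sweeps)) {
    for (pn in c("phi_max", "a", "b")) {
      lo <- max(bounds[[pn]][1], cur[[pn]] - steps[[pn]])
      hi <- min(bounds[[pn]][2], cur[[pn]] + steps[[pn]])
      fn1 <- function(x) {
        args <- as.list(cur); args[[pn]] <- x
        do.call(obj, args)
      }
      ref <- golden_section(fn1, lo, hi,
                            tol = max(1e-3, 1e-3 * widths[[pn]]))
      tr1 <- cbind(as.data.frame(as.list(cur))[rep(1, nrow(ref$trace)), ],
                   value = ref$trace$value)
      tr1[[pn]] <- ref$trace$x
      trace <- rbind(trace, tr1[names(trace)])
      if (!is.na(ref$fx) && ref$fx < cur_f) {
        cur[[pn]] <- ref$x; cur_f <- ref$fx
      }
    }
  }
  ill <- flag_ill_identified(trace, cur_f, widths)
  new_calibration_result(cur, cur_f, trace, "three", obs, ill)
}

#' One-at-a-time RMS sensitivity scan around a fitted optimum
#'
#' For each of `phi_max`, `a`, `b`, evaluates the RMSE along a grid while the
#' other two parameters are held at their fitted values; shows how sharply
#' the error rises away from the optimum for each parameter.
#'
#' @param obs The [observed_round()] the fit was made to.
#' @param result A `calibration_result` from [fit_three_params()].
#' @param params_base The base parameter set used for the fit.
#' @param grids Named list of grids; defaults to 21 points over the standard
#'   calibration bounds, with the fitted value spliced in.
#' @inheritParams fit_phi_max
#' @return Named list of data frames (`phi_max`, `a`, `b`), each with the
#'   scanned `value` of the parameter and the `rmse` along its grid.
#' @export
sensitivity_scan <- function(obs, result, params_base, grids = NULL,
                             init = list(R = 50, H = 0, theta = 0.8),
                             dt = 0.05, dt_out = 1) {
  stopifnot(inherits(result, "calibration_result"))
  if (result$mode != "three")
    stop("sensitivity_scan requires a three-parameter calibration result",
         call. = FALSE)
  est <- result$estimates
  if (is.null(grids)) {
    grids <- list(phi_max = seq(0, 40, length.out = 21),
                  a = seq(5, 30, length.out = 21),
                  b = seq(0.4, 0.9, length.out = 21))
  }
  obj <- round_objective(obs, params_base, init, dt, dt_out)
  out <- lapply(names(grids), function(pn) {
    g <- sort(unique(c(grids[[pn]], est[[pn]])))
    vals <- vapply(g, function(x) {
      args <- as.list(est); args[[pn]] <- x
      do.call(obj, args)
    }, numeric(1))
    df <- data.frame(value = g, rmse = vals)
    names(df)[1] <- pn
    df
  })
  names(out) <- names(grids)
  out
}
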