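#' Default configuration
#'
#' The full configuration of the pipeline as a named list: every model
#' parameter (see [cpr_params()]), the initial state, solver settings,
#' calibration bounds and grids, study-design settings, output directory,
#' master seed and log level. [load_config()] starts from these defaults and
#' overlays the file's keys.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  prm <- unclass(cpr_params())
  dsn <- unclass(study_design())
  list(
    model = prm,
    init = list(R = 50, H = 0, theta = 0.8),
    solver = list(dt = 0.05, dt_out = 1),
    calibration = list(phi_bounds = c(0, 40), a_bounds = c(5, 30),
                       b_bounds = c(0.4, 0.9), grid_step = 0.5,
                       n_grid = c(30, 15, 15)),
    design = list(n_sessions = dsn$n_sessions,
                  sampling_interval = dsn$sampling_interval,
                  noise_sd = dsn$noise_sd,
                  feedback = dsn$feedback,
                  init_phi = as.list(dsn$init_phi)),
    output_dir = "cpradapt-out",
    seed = 1L,
    log_level = "info")
}

merge_section <- function(base, upd, path) {
  bad <- setdiff(names(upd), names(base))
  if (length(bad) > 0)
    stop("unknown config key(s): ",
         paste(paste0(path, bad), collapse = ", "), call. = FALSE)
  for (nm in names(upd)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(upd[[nm]]))
        stop("config key '", path, nm, "' must be a section", call. = FALSE)
      base[[nm]] <- merge_section(base[[nm]], upd[[nm]], paste0(path, nm, "."))
    } else {
      v <- upd[[nm]]
      if (is.list(v)) v <- unlist(v)
      proto <- base[[nm]]
      if (is.numeric(proto) && !is.numeric(v))
        stop("config key '", path, nm, "' must be numeric", call. = FALSE)
      if (is.character(proto) && !is.character(v))
        stop("config key '", path, nm, "' must be character", call. = FALSE)
      base[[nm]] <- v
    }
  }
  base
}

#' Load a configuration file
#'
#' Reads a JSON configuration, overlays it on [default_config()], rejects
#' unknown keys (naming the offending key), and validates the model section
#' through [cpr_params()]. An empty file yields the all-defaults
#' configuration. `save_config()` writes a configuration such that
#' `load_config(save_config(cfg))` round-trips losslessly.
#'
#' @param path Path to a JSON configuration file.
#' @return Validated configuration list of class `cpr_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  upd <- if (nzchar(trimws(txt))) {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else list()
  cfg <- merge_section(default_config(), upd, "")
  prm <- cfg$model
  prm$punishment_on <- isTRUE(prm$punishment_on)
  do.call(cpr_params, prm)  # validation; errors name the offending field
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "cpr_config"
  cfg
}

#' @rdname load_config
#' @param config A configuration list.
#' @return `save_config` returns `path` invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Model parameters from a configuration
#'
#' @param config A configuration list from [load_config()].
#' @return A [cpr_params()] object.
#' @export
params_from_config <- function(config) {
  prm <- config$model
  prm$punishment_on <- isTRUE(prm$punishment_on)
  do.call(cpr_params, prm)
}

design_from_config <- function(config) {
  d <- config$design
  study_design(n_sessions = d$n_sessions,
               sampling_interval = d$sampling_interval,
               noise_sd = d$noise_sd,
               feedback = as.list(d$feedback),
               init_phi = unlist(d$init_phi),
               init = config$init)
}

traj_columns <- c("t", "R", "H", "theta", "G", "phi", "P", "A", "omega",
                  "affinity")

#' Write / read a trajectory CSV
#'
#' Columns `t,R,H,theta,G,phi,P,A,omega,affinity`, comma-separated with `.`
#' decimal and a single header row. `read_trajectory(write_trajectory(x))`
#' reproduces the series to full printed precision (15 significant digits).
#'
#' @param traj A `cpr_trajectory`.
#' @param path Output path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a data frame with the trajectory columns.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)[traj_columns]
  df[] <- lapply(df, function(x) formatC(x, format = "g", digits = 15))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, colClasses = "numeric")
  miss <- setdiff(traj_columns, names(df))
  if (length(miss) > 0)
    stop("trajectory file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Write / read an observed-round CSV
#'
#' Columns `t,R` and optionally `G`; metadata (session, round, treatment)
#' travels in the manifest, not in the data file.
#'
#' @param obs An [observed_round()].
#' @param path File path.
#' @return `write_observed` returns `path` invisibly.
#' @export
write_observed <- function(obs, path) {
  df <- data.frame(t = obs$t_obs, R = obs$R_obs)
  if (!is.null(obs$G_obs)) df$G <- obs$G_obs
  df[] <- lapply(df, function(x) formatC(x, format = "g", digits = 15))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observed
#' @param session_id,round_index,treatment Metadata for the constructed
#'   [observed_round()].
#' @export
read_observed <- function(path, session_id = "s1", round_index = 1L,
                          treatment = "NCP") {
  df <- read.csv(path, colClasses = "numeric")
  if (!all(c("t", "R") %in% names(df)))
    stop("observed-round file lacks column(s): ",
         paste(setdiff(c("t", "R"), names(df)), collapse = ", "),
         call. = FALSE)
  observed_round(df$t, df$R, session_id = session_id,
                 round_index = round_index, treatment = treatment,
                 G_obs = if ("G" %in% names(df)) df$G else NULL)
}

#' Read a study manifest and its round files
#'
#' The manifest is a CSV with columns `session_id,round_index,treatment,path`
#' (paths relative to the manifest's directory). Rounds whose file is
#' missing are skipped with a message.
#'
#' @param manifest_path Path to `manifest.csv`.
#' @return List of [observed_round()] objects.
#' @export
read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("session_id", "round_index", "treatment", "path")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0)
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  base <- dirname(manifest_path)
  out <- list()
  for (i in seq_len(nrow(man))) {
    f <- file.path(base, man$path[i])
    if (!file.exists(f)) {
      message("manifest entry missing on disk, skipped: ", man$path[i])
      next
    }
    out[[length(out) + 1L]] <- read_observed(
      f, session_id = man$session_id[i],
      round_index = as.integer(man$round_index[i]),
      treatment = man$treatment[i])
  }
  out
}

#' Calibrate every round of a study
#'
#' Runs the round-wise calibration over a list of observed rounds (e.g. from
#' [read_manifest()] or a [generate_study()] result) and assembles the
#' calibration report. Punishment is switched on for treatments `P` and
#' `CP`. The reported `H_T` is the total harvest of the fitted model
#' trajectory.
#'
#' @param rounds List of [observed_round()]s, or a [generate_study()] result.
#' @param params_base Base parameter set.
#' @param mode `"one"` (fit `phi_max`) or `"three"` (fit `phi_max`, `a`,
#'   `b`).
#' @param init Initial state for candidate trajectories.
#' @param dt,dt_out Solver settings for candidate trajectories.
#' @param ... Passed on to [fit_phi_max()] / [fit_three_params()].
#' @return Data frame with one row per round: `session_id`, `round_index`,
#'   `treatment`, the estimates, `rmse`, `H_T`, `ill_identified`.
#' @export
calibrate_study <- function(rounds, params_base = cpr_params(),
                            mode = c("one", "three"),
                            init = list(R = 50, H = 0, theta = 0.8),
                            dt = 0.05, dt_out = 1, ...) {
  mode <- match.arg(mode)
  if (is.list(rounds) && !is.null(rounds$sessions))
    rounds <- unlist(lapply(rounds$sessions, `[[`, "rounds"),
                     recursive = FALSE)
  rows <- lapply(rounds, function(obs) {
    prm <- update_params(params_base,
                         punishment_on = obs$treatment %in% c("P", "CP"))
    res <- if (mode == "one") {
      fit_phi_max(obs, prm, init = init, dt = dt, dt_out = dt_out, ...)
    } else {
      fit_three_params(obs, prm, init = init, dt = dt, dt_out = dt_out, ...)
    }
    est <- res$estimates
    fitted_prm <- update_params(prm, phi_max = est[["phi_max"]],
                                a = if ("a" %in% names(est)) est[["a"]] else prm$a,
                                b = if ("b" %in% names(est)) est[["b"]] else prm$b)
    ht <- total_harvest(integrate_round(fitted_prm, init = init, dt = dt,
                                        dt_out = dt_out))
    df <- data.frame(session_id = obs$session_id,
                     round_index = obs$round_index,
                     treatment = obs$treatment,
                     phi_max = est[["phi_max"]],
                     rmse = res$rmse_at_optimum, H_T = ht,
                     ill_identified = res$ill_identified)
    if (mode == "three") { df$a <- est[["a"]]; df$b <- est[["b"]] }
    df
  })
  do.call(rbind, rows)
}
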