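#' Design of a synthetic multi-session harvest experiment
#'
#' Describes the pseudo-experimental study the generator emulates: six
#' sessions of six rounds, a treatment change after round 3, noisy sampling
#' of the resource trajectory, and a between-round feedback in which the
#' total harvest of the previous same-treatment round sets the next round's
#' maximum discount factor through a logistic map
#' `phi' = phi_lo + (phi_hi - phi_lo) / (1 + exp(-s * (H_T - H_star)))`.
#'
#' The default feedback (`phi_lo = 1`, `phi_hi = 16`, `H_star = 191.12`,
#' `s = 0.35`) places the induced fixed point of the round-to-round map at
#' `phi* = 8.5` (because `H_star` equals the model's total harvest at
#' `phi_max = 8.5` under the default parameters) and makes the map expansive
#' around it (local slope about 2): groups above the threshold improve round
#' over round, groups below it spiral into overexploitation. The default
#' initial discount factors per treatment straddle the threshold, with
#' communication treatments above it.
#'
#' @param n_sessions Number of sessions (default 6).
#' @param treatment_sequences List of two-treatment character vectors, one
#'   per session (recycled); the first entry governs rounds 1-3, the second
#'   rounds 4-6.
#' @param sampling_interval Observation sampling step (time units).
#' @param noise_sd Standard deviation of the Gaussian observation noise on
#'   the sampled resource level (resource units); default `2` (2% of the
#'   default carrying capacity), emulating averages of 5-6 replicate groups.
#' @param feedback Named list `phi_lo`, `phi_hi`, `H_star`, `s`.
#' @param init_phi Named vector of initial `phi_max` per treatment, used in
#'   rounds 1 and 4 (the rounds that open a new treatment).
#' @param init State at the start of every round.
#' @return A `study_design` list.
#' @export
study_design <- function(n_sessions = 6,
                         treatment_sequences = list(
                           c("NCP", "C"), c("NCP", "P"), c("NCP", "CP"),
                           c("C", "NCP"), c("P", "NCP"), c("CP", "NCP")),
                         sampling_interval = 5,
                         noise_sd = 2,
                         feedback = list(phi_lo = 1, phi_hi = 16,
                                         H_star = 191.12, s = 0.35),
                         init_phi = c(NCP = 4, C = 13, P = 5.5, CP = 11.5),
                         init = list(R = 50, H = 0, theta = 0.8)) {
  stopifnot(n_sessions >= 1, sampling_interval > 0, noise_sd >= 0)
  stopifnot(all(c("phi_lo", "phi_hi", "H_star", "s") %in% names(feedback)))
  if (feedback$phi_hi < feedback$phi_lo)
    stop("feedback phi_hi must be >= phi_lo", call. = FALSE)
  treatments <- unique(unlist(treatment_sequences))
  if (!all(treatments %in% names(init_phi)))
    stop("init_phi must name every treatment used", call. = FALSE)
  structure(list(n_sessions = as.integer(n_sessions),
                 rounds_per_session = 6L,
                 treatment_sequences = treatment_sequences,
                 sampling_interval = sampling_interval,
                 noise_sd = noise_sd, feedback = feedback,
                 init_phi = init_phi, init = init),
            class = "study_design")
}

#' Between-round feedback map
#'
#' The logistic map from the previous round's total harvest to the next
#' round's maximum discount factor.
#'
#' @param H_T Previous total harvest.
#' @param feedback Named list `phi_lo`, `phi_hi`, `H_star`, `s`.
#' @return Next `phi_max`.
#' @export
feedback_map <- function(H_T, feedback) {
  feedback$phi_lo + (feedback$phi_hi - feedback$phi_lo) /
    (1 + exp(-feedback$s * (H_T - feedback$H_star)))
}

# run fn with a private RNG substream, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

# deterministic 31-bit substream seed derived from a master seed and labels
derive_seed <- function(seed, ...) {
  h <- as.double(seed %% 2147483647L)
  for (x in c(...)) {
    for (ch in utf8ToInt(as.character(x)))
      h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Generate one noisy observed round from the model
#'
#' Integrates the model under `params`, samples the resource level on a
#' uniform grid, and adds independent Gaussian observation noise truncated
#' at zero. Identical seeds give identical output.
#'
#' @param params A [cpr_params()] object.
#' @param noise_sd Observation noise standard deviation (resource units).
#' @param sampling_interval Sampling step (time units); must divide `T`.
#' @param seed Integer seed for the round's noise.
#' @param init Initial state.
#' @param with_G If `TRUE`, also emit a noisy harvest-rate series (noise
#'   scaled by `noise_sd / 20`, reflecting the smaller scale of rates).
#' @param ... Metadata passed to [observed_round()] (`session_id`,
#'   `round_index`, `treatment`).
#' @return An [observed_round()]; the generating trajectory is attached as
#'   attribute `truth` and the noiseless total harvest as `H_T_true`.
#' @export
generate_round <- function(params, noise_sd = 2, sampling_interval = 5,
                           seed = 1L, init = list(R = 50, H = 0, theta = 0.8),
                           with_G = FALSE, ...) {
  traj <- integrate_round(params, init = init, dt = 0.05,
                          dt_out = sampling_interval)
  obs <- with_seed(seed, function() {
    R_obs <- pmax(0, traj$R + rnorm(nrow(traj), 0, noise_sd))
    G_obs <- if (with_G)
      pmax(0, traj$G + rnorm(nrow(traj), 0, noise_sd / 20)) else NULL
    observed_round(traj$t, R_obs, G_obs = G_obs, ...)
  })
  attr(obs, "truth") <- traj
  attr(obs, "H_T_true") <- total_harvest(traj)
  obs
}

#' Generate one six-round session
#'
#' Rounds 1 and 4 (a fresh treatment) use the treatment's initial maximum
#' discount factor; rounds 2, 3, 5 and 6 receive theirs from the feedback
#' map applied to the previous same-treatment round's realized (noiseless)
#' total harvest. Punishment is switched on for treatments `P` and `CP`.
#'
#' @param design A [study_design()].
#' @param session_index Session number (selects the treatment sequence).
#' @param seed Master seed for the session; per-round noise seeds are
#'   derived from it.
#' @param params_base Base parameter set; `phi_max` and `punishment_on` are
#'   overridden per round.
#' @return A `session_dataset`: list with `session_id`, `rounds` (list of
#'   [observed_round()]s) and `meta` (data frame of the true per-round
#'   `phi_max` and noiseless `H_T`).
#' @export
generate_session <- function(design, session_index = 1L, seed = 1L,
                             params_base = cpr_params()) {
  stopifnot(inherits(design, "study_design"))
  seqs <- design$treatment_sequences
  sq <- seqs[[(session_index - 1L) %% length(seqs) + 1L]]
  session_id <- sprintf("s%02d", session_index)
  rounds <- vector("list", design$rounds_per_session)
  meta <- data.frame()
  phi <- NA_real_
  for (r in seq_len(design$rounds_per_session)) {
    treatment <- if (r <= 3L) sq[1] else sq[2]
    phi <- if (r %in% c(1L, 4L)) {
      unname(design$init_phi[[treatment]])
    } else {
      feedback_map(prev_HT, design$feedback)
    }
    prm <- update_params(params_base, phi_max = phi,
                         punishment_on = treatment %in% c("P", "CP"))
    obs <- generate_round(prm, noise_sd = design$noise_sd,
                          sampling_interval = design$sampling_interval,
                          seed = derive_seed(seed, session_id, r),
                          init = design$init,
                          session_id = session_id, round_index = r,
                          treatment = treatment)
    prev_HT <- attr(obs, "H_T_true")
    rounds[[r]] <- obs
    meta <- rbind(meta, data.frame(session_id = session_id, round_index = r,
                                   treatment = treatment, phi_max_true = phi,
                                   H_T_true = prev_HT))
  }
  structure(list(session_id = session_id, rounds = rounds, meta = meta),
            class = "session_dataset")
}

#' @export
print.session_dataset <- function(x, ...) {
  cat(sprintf("Session %s: %d rounds (%s -> %s)\n", x$session_id,
              length(x$rounds), x$meta$treatment[1],
              x$meta$treatment[nrow(x$meta)]))
  print(x$meta, row.names = FALSE)
  invisible(x)
}

#' Generate a full synthetic study
#'
#' Generates `design$n_sessions` sessions with per-session seeds derived
#' from the master seed. With `dir` given, writes one observed-round CSV per
#' round plus a `manifest.csv` in the format [calibrate_study()] and
#' [read_manifest()] consume.
#'
#' @param design A [study_design()].
#' @param seed Master seed.
#' @param params_base Base parameter set.
#' @param dir Optional output directory (created if missing).
#' @return List with `sessions` (list of `session_dataset`), `meta` (row-bound
#'   per-round truth), and `manifest` (`NULL` unless `dir` was given).
#' @export
generate_study <- function(design = study_design(), seed = 1L,
                           params_base = cpr_params(), dir = NULL) {
  stopifnot(inherits(design, "study_design"))
  sessions <- lapply(seq_len(design$n_sessions), function(i)
    generate_session(design, i, seed = derive_seed(seed, "session", i),
                     params_base = params_base))
  meta <- do.call(rbind, lapply(sessions, `[[`, "meta"))
  manifest <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    rows <- list()
    for (s in sessions) for (obs in s$rounds) {
      path <- sprintf("%s_r%d.csv", obs$session_id, obs$round_index)
      write_observed(obs, file.path(dir, path))
      rows[[length(rows) + 1L]] <- data.frame(
        session_id = obs$session_id, round_index = obs$round_index,
        treatment = obs$treatment, path = path)
    }
    manifest <- do.call(rbind, rows)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
              quote = FALSE)
  }
  list(sessions = sessions, meta = meta, manifest = manifest)
}

#' Induced fixed point of the between-round map
#'
#' Solves `phi = feedback_map(H_T(phi))` for the study's noiseless
#' round-to-round dynamics, where `H_T(phi)` is the model's total harvest at
#' maximum discount factor `phi`. This is the generating sustainability
#' threshold that the feedback analysis is expected to recover.
#'
#' With an expansive feedback the map has two stable plateau fixed points
#' and one interior unstable one (the threshold); `interval` must bracket
#' the interior root only. The default brackets the threshold of the
#' default design.
#'
#' @param design A [study_design()].
#' @param params_base Base parameter set (punishment off).
#' @param interval Search interval for the fixed point.
#' @return The fixed point `phi*`.
#' @export
induced_fixed_point <- function(design = study_design(),
                                params_base = cpr_params(),
                                interval = c(3, 13)) {
  f <- function(phi) {
    ht <- total_harvest(integrate_round(
      update_params(params_base, phi_max = phi), init = design$init))
    feedback_map(ht, design$feedback) - phi
  }
  uniroot(f, interval, tol = 1e-6)$root
}
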