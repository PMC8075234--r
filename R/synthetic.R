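#' Gait model parameters for the synthetic 6MWT generator
#'
#' The generator is a harmonic-plus-transient construction, not a
#' biomechanical simulation: each channel is a short harmonic series locked
#' to the stride frequency (so the spectral features are controllable),
#' foot strikes add a sharp AP impact transient, and turns add a yaw-rate
#' boxcar with amplified ML sway and a mid-turn AP bump, every
#' `walkway_length` of accumulated distance.
#'
#' `harmonic_amplitudes` is a 6 x 4 matrix (channels x stride harmonics
#' 1-4, rows ordered ML/vertical/AP accelerations then
#' tilt/rotation/obliquity angular velocities).  ML and the pelvis
#' rotations are dominated by the stride frequency (harmonic 1); vertical
#' and AP by the step frequency (harmonic 2).
#'
#' @param mean_step_time mean step duration, s (default 0.55).
#' @param step_time_cv coefficient of variation of step times (default
#'   0.03; must be < 0.5).
#' @param walking_speed m/s (default 0.8).
#' @param walkway_length m between turns (default 20).
#' @param duration trial length, s (default 360).
#' @param sample_rate Hz (default 50).
#' @param asymmetry fractional lengthening of left steps relative to right
#'   (default 0.04), exercising the symmetry index.
#' @param harmonic_amplitudes 6 x 4 amplitude matrix (m/s^2 or deg/s).
#' @param impact_amplitude AP strike transient height, m/s^2 (default 2).
#' @param impact_width_s Gaussian transient width, s (default 0.02 — one
#'   frame, so the strike stays the local AP maximum).
#' @param turn_duration s per 180-degree turn (default 3).
#' @param turn_yaw_rate deg/s during a turn; default `180 / turn_duration`.
#' @param turn_ml_gain fractional ML amplitude boost inside turns
#'   (default 0.8).
#' @param turn_ap_peak mid-turn AP bump amplitude, m/s^2 (default 1).
#' @param noise_sd named per-channel Gaussian noise SD; defaults to
#'   0.12 m/s^2 for accelerations and 2 deg/s for angular velocities.
#' @return list of class `gait_model_params`.
#' @export
gait_model_params <- function(mean_step_time = 0.55, step_time_cv = 0.03,
                              walking_speed = 0.8, walkway_length = 20,
                              duration = 360, sample_rate = 50,
                              asymmetry = 0.04,
                              harmonic_amplitudes = NULL,
                              impact_amplitude = 2, impact_width_s = 0.02,
                              turn_duration = 3, turn_yaw_rate = NULL,
                              turn_ml_gain = 0.8, turn_ap_peak = 1,
                              noise_sd = NULL) {
  if (is.null(harmonic_amplitudes)) {
    harmonic_amplitudes <- rbind(
      acc_ml       = c(0.60, 0.15, 0.10, 0.05),
      acc_vert     = c(0.15, 0.90, 0.10, 0.25),
      acc_ap       = c(0.20, 0.60, 0.10, 0.15),
      av_tilt      = c(3.0, 8.0, 1.5, 2.5),
      av_rotation  = c(8.0, 2.5, 1.5, 0.8),
      av_obliquity = c(8.0, 3.0, 1.5, 1.0))
  }
  if (is.null(turn_yaw_rate)) turn_yaw_rate <- 180 / turn_duration
  if (is.null(noise_sd))
    noise_sd <- c(acc_ml = 0.12, acc_vert = 0.12, acc_ap = 0.12,
                  av_tilt = 2, av_rotation = 2, av_obliquity = 2)
  stopifnot(mean_step_time > 0, step_time_cv >= 0, step_time_cv < 0.5,
            walking_speed > 0, walkway_length > 0, duration > 0,
            sample_rate > 0, turn_duration > 0, turn_yaw_rate > 0,
            all(noise_sd >= 0),
            identical(rownames(harmonic_amplitudes), SIX_CHANNELS))
  structure(as.list(environment()), class = "gait_model_params")
}

#' Class-effect parameters for the synthetic generator
#'
#' How fall-risk gait differs from no-fall-risk gait in the generator, all
#' scaled by a single `effect_scale` knob in \[0, 1\] (`0` makes the class
#' distributions identical; `1` is the full study-condition effect):
#' \itemize{
#'   \item step-time variability: CV multiplied by
#'     `1 + cv_delta * effect_scale`;
#'   \item spectral concentration: each channel's dominant stride harmonic
#'     amplified and the others damped, producing the more distinct FFT
#'     peaks (lower peak distinction) seen in fall-risk walkers;
#'   \item even-harmonic damping, lowering the even/odd harmonic ratio.
#' }
#' The spectral deltas act at full strength inside turns and at
#' `straight_weight` of it on straightaways: turning stresses balance
#' most, which is what makes turn steps the more discriminative set.
#'
#' @param effect_scale global multiplier in \[0, 1\] (default 1).
#' @param cv_delta fractional CV increase at full effect (default 1).
#' @param concentration dominant-harmonic amplification (default 0.5).
#' @param damp_nondominant non-dominant harmonic damping (default 0.4).
#' @param even_damp even-harmonic damping (default 0.35).
#' @param straight_weight fraction of the spectral effect applied outside
#'   turns (default 0.4).
#' @return list of class `class_effects`.
#' @export
class_effects <- function(effect_scale = 1, cv_delta = 0.6,
                          concentration = 0.25, damp_nondominant = 0.2,
                          even_damp = 0.2, straight_weight = 0.4) {
  stopifnot(effect_scale >= 0, effect_scale <= 1, straight_weight >= 0,
            straight_weight <= 1)
  structure(as.list(environment()), class = "class_effects")
}

#' Simulate one 6MWT participant
#'
#' Builds a jittered strike schedule, phase-locks the harmonic channels to
#' it, inserts AP impact transients at every strike and a turn (yaw
#' boxcar, ML amplification, mid-turn AP bump) each time the accumulated
#' walking distance crosses a walkway length, then adds Gaussian noise.
#' The exact construction events are returned as ground truth.
#' Deterministic per `seed`.
#'
#' @param params a [gait_model_params()].
#' @param effects a [class_effects()]; applied only when `label` is
#'   `TRUE`.
#' @param label logical fall-risk label of the simulated walker.
#' @param seed integer RNG seed.
#' @param participant_id identifier; defaults to `"sim<seed>"`.
#' @return list with `recording` (an [imu_recording()]) and `truth`: a
#'   list of `strikes` (data.frame `frame`, `time`, `side`), `turns`
#'   (data.frame `start_frame`, `end_frame`, `center_frame`,
#'   `net_rotation`), `step_labels` (turn/straight per step) and `label`.
#' @export
simulate_participant <- function(params = gait_model_params(),
                                 effects = class_effects(),
                                 label = FALSE, seed = 1,
                                 participant_id = NULL) {
  p <- params
  if (p$duration < 8 * p$mean_step_time)
    stop("duration shorter than 4 strides")
  set.seed(seed)
  fs <- p$sample_rate
  n <- round(p$duration * fs)
  t <- (seq_len(n) - 1) / fs

  scale <- if (label) effects$effect_scale else 0
  cv <- p$step_time_cv * (1 + effects$cv_delta * scale)

  # --- strike schedule, snapped to the frame grid -----------------------
  times <- numeric(0); sides <- character(0)
  tk <- p$mean_step_time
  side <- "right"
  while (tk < p$duration - 0.3) {
    times <- c(times, tk); sides <- c(sides, side)
    off <- if (side == "left") p$asymmetry else -p$asymmetry
    d <- p$mean_step_time * (1 + off) * (1 + cv * stats::rnorm(1))
    d <- min(max(d, 0.3), 1.5)
    tk <- tk + d
    side <- if (side == "right") "left" else "right"
  }
  frames <- as.integer(round(times * fs)) + 1L
  keep <- !duplicated(frames) & frames <= n
  frames <- frames[keep]; sides <- sides[keep]
  strike_t <- (frames - 1) / fs

  # --- turn schedule: one turn per walkway length of distance -----------
  n_turns <- floor((p$duration - p$turn_duration / 2) *
                   p$walking_speed / p$walkway_length)
  centers <- seq_len(n_turns) * p$walkway_length / p$walking_speed
  half <- p$turn_duration / 2
  turn_start <- pmax(as.integer(round((centers - half) * fs)) + 1L, 1L)
  turn_end <- pmin(as.integer(round((centers + half) * fs)) + 1L, as.integer(n))
  in_turn <- rep(FALSE, n)
  yaw_extra <- numeric(n)
  ap_bump <- numeric(n)
  for (j in seq_len(n_turns)) {
    idx <- turn_start[j]:turn_end[j]
    in_turn[idx] <- TRUE
    yaw_extra[idx] <- yaw_extra[idx] +
      (if (j %% 2 == 1) 1 else -1) * p$turn_yaw_rate
    ctr <- (turn_start[j] + turn_end[j]) %/% 2L
    ap_bump <- ap_bump + p$turn_ap_peak * exp(-((t - t[ctr])^2) / (2 * 0.3^2))
  }

  # --- stride phase locked to the strikes -------------------------------
  # phase advances half a stride cycle per step
  phi_k <- (seq_along(strike_t) - 1) / 2
  phi <- approx(strike_t, phi_k, xout = t, rule = 2)$y

  # spectral class effect, stronger inside turns
  w <- ifelse(in_turn, 1, effects$straight_weight) * scale
  A <- p$harmonic_amplitudes
  dominant <- apply(A, 1, which.max)
  phases <- matrix(seq(0.3, by = 0.7, length.out = 24), 6, 4)
  # AP even harmonics crest at the strikes (phase pi/2 at integer step
  # phase): the AP peak at foot strike is the phenomenon strike detection
  # relies on, so the harmonic part must reinforce, not fight, the impacts
  phases[3, c(2, 4)] <- pi / 2

  channels <- list()
  for (ci in seq_along(SIX_CHANNELS)) {
    ch <- SIX_CHANNELS[ci]
    x <- numeric(n)
    for (h in 1:4) {
      g <- if (h == dominant[ci]) 1 + effects$concentration * w else
        1 - effects$damp_nondominant * w
      if (h %% 2 == 0) g <- g * (1 - effects$even_damp * w)
      x <- x + A[ci, h] * g * sin(2 * pi * h * phi + phases[ci, h])
    }
    channels[[ch]] <- x
  }
  channels$acc_ml <- channels$acc_ml * (1 + p$turn_ml_gain * in_turn)
  channels$av_rotation <- channels$av_rotation + yaw_extra
  channels$acc_ap <- channels$acc_ap + ap_bump
  # sharp impact transient at each strike frame
  sig2 <- 2 * p$impact_width_s^2
  for (f in frames) {
    lo <- max(1L, f - 5L); hi <- min(n, f + 5L)
    channels$acc_ap[lo:hi] <- channels$acc_ap[lo:hi] +
      p$impact_amplitude * exp(-((t[lo:hi] - t[f])^2) / sig2)
  }
  for (ch in SIX_CHANNELS)
    channels[[ch]] <- channels[[ch]] + stats::rnorm(n, sd = p$noise_sd[[ch]])

  if (is.null(participant_id)) participant_id <- paste0("sim", seed)
  rec <- imu_recording(t, channels, sample_rate = fs,
                       participant_id = participant_id,
                       metadata = list(walkway_length = p$walkway_length,
                                       label = label, seed = seed))
  truth_strikes <- data.frame(frame = frames, time = strike_t, side = sides,
                              source = "auto")
  truth_turns <- data.frame(
    start_frame = turn_start, end_frame = turn_end,
    center_frame = (turn_start + turn_end) %/% 2L,
    net_rotation = (turn_end - turn_start + 1L) / fs * p$turn_yaw_rate *
      ifelse(seq_len(n_turns) %% 2 == 1, 1, -1))
  truth_seq <- label_steps(step_sequence(truth_strikes,
                                         participant_id = participant_id),
                           truth_turns)
  list(recording = rec,
       truth = list(strikes = truth_strikes, turns = truth_turns,
                    step_labels = truth_seq$labels, label = label))
}

#' Plan a synthetic cohort
#'
#' Draws the per-participant gait parameters (lognormal population spread
#' around the supplied defaults), labels and child seeds for a cohort,
#' without generating any signals.  [simulate_cohort()] and streaming
#' consumers both realize participants from the same plan, so results
#' agree.
#'
#' @param n cohort size (default 89).
#' @param n_fall_risk number of fall-risk participants (default 32).
#' @param params baseline [gait_model_params()].
#' @param effects a [class_effects()].
#' @param seed integer RNG seed.
#' @return list with `ids`, `labels` (named logical), `params`
#'   (per-participant `gait_model_params`), `seeds`, `effects`.
#' @export
cohort_plan <- function(n = 89, n_fall_risk = 32,
                        params = gait_model_params(),
                        effects = class_effects(), seed = 1) {
  if (n_fall_risk <= 0 || n_fall_risk >= n)
    stop("need 0 < n_fall_risk < n")
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n))
  labels <- sample(c(rep(TRUE, n_fall_risk), rep(FALSE, n - n_fall_risk)))
  names(labels) <- ids
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  plist <- lapply(seq_len(n), function(i) {
    p <- params
    p$mean_step_time <- p$mean_step_time * exp(stats::rnorm(1, sd = 0.08))
    p$walking_speed <- p$walking_speed * exp(stats::rnorm(1, sd = 0.12))
    p$step_time_cv <- p$step_time_cv * exp(stats::rnorm(1, sd = 0.4))
    p$asymmetry <- p$asymmetry * exp(stats::rnorm(1, sd = 0.4))
    p$noise_sd <- p$noise_sd * exp(stats::rnorm(1, sd = 0.25))
    amp <- p$harmonic_amplitudes *
      exp(stats::rnorm(length(SIX_CHANNELS), sd = 0.3))  # per-channel gain
    # subject-level spread in how peaked the dominant harmonic is
    dom <- apply(p$harmonic_amplitudes, 1, which.max)
    for (ci in seq_along(dom))
      amp[ci, dom[ci]] <- amp[ci, dom[ci]] * exp(stats::rnorm(1, sd = 0.3))
    p$harmonic_amplitudes <- amp
    p
  })
  list(ids = ids, labels = labels, params = plist, seeds = seeds,
       effects = effects)
}

#' Simulate a labeled cohort
#'
#' Defaults reproduce the study's class balance: 89 walkers, 32 of them
#' fall-risk (36\%).  Reproducible bit-for-bit per seed.
#'
#' @inheritParams cohort_plan
#' @return list with `participants` (list of [simulate_participant()]
#'   results, named by id), `labels`, `ids`, `plan`.
#' @export
simulate_cohort <- function(n = 89, n_fall_risk = 32,
                            params = gait_model_params(),
                            effects = class_effects(), seed = 1) {
  plan <- cohort_plan(n, n_fall_risk, params, effects, seed)
  participants <- lapply(seq_len(n), function(i)
    simulate_participant(plan$params[[i]], plan$effects,
                         label = plan$labels[[i]], seed = plan$seeds[[i]],
                         participant_id = plan$ids[[i]]))
  names(participants) <- plan$ids
  list(participants = participants, labels = plan$labels, ids = plan$ids,
       plan = plan)
}
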