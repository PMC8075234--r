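ACC_CHANNELS <- c("acc_ml", "acc_vert", "acc_ap")
AV_CHANNELS  <- c("av_tilt", "av_rotation", "av_obliquity")
SIX_CHANNELS <- c(ACC_CHANNELS, AV_CHANNELS)   # block order: ML, vert, AP, tilt, rotation, obliquity
AGG_STATS    <- c("min", "max", "mean", "sd")

#' The canonical 62-feature per-step catalog
#'
#' Every step contributes a fixed, ordered vector of 62 features; the
#' participant-level vector aggregates each by minimum, maximum, mean and
#' standard deviation over steps, giving 248 features.  Aggregate feature
#' numbering follows `(f - 1) * 4 + s` with `f` the 1-based per-step
#' feature index and `s` the 1-based statistic index in the order
#' min, max, mean, sd — so e.g. aggregate 46 is the maximum over steps of
#' per-step feature 12 (standard deviation of vertical acceleration), and
#' aggregate 185 is the minimum of feature 47 (AP peak distinction).
#'
#' Layout (channel order within each block: ML, vertical, AP accelerations
#' then tilt, rotation, obliquity angular velocities):
#' \itemize{
#'   \item f1: range of vertical acceleration (non-canonical slot; see
#'     `non_canonical` flag)
#'   \item f2-f4 max, f5-f7 min, f8-f10 mean, f11-f13 sd of the three
#'     accelerations
#'   \item f14-f16 range, f17-f19 mean, f20-f22 sd of the three angular
#'     velocities
#'   \item f23 step time, f24 symmetry index, f25 stride time, f26 cadence
#'   \item f27-f32 FQFFT, f33-f38 spectral maximum, f39-f44 spectral sd,
#'     f45-f50 peak distinction, f51-f56 REOH, f57-f62 RMS — each over the
#'     six channels
#' }
#'
#' @return data.frame with columns `feature_index`, `name`, `block`,
#'   `channel`, `non_canonical`; the statistic order is stored in the
#'   `stats` attribute.
#' @export
feature_catalog <- function() {
  if (!is.null(.gaitfall_cache$catalog)) return(.gaitfall_cache$catalog)
  rows <- list()
  add <- function(name, block, channel = NA_character_, non_canonical = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, block = block, channel = channel,
      non_canonical = non_canonical)
  add("range_acc_vert", "range", "acc_vert", non_canonical = TRUE)
  for (ch in ACC_CHANNELS) add(paste0("max_", ch), "max", ch)
  for (ch in ACC_CHANNELS) add(paste0("min_", ch), "min", ch)
  for (ch in ACC_CHANNELS) add(paste0("mean_", ch), "mean", ch)
  for (ch in ACC_CHANNELS) add(paste0("sd_", ch), "sd", ch)
  for (ch in AV_CHANNELS) add(paste0("range_", ch), "range", ch)
  for (ch in AV_CHANNELS) add(paste0("mean_", ch), "mean", ch)
  for (ch in AV_CHANNELS) add(paste0("sd_", ch), "sd", ch, non_canonical = TRUE)
  add("step_time", "temporal"); add("symmetry_index", "temporal")
  add("stride_time", "temporal"); add("cadence", "temporal")
  for (ch in SIX_CHANNELS) add(paste0("fqfft_", ch), "fqfft", ch)
  for (ch in SIX_CHANNELS) add(paste0("specmax_", ch), "specmax", ch)
  for (ch in SIX_CHANNELS) add(paste0("specsd_", ch), "specsd", ch)
  for (ch in SIX_CHANNELS) add(paste0("peakdist_", ch), "peakdist", ch)
  for (ch in SIX_CHANNELS) add(paste0("reoh_", ch), "reoh", ch)
  for (ch in SIX_CHANNELS) add(paste0("rms_", ch), "rms", ch)
  cat <- do.call(rbind, rows)
  cat <- cbind(feature_index = seq_len(nrow(cat)), cat)
  stopifnot(nrow(cat) == 62)
  attr(cat, "stats") <- AGG_STATS
  .gaitfall_cache$catalog <- cat
  cat
}

.gaitfall_cache <- new.env(parent = emptyenv())

#' Aggregate feature numbering
#'
#' @param feature per-step feature index (1-62) or name.
#' @param stat statistic index (1-4) or name in `c("min","max","mean","sd")`.
#' @param catalog a [feature_catalog()].
#' @return the 1-based aggregate feature number `(f - 1) * 4 + s`.
#' @export
aggregate_index <- function(feature, stat, catalog = feature_catalog()) {
  if (is.character(feature)) feature <- match(feature, catalog$name)
  if (is.character(stat)) stat <- match(stat, AGG_STATS)
  stopifnot(!is.na(feature), !is.na(stat), feature >= 1, feature <= 62,
            stat >= 1, stat <= 4)
  (feature - 1L) * 4L + stat
}

#' Names of the 248 aggregate features
#' @param catalog a [feature_catalog()].
#' @return character vector of length 248, in aggregate-index order.
#' @export
aggregate_feature_names <- function(catalog = feature_catalog()) {
  as.vector(t(outer(catalog$name, AGG_STATS, paste, sep = "__")))
}

#' One-sided magnitude spectrum of a step segment
#'
#' Magnitudes of the discrete Fourier transform of the mean-removed,
#' unwindowed segment; one-sided with the DC bin excluded.  No zero padding.
#'
#' @param x real signal segment (length >= 2).
#' @param sample_rate Hz.
#' @return list with `freqs` (Hz, in `(0, nyquist]`), `mags` (>= 0) and
#'   `nyquist`.
#' @export
compute_spectrum <- function(x, sample_rate) {
  n <- length(x)
  if (n < 2) stop("segment too short for a spectrum (need >= 2 samples)")
  x <- x - mean(x)
  ft <- stats::fft(x)
  k <- seq_len(n %/% 2)          # bins 1..floor(n/2); DC (k = 0) excluded
  list(freqs = k * sample_rate / n,
       mags = Mod(ft[k + 1L]),
       nyquist = sample_rate / 2)
}

#' First-quartile FFT fraction (FQFFT)
#'
#' Percentage of total spectral magnitude at frequencies at or below the
#' first quartile of the Nyquist frequency (6.25 Hz for 50 Hz data).  Lower
#' values mean more high-frequency content, associated with unstable gait.
#'
#' @param spec a spectrum from [compute_spectrum()].
#' @return percent in \[0, 100\], or `NA` if the spectrum has zero total
#'   magnitude.
#' @export
fqfft <- function(spec) {
  tot <- sum(spec$mags)
  if (tot <= 0) return(NA_real_)
  cutoff <- spec$nyquist / 4
  100 * sum(spec$mags[spec$freqs <= cutoff]) / tot
}

#' Ratio of even to odd harmonics (REOH)
#'
#' With the stride frequency `1 / stride_time` as fundamental, each
#' harmonic at or below Nyquist is mapped to its nearest spectral bin and
#' the even-harmonic magnitudes are summed against the odd-harmonic ones.
#' Lower values have been associated with fall risk.
#'
#' @param spec a spectrum from [compute_spectrum()].
#' @param stride_time stride duration in seconds (> 0), or `NA`.
#' @param eps regularizer added to the odd-harmonic sum (default 1e-12).
#' @return non-negative ratio, or `NA` when `stride_time` is undefined.
#' @export
reoh <- function(spec, stride_time, eps = 1e-12) {
  if (is.na(stride_time) || stride_time <= 0) return(NA_real_)
  f0 <- 1 / stride_time
  ks <- seq_len(floor(spec$nyquist / f0))
  if (!length(ks)) return(NA_real_)
  bins <- vapply(ks * f0, function(f) which.min(abs(spec$freqs - f)), 1L)
  even <- sum(spec$mags[bins[ks %% 2 == 0]])
  odd <- sum(spec$mags[bins[ks %% 2 == 1]])
  even / (odd + eps)
}

#' Spectral peak distinction
#'
#' Percentage of spectral bins whose magnitude exceeds one third of the
#' peak magnitude.  A lower value means a more distinct dominant peak;
#' fall-risk walkers tend to show more distinct peaks.
#'
#' @param spec a spectrum from [compute_spectrum()].
#' @return percent in \[0, 100\], or `NA` for an all-zero spectrum.
#' @export
peak_distinction <- function(spec) {
  m <- spec$mags
  if (!length(m) || max(m) <= 0) return(NA_real_)
  100 * sum(m > max(m) / 3) / length(m)
}

#' Step-time symmetry index
#'
#' Normalized percent difference between mean right and mean left step
#' times: `100 * |mean_R - mean_L| / (0.5 * (mean_R + mean_L))`.  0 is
#' perfect symmetry.
#'
#' @param left_step_times,right_step_times step durations in seconds.
#' @return percent, or `NA` when either side has no steps.
#' @export
symmetry_index <- function(left_step_times, right_step_times) {
  if (!length(left_step_times) || !length(right_step_times)) return(NA_real_)
  ml <- mean(left_step_times); mr <- mean(right_step_times)
  100 * abs(mr - ml) / (0.5 * (mr + ml))
}

#' Per-step feature vector
#'
#' Computes the 62 catalog features for one step window: the six channels
#' clipped to `[strike_i, strike_{i+1})`.  The symmetry index (f24) is a
#' per-participant quantity and is left `NA` here; [aggregate_features()]
#' callers fill it (see [build_feature_sets()]).  When `stride_time` is
#' undefined (last step of a sequence) the stride feature is `NA` and REOH
#' falls back to `reoh_stride_time`, typically the participant's mean
#' stride.
#'
#' @param signals named list of the six channel segments (`acc_ml`,
#'   `acc_vert`, `acc_ap`, `av_tilt`, `av_rotation`, `av_obliquity`).
#' @param step_time step duration in seconds.
#' @param stride_time stride duration (s) or `NA`.
#' @param sample_rate Hz.
#' @param reoh_stride_time stride time used for REOH when `stride_time` is
#'   `NA` (default: `stride_time`).
#' @return named numeric vector of length 62.
#' @export
per_step_features <- function(signals, step_time, stride_time, sample_rate,
                              reoh_stride_time = stride_time) {
  stopifnot(all(SIX_CHANNELS %in% names(signals)), step_time > 0)
  if (length(signals[[1]]) < 2) stop("step window must hold >= 2 samples")
  cat <- feature_catalog()
  v <- numeric(62)
  specs <- lapply(SIX_CHANNELS, function(ch)
    compute_spectrum(signals[[ch]], sample_rate))
  names(specs) <- SIX_CHANNELS
  rt <- if (is.na(stride_time)) reoh_stride_time else stride_time
  for (i in seq_len(62)) {
    ch <- cat$channel[i]
    x <- if (!is.na(ch)) signals[[ch]] else NULL
    v[i] <- switch(cat$block[i],
      range = diff(range(x)),
      max = max(x),
      min = min(x),
      mean = mean(x),
      sd = sd(x),
      temporal = switch(cat$name[i],
        step_time = step_time,
        symmetry_index = NA_real_,
        stride_time = stride_time,
        cadence = 60 / step_time),
      fqfft = fqfft(specs[[ch]]),
      specmax = max(specs[[ch]]$mags),
      specsd = sd(specs[[ch]]$mags),
      peakdist = peak_distinction(specs[[ch]]),
      reoh = reoh(specs[[ch]], rt),
      rms = sqrt(mean(x^2)))
  }
  names(v) <- cat$name
  v
}

# sd over steps; a single step has, by convention, zero spread
agg_sd <- function(x) if (length(x) <= 1) 0 else sd(x)

#' Aggregate per-step features into a participant vector
#'
#' For each of the 62 per-step features, the minimum, maximum, mean and
#' standard deviation over steps are computed (NA step values skipped),
#' yielding 248 features laid out by [aggregate_index()].  A feature
#' undefined for every step aggregates to `NA`.
#'
#' @param per_step numeric matrix, steps x 62.
#' @return named numeric vector of length 248.
#' @export
aggregate_features <- function(per_step) {
  if (is.null(dim(per_step))) per_step <- matrix(per_step, nrow = 1)
  if (nrow(per_step) < 1) stop("no steps to aggregate")
  if (ncol(per_step) != 62) stop("per-step matrix must have 62 columns")
  out <- numeric(248)
  for (f in seq_len(62)) {
    x <- per_step[, f]
    x <- x[!is.na(x)]
    base <- (f - 1L) * 4L
    if (!length(x)) {
      out[base + 1:4] <- NA_real_
    } else {
      out[base + 1L] <- min(x)
      out[base + 2L] <- max(x)
      out[base + 3L] <- mean(x)
      out[base + 4L] <- agg_sd(x)
    }
  }
  names(out) <- aggregate_feature_names()
  out
}

# Slice one step's six channels out of a recording: frames [a, b)
step_window_signals <- function(recording, a, b) {
  idx <- a:(b - 1L)
  lapply(recording$channels[SIX_CHANNELS], function(x) x[idx])
}

#' Per-step feature matrix for a whole recording
#'
#' @param recording an [imu_recording()].
#' @param steps a labeled or unlabeled [step_sequence()].
#' @return matrix (steps x 62) with the catalog feature names as columns;
#'   row order follows the step order.
#' @export
step_feature_matrix <- function(recording, steps) {
  ns <- n_steps(steps)
  if (ns < 1) stop("no steps")
  fr <- steps$strikes$frame
  tm <- steps$strikes$time
  step_times <- diff(tm)
  stride_times <- rep(NA_real_, ns)
  if (ns >= 2)
    stride_times[1:(ns - 1)] <- tm[3:(ns + 1)] - tm[1:(ns - 1)]
  mean_stride <- if (all(is.na(stride_times))) 2 * mean(step_times) else
    mean(stride_times, na.rm = TRUE)
  m <- matrix(NA_real_, ns, 62, dimnames = list(NULL, feature_catalog()$name))
  for (i in seq_len(ns)) {
    sig <- step_window_signals(recording, fr[i], fr[i + 1L])
    m[i, ] <- per_step_features(sig, step_times[i], stride_times[i],
                                recording$sample_rate,
                                reoh_stride_time = mean_stride)
  }
  m
}

#' Build the four participant feature vectors (AS, S, T, S&T)
#'
#' Aggregates the per-step features over all steps (AS), straight steps
#' only (S), turn steps only (T), and concatenates S then T into the
#' 496-feature S&T vector (names suffixed `_S` / `_T`).  The symmetry
#' index slot is filled per subset from that subset's left/right mean step
#' times before aggregation, so its across-step spread is zero by
#' construction.
#'
#' @param recording an [imu_recording()].
#' @param steps a labeled [step_sequence()] (see [label_steps()]).
#' @return list with elements `AS`, `S`, `T` (length-248 vectors or `NULL`
#'   when a subset has no steps), `ST` (length-496 or `NULL`), and
#'   `missing` (character vector of unavailable sets).
#' @export
build_feature_sets <- function(recording, steps) {
  if (is.null(steps$labels)) stop("steps must be labeled (run label_steps)")
  per_step <- step_feature_matrix(recording, steps)
  sides <- steps$strikes$side[-nrow(steps$strikes)]  # side of the striking foot
  step_times <- per_step[, "step_time"]
  si_col <- match("symmetry_index", colnames(per_step))
  agg_subset <- function(keep) {
    if (!any(keep)) return(NULL)
    m <- per_step[keep, , drop = FALSE]
    si <- symmetry_index(step_times[keep & sides == "left"],
                         step_times[keep & sides == "right"])
    m[, si_col] <- si
    aggregate_features(m)
  }
  all_steps <- rep(TRUE, nrow(per_step))
  AS <- agg_subset(all_steps)
  S <- agg_subset(steps$labels == "straight")
  TT <- agg_subset(steps$labels == "turn")
  missing <- character(0)
  if (is.null(S)) missing <- c(missing, "S")
  if (is.null(TT)) missing <- c(missing, "T")
  ST <- NULL
  if (!is.null(S) && !is.null(TT)) {
    ST <- c(stats::setNames(S, paste0(names(S), "_S")),
            stats::setNames(TT, paste0(names(TT), "_T")))
  } else missing <- c(missing, "S&T")
  list(AS = AS, S = S, T = TT, ST = ST, missing = missing)
}
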