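#' Segmentation parameters
#'
#' Tunables for foot-strike and turn detection.  Defaults target a 180-degree
#' cone turn on a 20 m walkway at 50 Hz.
#'
#' @param init_window_s seconds of signal used to bootstrap the step
#'   duration estimate (default 10).
#' @param search_band multiplicative band around the predicted next strike,
#'   as fractions of the running-average step duration (default
#'   `c(0.5, 1.5)`).
#' @param running_avg_span number of most recent inter-strike intervals
#'   averaged to predict the next strike (default 4).
#' @param min_peak_height minimum AP-acceleration peak height in m/s^2 for a
#'   confident strike (default 0.5).
#' @param turn_rate_thresh pelvis yaw-rate threshold in deg/s marking
#'   rotation onset/offset (default 15).
#' @param turn_min_rotation minimum net rotation in degrees for a candidate
#'   interval to count as a turn (default 100).
#' @param smooth_cutoff_hz zero-phase low-pass cutoff applied to the yaw
#'   rate before thresholding (default 2).
#' @param step_duration_range admissible step durations in seconds
#'   (default `c(0.3, 1.5)`).
#' @return a list of class `segmentation_params`.
#' @export
segmentation_params <- function(init_window_s = 10,
                                search_band = c(0.5, 1.5),
                                running_avg_span = 4,
                                min_peak_height = 0.5,
                                turn_rate_thresh = 15,
                                turn_min_rotation = 100,
                                smooth_cutoff_hz = 2,
                                step_duration_range = c(0.3, 1.5)) {
  stopifnot(search_band[1] < search_band[2],
            min_peak_height > 0, turn_rate_thresh > 0,
            turn_min_rotation > 0, smooth_cutoff_hz > 0,
            step_duration_range[1] < step_duration_range[2])
  structure(list(init_window_s = init_window_s, search_band = search_band,
                 running_avg_span = running_avg_span,
                 min_peak_height = min_peak_height,
                 turn_rate_thresh = turn_rate_thresh,
                 turn_min_rotation = turn_min_rotation,
                 smooth_cutoff_hz = smooth_cutoff_hz,
                 step_duration_range = step_duration_range),
            class = "segmentation_params")
}

#' Construct a step sequence
#'
#' An ordered set of foot strikes for one recording.  Steps are the
#' half-open frame windows between consecutive strikes
#' `[strike_i, strike_{i+1})`; a sequence of `n` strikes therefore holds
#' `n - 1` steps.  `labels`, when present, assigns `"turn"` or `"straight"`
#' to each step.
#'
#' @param strikes data.frame with columns `frame` (1-based, strictly
#'   increasing), `time` (s), `side` (`"left"`/`"right"`), `source`
#'   (`"auto"`/`"manual"`).
#' @param labels optional character vector of per-step labels, length
#'   `nrow(strikes) - 1`.
#' @param participant_id recording reference.
#' @param truncated_turns number of turns whose 5-step window was clipped at
#'   a recording edge (set by [label_steps()]).
#' @return an object of class `step_sequence`.
#' @export
step_sequence <- function(strikes, labels = NULL, participant_id = "unknown",
                          truncated_turns = 0L) {
  stopifnot(is.data.frame(strikes),
            all(c("frame", "time", "side", "source") %in% names(strikes)))
  strikes$frame <- as.integer(strikes$frame)
  if (nrow(strikes) >= 2 && any(diff(strikes$frame) <= 0))
    stop("strike frames must be strictly increasing")
  if (!all(strikes$side %in% c("left", "right")))
    stop("side must be 'left' or 'right'")
  if (!is.null(labels)) {
    if (length(labels) != nrow(strikes) - 1)
      stop("need one label per step (= strikes - 1)")
    if (!all(labels %in% c("turn", "straight")))
      stop("labels must be 'turn' or 'straight'")
  }
  structure(list(strikes = strikes, labels = labels,
                 participant_id = participant_id,
                 truncated_turns = as.integer(truncated_turns)),
            class = "step_sequence")
}

#' @export
print.step_sequence <- function(x, ...) {
  n <- nrow(x$strikes)
  cat(sprintf("<step_sequence> %s: %d strikes (%d steps)", x$participant_id,
              n, max(n - 1L, 0L)))
  if (!is.null(x$labels))
    cat(sprintf(", %d turn / %d straight steps",
                sum(x$labels == "turn"), sum(x$labels == "straight")))
  cat("\n")
  invisible(x)
}

#' Number of steps in a sequence
#' @param steps a `step_sequence`.
#' @return integer.
#' @export
n_steps <- function(steps) max(nrow(steps$strikes) - 1L, 0L)

# indices i with x[i] a strict-left / weak-right local maximum
local_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

#' Estimate the initial average step duration
#'
#' Autocorrelates the first `init_window_s` seconds of AP acceleration and
#' returns the lag of the strongest autocorrelation peak inside the
#' admissible step-duration band.  Used to bootstrap the strike detector's
#' prediction of where the next strike should fall.
#'
#' @param acc_ap anterior-posterior acceleration signal (m/s^2).
#' @param sample_rate Hz.
#' @param params a [segmentation_params()].
#' @return step duration in seconds.
#' @export
estimate_initial_step_duration <- function(acc_ap, sample_rate,
                                           params = segmentation_params()) {
  win <- min(length(acc_ap), round(params$init_window_s * sample_rate))
  if (win < params$step_duration_range[2] * 2 * sample_rate)
    stop("signal too short to estimate step duration")
  x <- acc_ap[seq_len(win)]
  x <- x - mean(x)
  if (sd(x) == 0) stop("no periodicity: signal has no variance")
  max_lag <- ceiling(params$step_duration_range[2] * sample_rate)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1L
  pk <- local_peaks(ac)
  lo <- params$step_duration_range[1] * sample_rate
  hi <- params$step_duration_range[2] * sample_rate
  pk <- pk[lags[pk] >= lo & lags[pk] <= hi]
  pk <- pk[ac[pk] > 0.1]          # require genuine periodic structure
  if (!length(pk)) stop("no periodicity in the admissible step-duration band")
  # first prominent peak: the step lag, not the (often stronger) stride lag
  best <- pk[ac[pk] >= 0.5 * max(ac[pk])][1]
  lags[best] / sample_rate
}

#' Detect foot strikes from anterior-posterior acceleration
#'
#' Greedy forward pass: from the last accepted strike, the next one is
#' predicted one running-average step duration ahead; the candidate is the
#' largest local AP-acceleration peak inside the search band around that
#' prediction (peaks above `min_peak_height` preferred; if the band holds
#' only sub-threshold peaks the largest of those is taken, so an attenuated
#' impact still yields a strike).  The running average is the mean of the
#' last `running_avg_span` inter-strike intervals, clamped to the admissible
#' step-duration range.  Sides alternate, seeded from the sign of ML
#' acceleration at the first strike (right-positive convention).
#'
#' @param recording an [imu_recording()].
#' @param params a [segmentation_params()].
#' @return a [step_sequence()].
#' @export
detect_foot_strikes <- function(recording, params = segmentation_params()) {
  fs <- recording$sample_rate
  x <- recording$channels$acc_ap
  n <- length(x)
  avg <- estimate_initial_step_duration(x, fs, params)
  rng <- params$step_duration_range
  band <- params$search_band

  pick <- function(from, to) {
    from <- max(from, 2L); to <- min(to, n - 1L)
    if (from > to) return(NA_integer_)
    idx <- local_peaks(x[(from - 1L):(to + 1L)]) + from - 2L
    if (!length(idx)) return(NA_integer_)
    strong <- idx[x[idx] >= params$min_peak_height]
    cand <- if (length(strong)) strong else idx
    cand[which.max(x[cand])]
  }

  # first strike: largest peak within the first 1.5 estimated step durations
  first <- pick(1L, ceiling(band[2] * avg * fs))
  if (is.na(first)) first <- pick(1L, ceiling(2 * avg * fs))
  frames <- integer(0)
  if (!is.na(first)) frames <- first
  intervals <- numeric(0)
  pos <- if (length(frames)) frames[1] else 1L
  while (TRUE) {
    lo <- pos + floor(band[1] * avg * fs)
    hi <- pos + ceiling(band[2] * avg * fs)
    if (lo > n - 1L) break
    cand <- pick(lo, hi)
    if (is.na(cand)) {          # flat stretch: slide the window forward
      pos <- pos + round(avg * fs)
      next
    }
    if (length(frames)) {
      intervals <- c(intervals, (cand - frames[length(frames)]) / fs)
      keep <- tail(intervals, params$running_avg_span)
      avg <- min(max(mean(keep), rng[1]), rng[2])
    }
    frames <- c(frames, cand)
    pos <- cand
  }
  if (length(frames) < 10)
    stop("insufficient steps: only ", length(frames),
         " foot strikes detected (need >= 10)")
  ml0 <- recording$channels$acc_ml[frames[1]]
  first_side <- if (ml0 >= 0) "right" else "left"
  sides <- rep(c(first_side, setdiff(c("left", "right"), first_side)),
               length.out = length(frames))
  strikes <- data.frame(frame = frames,
                        time = recording$time[frames],
                        side = sides, source = "auto")
  step_sequence(strikes, participant_id = recording$participant_id)
}

#' Apply manual corrections to a step sequence
#'
#' Automated strike detection can fail on highly asymmetric or variable
#' gait; this provides the reproducible equivalent of a manual clean-up
#' pass.  Edits are a list of moves with fields `op`
#' (`"add"`/`"remove"`/`"move"`), `frame`, and for adds `side`, for moves
#' `to`.  Edited strikes are marked `source = "manual"` and the sequence is
#' re-sorted and revalidated.  Side alternation is not enforced across
#' manual edits.
#'
#' @param steps a [step_sequence()].
#' @param edits list of edit records, or a path to a JSON file holding one.
#' @param recording optional [imu_recording()] used to refresh strike times
#'   and bound frames.
#' @return the edited `step_sequence` (labels dropped; re-run
#'   [label_steps()]).
#' @export
apply_manual_corrections <- function(steps, edits, recording = NULL) {
  if (is.character(edits) && length(edits) == 1)
    edits <- jsonlite::read_json(edits, simplifyVector = FALSE)
  s <- steps$strikes
  fs <- if (!is.null(recording)) recording$sample_rate else
    1 / median(diff(s$time))
  t0 <- s$time[1] - (s$frame[1] - 1) / fs
  frame_time <- function(f) if (!is.null(recording)) recording$time[f] else
    t0 + (f - 1) / fs
  for (e in edits) {
    op <- e$op
    f <- as.integer(e$frame)
    if (!is.null(recording) && (f < 1 || f > n_frames(recording)))
      stop("edit frame ", f, " outside recording")
    if (op == "add") {
      if (f %in% s$frame) stop("add would duplicate strike at frame ", f)
      side <- if (is.null(e$side)) "left" else e$side
      s <- rbind(s, data.frame(frame = f, time = frame_time(f),
                               side = side, source = "manual"))
    } else if (op == "remove") {
      if (!f %in% s$frame) stop("no strike at frame ", f, " to remove")
      s <- s[s$frame != f, ]
    } else if (op == "move") {
      to <- as.integer(e$to)
      if (!f %in% s$frame) stop("no strike at frame ", f, " to move")
      if (to %in% s$frame) stop("move would duplicate strike at frame ", to)
      i <- which(s$frame == f)
      s$frame[i] <- to
      s$time[i] <- frame_time(to)
      s$source[i] <- "manual"
    } else stop("unknown edit op: ", op)
  }
  s <- s[order(s$frame), ]
  rownames(s) <- NULL
  step_sequence(s, participant_id = steps$participant_id)
}

#' Detect turn intervals from pelvis yaw rate
#'
#' The rotation angular velocity is zero-phase low-pass filtered at
#' `smooth_cutoff_hz`; maximal contiguous runs where the smoothed rate
#' exceeds `turn_rate_thresh` in magnitude are candidate turns, kept when
#' the rotation integrated over the run reaches `turn_min_rotation`
#' degrees.  The turn center is the middle frame between rotation onset
#' and offset: `floor((start + end) / 2)`.
#'
#' @param recording an [imu_recording()].
#' @param params a [segmentation_params()].
#' @return data.frame with columns `start_frame`, `end_frame`,
#'   `center_frame`, `net_rotation` (deg); zero rows if no turns.
#' @export
detect_turn_intervals <- function(recording, params = segmentation_params()) {
  fs <- recording$sample_rate
  w <- recording$channels$av_rotation
  wn <- params$smooth_cutoff_hz / (fs / 2)
  if (wn < 1) {
    bf <- signal::butter(2, wn, type = "low")
    sm <- as.numeric(signal::filtfilt(bf, w))
  } else sm <- w
  active <- abs(sm) > params$turn_rate_thresh
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start_frame = integer(0), end_frame = integer(0),
                    center_frame = integer(0), net_rotation = numeric(0))
  for (j in keep) {
    a <- starts[j]; b <- ends[j]
    net <- sum(sm[a:b]) / fs
    if (abs(net) >= params$turn_min_rotation)
      out <- rbind(out, data.frame(start_frame = a, end_frame = b,
                                   center_frame = (a + b) %/% 2L,
                                   net_rotation = net))
  }
  rownames(out) <- NULL
  out
}

#' Label steps turn vs straight
#'
#' A turn comprises the five steps around each turn center: the step whose
#' half-open window `[strike_i, strike_{i+1})` contains the center frame is
#' the middle step, and it plus its two predecessors and two successors are
#' labeled `"turn"`.  All remaining steps are `"straight"`.  Near a
#' recording edge fewer than five steps may exist; those turns are counted
#' in `truncated_turns`.  A turn whose center falls outside every step
#' window is skipped with a warning.
#'
#' @param steps a [step_sequence()].
#' @param turns a turn-interval data.frame from [detect_turn_intervals()].
#' @return the `step_sequence` with `labels` filled and `truncated_turns`
#'   set.
#' @export
label_steps <- function(steps, turns) {
  ns <- n_steps(steps)
  if (ns < 1) stop("step sequence holds no steps")
  frames <- steps$strikes$frame
  labels <- rep("straight", ns)
  truncated <- 0L
  for (j in seq_len(nrow(turns))) {
    ctr <- turns$center_frame[j]
    mid <- findInterval(ctr, frames)
    if (mid < 1 || mid > ns) {
      warning("turn centered at frame ", ctr,
              " lies outside all step windows; skipped")
      next
    }
    lo <- mid - 2L; hi <- mid + 2L
    if (lo < 1L || hi > ns) truncated <- truncated + 1L
    labels[max(lo, 1L):min(hi, ns)] <- "turn"
  }
  step_sequence(steps$strikes, labels = labels,
                participant_id = steps$participant_id,
                truncated_turns = truncated)
}
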