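#' @importFrom stats approx median sd
#' @importFrom utils read.csv write.csv head tail
NULL

# Channels every recording must carry.  Linear acceleration is
# gravity-removed, in m/s^2; angular velocities are deg/s.
REQUIRED_CHANNELS <- c("acc_ml", "acc_vert", "acc_ap",
                       "av_tilt", "av_rotation", "av_obliquity")
ANGLE_CHANNELS <- c("ang_tilt", "ang_rotation", "ang_obliquity")

#' Construct a pelvis IMU recording
#'
#' A recording holds the synchronized 50 Hz channels captured during one
#' six-minute walk test: tri-axial linear acceleration (gravity removed,
#' m/s^2) and pelvic tilt/rotation/obliquity angular velocities (deg/s),
#' with optional pelvis angles (deg).  Axis convention: vertical is
#' up-positive, anterior-posterior (AP) forward-positive, medial-lateral
#' (ML) right-positive.  Frame indices are 1-based.
#'
#' If the pelvis rotation angle is absent it is integrated from the rotation
#' angular velocity, since turn-detection gates on net rotation.
#'
#' @param time numeric vector, seconds from trial start, strictly increasing.
#' @param channels named list of numeric channel vectors; must contain
#'   `acc_ml`, `acc_vert`, `acc_ap`, `av_tilt`, `av_rotation`,
#'   `av_obliquity`, each the same length as `time`.
#' @param sample_rate nominal sampling rate in Hz (default 50).
#' @param participant_id identifier string.
#' @param metadata named list of free-form metadata (walkway length,
#'   prosthesis info, label if known, unknown export columns).
#' @return an object of class `imu_recording`.
#' @export
imu_recording <- function(time, channels, sample_rate = 50,
                          participant_id = "unknown", metadata = list()) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  missing_ch <- setdiff(REQUIRED_CHANNELS, names(channels))
  if (length(missing_ch))
    stop("missing required channel(s): ", paste(missing_ch, collapse = ", "))
  n <- length(time)
  if (n < 2 * sample_rate)
    stop("recording too short: need at least 2 seconds of data")
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing")
  for (ch in names(channels)) {
    if (length(channels[[ch]]) != n)
      stop("channel ", ch, " has length ", length(channels[[ch]]),
           " but time has length ", n)
  }
  if (is.null(channels$ang_rotation))
    channels$ang_rotation <- cumsum(channels$av_rotation) / sample_rate
  rec <- structure(list(
    sample_rate = sample_rate,
    time = as.numeric(time),
    channels = lapply(channels, as.numeric),
    participant_id = as.character(participant_id),
    metadata = metadata
  ), class = "imu_recording")
  rec
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> participant %s: %d frames at %g Hz (%.1f s), channels: %s\n",
              x$participant_id, n_frames(x), x$sample_rate,
              diff(range(x$time)), paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Number of frames in a recording
#' @param rec an `imu_recording`.
#' @return integer frame count.
#' @export
n_frames <- function(rec) length(rec$time)

#' Read a pelvis IMU recording from CSV
#'
#' The default export dialect is a CSV with header
#' `time,acc_ml,acc_vert,acc_ap,av_tilt,av_rotation,av_obliquity` and
#' optional angle columns `ang_tilt,ang_rotation,ang_obliquity`; `time` is
#' seconds from trial start.  Real exports with other column names are
#' handled through `dialect`, a named character vector mapping canonical
#' names to file column names.  Unknown columns are preserved in
#' `metadata$extra_columns`.
#'
#' If the median inter-sample interval deviates more than 2\% from
#' `1/sample_rate`, the channels are linearly resampled onto the nominal
#' rate with a warning.
#'
#' @param path path to a CSV file.
#' @param dialect named character vector mapping canonical channel names
#'   (including `"time"`) to the file's column names; defaults to identity.
#' @param sample_rate nominal rate in Hz.
#' @param participant_id identifier; defaults to the file name sans extension.
#' @return an [imu_recording()].
#' @export
read_recording <- function(path, dialect = NULL, sample_rate = 50,
                           participant_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  canonical <- c("time", REQUIRED_CHANNELS, ANGLE_CHANNELS)
  map <- stats::setNames(canonical, canonical)
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  need <- c("time", REQUIRED_CHANNELS)
  for (ch in need) {
    if (!map[[ch]] %in% names(df))
      stop("recording file is missing required column '", map[[ch]],
           "' (channel ", ch, ")")
  }
  time <- df[[map[["time"]]]]
  if (any(diff(time) <= 0)) stop("time column is not strictly increasing")
  present <- canonical[-1][vapply(canonical[-1],
                                  function(ch) map[[ch]] %in% names(df), TRUE)]
  channels <- lapply(present, function(ch) as.numeric(df[[map[[ch]]]]))
  names(channels) <- present
  known_cols <- unname(map[c("time", present)])
  extra <- setdiff(names(df), known_cols)
  meta <- list()
  if (length(extra)) meta$extra_columns <- df[extra]
  # resample onto the nominal grid when the export clock drifted
  dt <- median(diff(time))
  if (abs(dt - 1 / sample_rate) > 0.02 / sample_rate) {
    warning(sprintf(
      "median sampling interval %.5f s deviates >2%% from nominal %.5f s; resampling",
      dt, 1 / sample_rate))
    new_time <- seq(time[1], time[length(time)], by = 1 / sample_rate)
    channels <- lapply(channels, function(x)
      approx(time, x, xout = new_time, rule = 2)$y)
    time <- new_time
  }
  if (is.null(participant_id))
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  imu_recording(time, channels, sample_rate = sample_rate,
                participant_id = participant_id, metadata = meta)
}

#' Write a recording in the CSV export dialect
#'
#' @param rec an [imu_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  cols <- c(list(time = rec$time), rec$channels)
  df <- as.data.frame(lapply(cols, function(x) formatC(x, digits = 17, format = "g")),
                      check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a participant feature table
#'
#' Feature tables are CSV files with columns `participant_id`, `fall_risk`
#' and then one column per feature.  Values are written with 17 significant
#' digits so the round trip is lossless to floating-point precision;
#' undefined features are written as `NA`.
#'
#' @param table a `feature_table`: data.frame with `participant_id`
#'   (character), `fall_risk` (logical) and numeric feature columns, plus a
#'   `set_id` attribute.
#' @param path file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the table with `set_id` restored from the
#'   `set_id` argument.
#' @export
write_feature_table <- function(table, path) {
  if (anyDuplicated(names(table)))
    stop("duplicate column names in feature table")
  num <- !(names(table) %in% c("participant_id", "fall_risk"))
  out <- table
  out[num] <- lapply(table[num], function(x)
    ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g")))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param set_id feature-set identifier to attach (`"AS"`, `"S"`, `"T"`,
#'   `"S&T"`) or `NULL`.
#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, set_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(df))) stop("duplicate column names in feature table")
  if (!all(c("participant_id", "fall_risk") %in% names(df)))
    stop("feature table must have participant_id and fall_risk columns")
  df$participant_id <- as.character(df$participant_id)
  df$fall_risk <- as.logical(df$fall_risk)
  num <- !(names(df) %in% c("participant_id", "fall_risk"))
  df[num] <- lapply(df[num], as.numeric)
  attr(df, "set_id") <- set_id
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Assemble a feature table from per-participant vectors
#'
#' @param vectors named list (by participant id) of equal-length named
#'   numeric feature vectors.
#' @param labels named logical vector of fall-risk labels, one per
#'   participant id.
#' @param set_id which step set the vectors came from.
#' @return a `feature_table` data.frame.
#' @export
feature_table <- function(vectors, labels, set_id = "AS") {
  ids <- names(vectors)
  stopifnot(length(ids) > 0, !is.null(names(labels)))
  if (!all(ids %in% names(labels)))
    stop("missing label for participant(s): ",
         paste(setdiff(ids, names(labels)), collapse = ", "))
  mat <- do.call(rbind, vectors)
  df <- data.frame(participant_id = ids,
                   fall_risk = unname(labels[ids]),
                   mat, check.names = FALSE, row.names = NULL)
  attr(df, "set_id") <- set_id
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Extract the numeric feature matrix from a feature table
#' @param table a `feature_table`.
#' @return numeric matrix (participants x features).
#' @export
feature_matrix <- function(table) {
  num <- !(names(table) %in% c("participant_id", "fall_risk"))
  as.matrix(as.data.frame(table)[num])
}

#' Write / read step annotations
#'
#' Step annotations are CSV files with columns
#' `frame,time,side,source,label`: one row per foot strike, `label` being
#' the turn/straight label of the step starting at that strike (empty for
#' the final strike, which starts no step).
#'
#' @param steps a `step_sequence` (see [detect_foot_strikes()]).
#' @param path file path.
#' @return the path (write) or a `step_sequence` (read).
#' @export
write_step_annotations <- function(steps, path) {
  s <- steps$strikes
  lab <- c(steps$labels, "")
  if (is.null(steps$labels)) lab <- rep("", nrow(s))
  df <- data.frame(frame = s$frame,
                   time = formatC(s$time, digits = 17, format = "g"),
                   side = s$side, source = s$source, label = lab)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param participant_id id to attach to the sequence on read.
#' @rdname write_step_annotations
#' @export
read_step_annotations <- function(path, participant_id = "unknown") {
  df <- read.csv(path, check.names = FALSE)
  strikes <- data.frame(frame = as.integer(df$frame),
                        time = as.numeric(df$time),
                        side = as.character(df$side),
                        source = as.character(df$source))
  labels <- as.character(df$label[-nrow(df)])
  if (all(labels == "" | is.na(labels))) labels <- NULL
  step_sequence(strikes, labels = labels, participant_id = participant_id)
}

#' Write a model report as JSON
#'
#' @param report any list-like report (grid results, sweeps, robustness
#'   summaries).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
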