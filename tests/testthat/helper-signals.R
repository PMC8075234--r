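# Shared fixtures and independent oracles, built in code at test time.

# Zero every noise channel so generator ground truth is bit-reproducible
zero_noise <- function() c(acc_ml = 0, acc_vert = 0, acc_ap = 0,
                           av_tilt = 0, av_rotation = 0, av_obliquity = 0)

# A short walk (keeps unit tests fast); defaults elsewhere stay at 360 s
short_params <- function(duration = 60, ...)
  gait_model_params(duration = duration, ...)

# Minimal hand-built recording: supply any subset of channels, rest zero
toy_recording <- function(n = 500, fs = 50, ...) {
  given <- list(...)
  channels <- lapply(
    stats::setNames(nm = c("acc_ml", "acc_vert", "acc_ap",
                           "av_tilt", "av_rotation", "av_obliquity")),
    function(ch) if (!is.null(given[[ch]])) given[[ch]] else numeric(n))
  imu_recording(time = (seq_len(n) - 1) / fs, channels, sample_rate = fs,
                participant_id = "toy")
}

# Brute-force one-sided DFT magnitudes (DC excluded), independent of fft()
naive_dft_mags <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  ks <- seq_len(n %/% 2)
  sapply(ks, function(k) {
    w <- -2i * pi * k * (0:(n - 1)) / n
    Mod(sum(x * exp(w)))
  })
}

# Independent recomputation of the whole 62-feature per-step vector
oracle_step_features <- function(sig, step_time, stride_time, fs,
                                 reoh_stride = stride_time) {
  spec_of <- function(x) {
    m <- naive_dft_mags(x, fs)
    list(freqs = seq_along(m) * fs / length(x), mags = m, nyquist = fs / 2)
  }
  o_fqfft <- function(sp)   # first quartile of Nyquist = fs / 8
    100 * sum(sp$mags[sp$freqs <= fs / 8]) / sum(sp$mags)
  o_pd <- function(sp) 100 * mean(sp$mags > max(sp$mags) / 3)
  o_reoh <- function(sp, st) {
    f0 <- 1 / st
    ks <- seq_len(floor(sp$nyquist / f0))
    b <- sapply(ks * f0, function(f) which.min(abs(sp$freqs - f)))
    sum(sp$mags[b[ks %% 2 == 0]]) / (sum(sp$mags[b[ks %% 2 == 1]]) + 1e-12)
  }
  chans <- c("acc_ml", "acc_vert", "acc_ap", "av_tilt", "av_rotation",
             "av_obliquity")
  sp <- lapply(chans, function(ch) spec_of(sig[[ch]]))
  names(sp) <- chans
  st_eff <- if (is.na(stride_time)) reoh_stride else stride_time
  c(diff(range(sig$acc_vert)),
    sapply(chans[1:3], function(ch) max(sig[[ch]])),
    sapply(chans[1:3], function(ch) min(sig[[ch]])),
    sapply(chans[1:3], function(ch) mean(sig[[ch]])),
    sapply(chans[1:3], function(ch) sd(sig[[ch]])),
    sapply(chans[4:6], function(ch) diff(range(sig[[ch]]))),
    sapply(chans[4:6], function(ch) mean(sig[[ch]])),
    sapply(chans[4:6], function(ch) sd(sig[[ch]])),
    step_time, NA_real_, stride_time, 60 / step_time,
    sapply(chans, function(ch) o_fqfft(sp[[ch]])),
    sapply(chans, function(ch) max(sp[[ch]]$mags)),
    sapply(chans, function(ch) sd(sp[[ch]]$mags)),
    sapply(chans, function(ch) o_pd(sp[[ch]])),
    sapply(chans, function(ch) o_reoh(sp[[ch]], st_eff)),
    sapply(chans, function(ch) sqrt(mean(sig[[ch]]^2))),
    use.names = FALSE)
}

# Random step window of random length for oracle sweeps
random_step <- function(fs = 50) {
  n <- sample(20:45, 1)
  sig <- lapply(stats::setNames(nm = c("acc_ml", "acc_vert", "acc_ap",
                                       "av_tilt", "av_rotation",
                                       "av_obliquity")),
                function(ch) rnorm(n))
  list(sig = sig, step_time = n / fs,
       stride_time = 2 * n / fs * runif(1, 0.9, 1.1))
}

# Small random feature table (no simulation needed)
random_feature_table <- function(n = 20, p = 12, seed = 1, set_id = "AS",
                                 informative = 0) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("feat", seq_len(p))))
  if (informative > 0)
    for (j in seq_len(informative))
      X[, j] <- as.numeric(y) * 2 + rnorm(n, sd = 0.3)
  vecs <- lapply(seq_len(n), function(i) X[i, ])
  ids <- sprintf("P%03d", seq_len(n))
  names(vecs) <- ids
  feature_table(vecs, stats::setNames(y, ids), set_id = set_id)
}
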