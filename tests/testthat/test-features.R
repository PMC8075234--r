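test_that("spectra equal a brute-force DFT and behave on pure tones", {
  fs <- 50
  set.seed(7)
  x <- rnorm(30)
  sp <- compute_spectrum(x, fs)
  expect_lt(max(abs(sp$mags - naive_dft_mags(x, fs))), 1e-9)
  expect_equal(sp$freqs, (1:15) * fs / 30)
  expect_equal(sp$nyquist, 25)
  # bin-aligned 5 Hz tone: one dominant bin at 5 Hz
  t <- (0:49) / fs
  sp5 <- compute_spectrum(sin(2 * pi * 5 * t), fs)
  expect_equal(sp5$freqs[which.max(sp5$mags)], 5)
  expect_gt(max(sp5$mags) / (sum(sp5$mags) - max(sp5$mags) + 1e-12), 1e6)
  # constant signal vanishes after mean removal
  expect_lt(max(compute_spectrum(rep(3.2, 40), fs)$mags), 1e-9)
  expect_error(compute_spectrum(1, fs), "2 samples")
})

test_that("FQFFT is the spectral fraction below a quarter of Nyquist", {
  fs <- 50; t <- (0:49) / fs
  expect_equal(fqfft(compute_spectrum(sin(2 * pi * 2 * t), fs)), 100,
               tolerance = 1e-6)
  expect_equal(fqfft(compute_spectrum(sin(2 * pi * 10 * t), fs)), 0,
               tolerance = 1e-6)
  both <- sin(2 * pi * 2 * t) + sin(2 * pi * 10 * t)
  expect_equal(fqfft(compute_spectrum(both, fs)), 50, tolerance = 1e-4)
  # cutoff sits exactly at sample_rate / 2 / 4
  sp <- list(freqs = c(6.25, 6.5), mags = c(1, 1), nyquist = 25)
  expect_equal(fqfft(sp), 50)
  expect_true(is.na(fqfft(list(freqs = 1:5, mags = rep(0, 5), nyquist = 25))))
})

test_that("REOH contrasts even against odd stride harmonics", {
  sp <- function(mags) list(freqs = 1:25, mags = mags, nyquist = 25)
  m <- numeric(25)
  m[4] <- 1                       # 2 * f0 with f0 = 2 Hz: even only
  expect_gt(reoh(sp(m), stride_time = 0.5), 1e10)
  m2 <- numeric(25); m2[2] <- 1   # f0 only: odd only
  expect_equal(reoh(sp(m2), stride_time = 0.5), 0, tolerance = 1e-9)
  m3 <- numeric(25); m3[2] <- 1; m3[4] <- 1
  expect_equal(reoh(sp(m3), stride_time = 0.5), 1, tolerance = 1e-9)
  expect_true(is.na(reoh(sp(m3), stride_time = NA)))
})

test_that("peak distinction counts bins above one third of the peak", {
  sp <- function(mags) list(freqs = seq_along(mags), mags = mags,
                            nyquist = length(mags))
  expect_equal(peak_distinction(sp(rep(2, 12))), 100)
  expect_equal(peak_distinction(sp(c(1, rep(0, 18)))), 100 / 19,
               tolerance = 1e-12)          # one distinct peak: 5.26%
  expect_equal(peak_distinction(sp(c(3, 1, 1))), 100 / 3, tolerance = 1e-12)
  expect_true(is.na(peak_distinction(sp(rep(0, 10)))))
})

test_that("symmetry index is the normalized left/right step-time gap", {
  expect_equal(symmetry_index(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(symmetry_index(0.4, 0.6), 40)
  expect_equal(symmetry_index(0.45, 0.55), 20)
  expect_true(is.na(symmetry_index(numeric(0), 0.5)))
})

test_that("the per-step vector matches an independent oracle", {
  fs <- 50
  set.seed(11)
  for (rep in 1:100) {
    st <- random_step(fs)
    got <- per_step_features(st$sig, st$step_time, st$stride_time, fs)
    expect_equal(length(got), 62)
    want <- oracle_step_features(st$sig, st$step_time, st$stride_time, fs)
    # the symmetry slot is a participant-level quantity, NA per step
    expect_true(is.na(got[["symmetry_index"]]))
    idx <- setdiff(seq_len(62), 24)
    expect_lt(max(abs(unname(got[idx]) - want[idx])), 1e-9)
  }
})

test_that("a constant-signal step collapses its descriptive statistics", {
  sig <- lapply(stats::setNames(nm = c("acc_ml", "acc_vert", "acc_ap",
                                       "av_tilt", "av_rotation",
                                       "av_obliquity")),
                function(ch) rep(1.5, 25))
  v <- per_step_features(sig, 0.5, 1.0, 50)
  expect_equal(unname(v[c("sd_acc_ml", "sd_acc_vert", "sd_acc_ap")]),
               rep(0, 3))
  expect_equal(unname(v["min_acc_ml"]), unname(v["max_acc_ml"]))
  expect_equal(unname(v["mean_acc_ml"]), 1.5)
  expect_equal(unname(v["cadence"]), 60 / 0.5)
})

test_that("aggregation lays out 248 features as (f-1)*4+s", {
  set.seed(3)
  m <- matrix(rnorm(10 * 62), 10, 62)
  agg <- aggregate_features(m)
  expect_equal(length(agg), 248)
  for (f in c(1, 12, 24, 47, 62)) {
    x <- m[, f]
    expect_equal(unname(agg[(f - 1) * 4 + 1]), min(x), tolerance = 1e-12)
    expect_equal(unname(agg[(f - 1) * 4 + 2]), max(x), tolerance = 1e-12)
    expect_equal(unname(agg[(f - 1) * 4 + 3]), mean(x), tolerance = 1e-12)
    expect_equal(unname(agg[(f - 1) * 4 + 4]), sd(x), tolerance = 1e-12)
  }
  # single step: min = max = mean, spread 0
  one <- aggregate_features(m[1, , drop = FALSE])
  expect_equal(unname(one[1]), unname(one[2]))
  expect_equal(unname(one[4]), 0)
  # NA steps are skipped; an all-NA feature aggregates to NA
  m2 <- m; m2[, 5] <- NA; m2[1:3, 6] <- NA
  agg2 <- aggregate_features(m2)
  expect_true(all(is.na(agg2[(5 - 1) * 4 + 1:4])))
  expect_equal(unname(agg2[(6 - 1) * 4 + 3]), mean(m2[4:10, 6]),
               tolerance = 1e-12)
  expect_error(aggregate_features(m[0, , drop = FALSE]), "no steps")
})

test_that("the catalog reproduces the published aggregate numbering", {
  cat62 <- feature_catalog()
  expect_equal(nrow(cat62), 62)
  expect_identical(attr(cat62, "stats"), c("min", "max", "mean", "sd"))
  # frozen (feature, statistic) -> aggregate-number assignments
  known <- list(
    list("max_acc_vert", "max", 10),  list("max_acc_vert", "sd", 12),
    list("max_acc_ap", "mean", 15),   list("max_acc_ap", "sd", 16),
    list("mean_acc_ml", "sd", 32),    list("mean_acc_vert", "min", 33),
    list("sd_acc_vert", "max", 46),   list("sd_acc_vert", "sd", 48),
    list("range_av_tilt", "sd", 56),  list("mean_av_tilt", "min", 65),
    list("mean_av_rotation", "sd", 72),
    list("mean_av_obliquity", "mean", 75),
    list("step_time", "max", 90),     list("step_time", "mean", 91),
    list("step_time", "sd", 92),
    list("stride_time", "min", 97),   list("stride_time", "max", 98),
    list("stride_time", "mean", 99),  list("stride_time", "sd", 100),
    list("cadence", "min", 101),      list("cadence", "mean", 103),
    list("fqfft_acc_ml", "min", 105), list("fqfft_acc_ml", "sd", 108),
    list("fqfft_acc_vert", "sd", 112),
    list("fqfft_av_tilt", "mean", 119),
    list("fqfft_av_rotation", "min", 121),
    list("specmax_av_tilt", "mean", 143),
    list("specsd_acc_ml", "min", 153),
    list("specsd_acc_ap", "min", 161),
    list("specsd_av_rotation", "mean", 171),
    list("specsd_av_obliquity", "sd", 176),
    list("peakdist_acc_ml", "mean", 179),
    list("peakdist_acc_vert", "max", 182),
    list("peakdist_acc_vert", "mean", 183),
    list("peakdist_acc_ap", "min", 185),
    list("peakdist_av_tilt", "min", 189),
    list("peakdist_av_rotation", "min", 193),
    list("peakdist_av_rotation", "max", 194),
    list("peakdist_av_obliquity", "mean", 199),
    list("reoh_acc_vert", "min", 205), list("reoh_acc_vert", "max", 206),
    list("reoh_acc_vert", "mean", 207),
    list("rms_av_rotation", "min", 241))
  for (k in known)
    expect_equal(aggregate_index(k[[1]], k[[2]], cat62), k[[3]])
  # names line up with the numbering
  nm <- aggregate_feature_names(cat62)
  expect_equal(length(nm), 248)
  expect_identical(nm[46], "sd_acc_vert__max")
  expect_identical(nm[185], "peakdist_acc_ap__min")
})

test_that("the four feature sets have the stated shapes and relations", {
  sim <- simulate_participant(short_params(180), seed = 23)
  out <- process_recording(sim$recording)
  f <- out$features
  expect_equal(length(f$AS), 248)
  expect_equal(length(f$S), 248)
  expect_equal(length(f$T), 248)
  expect_equal(length(f$ST), 496)
  expect_equal(unname(f$ST[1:248]), unname(f$S))   # S & T concatenation
  expect_equal(unname(f$ST[249:496]), unname(f$T))
  expect_identical(names(f$ST)[1], paste0(names(f$S)[1], "_S"))
  # symmetry index aggregates with zero spread by construction
  expect_equal(unname(f$AS[aggregate_index("symmetry_index", "sd")]), 0)

  # all-straight walker: AS == S and T flagged missing
  steps <- out$steps
  all_straight <- step_sequence(steps$strikes,
                                labels = rep("straight", n_steps(steps)),
                                participant_id = steps$participant_id)
  f2 <- build_feature_sets(sim$recording, all_straight)
  expect_equal(unname(f2$AS), unname(f2$S))
  expect_null(f2$T)
  expect_true(all(c("T", "S&T") %in% f2$missing))
})
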