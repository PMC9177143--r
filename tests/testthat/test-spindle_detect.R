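test_that("Hilbert envelope recovers amplitude and tracks modulation", {
  fs <- 200
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- 4 * sin(2 * pi * 13 * t)
  env <- spindle_envelope(fir_bandpass(x, fs, 10, 16), fs)
  core <- 1000:5000
  expect_true(all(abs(env[core] - 4) / 4 < 0.02))
  # amplitude-modulated burst: envelope follows the modulator
  mod <- 1 + 0.5 * sin(2 * pi * 0.4 * t)
  env2 <- spindle_envelope(fir_bandpass(mod * sin(2 * pi * 13 * t), fs, 10, 16),
                           fs)
  expect_true(all(abs(env2[core] - mod[core]) / mod[core] < 0.05))
  expect_true(all(spindle_envelope(numeric(4000), fs) < 1e-9))
  expect_error(spindle_envelope(rnorm(100), fs, smooth_win = 0.001), "window")
})

test_that("spindle duration gate keeps 0.5-3 s events only", {
  fs <- 200
  dur <- 60
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  mk <- function(onset, len) {
    burst <- numeric(length(t))
    idx <- round(onset * fs):(round(onset * fs) + round(len * fs))
    u <- seq(0, 1, length.out = length(idx))
    burst[idx] <- 30 * sin(2 * pi * 13 * t[idx]) * sin(pi * u)
    burst
  }
  noise <- pink_noise(length(t), rms = 5, seed = 8)
  thr <- 10  # calibrated absolute threshold, high-SNR regime
  one <- detect_spindles(mk(20, 1.0) + noise, fs, threshold = thr)
  expect_equal(nrow(one), 1)
  expect_lt(abs(one$onset - 20), 0.25)
  expect_gte(one$duration, 0.5)
  short <- detect_spindles(mk(20, 0.3) + noise, fs, threshold = thr)
  expect_equal(nrow(short), 0)
  long <- detect_spindles(mk(20, 4) + noise, fs, threshold = thr)
  expect_equal(nrow(long), 0)
})

test_that("percentile threshold marks ~25% of analysed samples before gating", {
  rp <- subject_recipes(300, seed = 21)
  g <- generate_recording(rp$sw_recipes, rp$spindle_recipes, duration = 300,
                          seed = 21)
  fs <- 200
  x <- g$recording$data[, 2]
  env <- spindle_envelope(fir_bandpass(x, fs, 10, 16), fs)
  thr <- quantile(env, 0.75)
  expect_equal(mean(env > thr), 0.25, tolerance = 0.02)
})

test_that("raising the percentile never increases the spindle count", {
  rp <- subject_recipes(300, seed = 13)
  g <- generate_recording(rp$sw_recipes, rp$spindle_recipes, duration = 300,
                          seed = 13)
  x <- g$recording$data[, 1]
  counts <- vapply(c(60, 75, 90, 97),
                   function(p) nrow(detect_spindles(x, 200, percentile = p)),
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("detected spindles are non-overlapping supra-threshold runs", {
  rp <- subject_recipes(300, seed = 3)
  g <- generate_recording(rp$sw_recipes, rp$spindle_recipes, duration = 300,
                          seed = 3)
  fs <- 200
  x <- g$recording$data[, 1]
  sp <- detect_spindles(x, fs)
  expect_gt(nrow(sp), 5)
  expect_true(all(sp$offset[-nrow(sp)] <= sp$onset[-1] + 1e-9))
  expect_true(all(sp$duration >= 0.5 & sp$duration <= 3))
  expect_true(all(sp$peak_env > sp$threshold_used))
  env <- spindle_envelope(fir_bandpass(x, fs, 10, 16), fs)
  for (k in seq_len(nrow(sp))) {
    run <- env[(round(sp$onset[k] * fs) + 1):(round(sp$offset[k] * fs))]
    expect_true(all(run > sp$threshold_used[k]))
  }
})

test_that("spindle density averages per-minute counts over channels", {
  ev <- data.frame(channel = rep(c("F3", "Fz", "F4"), c(83, 83, 83)))
  expect_equal(spindle_density(ev, 10, channels = c("F3", "Fz", "F4")), 8.3)
  expect_equal(spindle_density(ev[0, , drop = FALSE], 10, channels = "F3"), 0)
  expect_equal(spindle_density(data.frame(channel = rep("F3", 12)), 2), 6)
  expect_error(spindle_density(ev, 0), "positive")
})

test_that("empty segments yield an empty event table", {
  hyp <- hypnogram(rep("R", 4))
  seg <- suppressWarnings(select_analysis_segments(hyp, mask_events(), 200))
  sp <- detect_spindles(rnorm(200 * 120), 200, segments = seg)
  expect_equal(nrow(sp), 0)
})
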