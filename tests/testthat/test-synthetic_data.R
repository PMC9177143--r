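test_that("synthetic slow waves carry exact landmarks and transition frequency", {
  r <- sw_recipe("slow", neg_amp = -45, pos_amp = 45,
                 durations = rep(0.225, 4))
  w <- synth_slow_wave(r, 200)
  expect_equal(unname(w$landmarks),
               c(0, 0.225, 0.45, 0.675, 0.9))
  expect_equal(1 / (2 * (0.225 + 0.225)), 1.111, tolerance = 1e-3)
  fast <- sw_recipe("fast", durations = c(0.2, 0.125, 0.125, 0.2))
  expect_equal(1 / (2 * (fast$durations[2] + fast$durations[3])), 2.0)
  # waveform touches the requested amplitudes at the peak landmarks
  expect_equal(min(w$waveform), -45, tolerance = 0.01)
  expect_equal(max(w$waveform), 45, tolerance = 0.01)
  expect_error(synth_slow_wave(modifyList(r, list(neg_amp = 0)), 200), "flat")
  expect_error(sw_recipe("slow", neg_amp = 45, pos_amp = 45), "sign")
})

test_that("generators are pure functions of their seed", {
  rp <- subject_recipes(120, seed = 3)
  g1 <- generate_recording(rp$sw_recipes, rp$spindle_recipes, 120, seed = 3)
  g2 <- generate_recording(rp$sw_recipes, rp$spindle_recipes, 120, seed = 3)
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(g1$truth, g2$truth)
  c1 <- generate_cohort(cohort_truth(seed = 8))
  c2 <- generate_cohort(cohort_truth(seed = 8))
  expect_identical(c1$subjects, c2$subjects)
})

test_that("phase-targeted spindles invert the phase map exactly", {
  fs <- 200
  sw <- sw_recipe("slow", at = 5)
  phases <- c(0.3, 0.9, 1.25, 1.7) * pi
  sps <- lapply(phases, function(p) spindle_recipe(sw_ref = 1, phase = p,
                                                   duration = 1))
  g <- generate_recording(list(sw), sps, duration = 30, seed = 2)
  sw_row <- g$truth$sw[1, ]
  for (k in seq_along(phases)) {
    realised <- sw_phase_at(sw_row, g$truth$spindles$onset[k])
    step <- diff(range(sw_phase_at(sw_row, sw_row$t_start + c(0, 1 / fs))))
    expect_lt(abs(realised - phases[k]), step + 1e-9)
  }
  # infeasible placement: spindle would end beyond the recording
  expect_error(generate_recording(list(sw_recipe("slow", at = 28)),
                                  list(spindle_recipe(sw_ref = 1, phase = pi,
                                                      duration = 5)),
                                  duration = 30, seed = 1),
               "infeasible")
})

test_that("noise-free injected waves are recovered landmark-exactly", {
  rp <- subject_recipes(180, spindles_per_min = 0, seed = 6)
  g <- generate_recording(rp$sw_recipes, list(), 180,
                          noise = list(rms = 0, alpha = 1), seed = 6)
  fs <- 200
  sw <- detect_slow_waves(g$recording$data[, 1], fs, "female")
  truth <- g$truth$sw
  expect_equal(nrow(sw), nrow(truth))
  for (lm in c("t_start", "t_neg_peak", "t_mid_cross", "t_pos_peak", "t_end")) {
    expect_lt(max(abs(sw[[lm]] - truth[[lm]])), 1 / fs + 1e-9)
  }
  expect_true(all(abs(sw$transition_freq / truth$transition_freq - 1) < 0.02))
})

test_that("event-free noise yields almost no detections at default criteria", {
  fs <- 200
  g <- generate_recording(list(), list(), duration = 600, seed = 99)
  x <- g$recording$data[, 1]
  sw <- detect_slow_waves(fir_bandpass(x, fs, 0.3, 4), fs, "female")
  expect_lte(nrow(sw), 1)
  # spindle check uses an absolute threshold calibrated on a recording with
  # events (a percentile threshold is relative by construction and marks 25%
  # of any input)
  rp <- subject_recipes(600, seed = 98)
  gref <- generate_recording(rp$sw_recipes, rp$spindle_recipes, 600, seed = 98)
  thr <- detect_spindles(gref$recording$data[, 1], fs)$threshold_used[1]
  sp <- detect_spindles(x, fs, threshold = thr)
  expect_lte(nrow(sp), 1)
})

test_that("cohort generator reproduces the designed association structure", {
  co <- generate_cohort(cohort_truth(n_subjects = 400, n_followup = 264,
                                     seed = 21))
  s <- co$subjects
  expect_equal(nrow(co$long), 800)
  expect_true(all(s$age >= 50 & s$age <= 70))
  expect_equal(mean(s$sex == "female"), 0.68, tolerance = 0.08)
  expect_equal(mean(s$tst), 392.8, tolerance = 10)
  expect_true(all(s$centiloid > 0))
  expect_gt(mean(s$centiloid), stats::median(s$centiloid))  # right-skewed
  # the injected slow-type slope is recoverable by regression
  b <- coef(lm(cos_slow ~ centiloid, s))[2]
  expect_lt(abs(unname(b) - (-0.0065)), 0.004)
  # decline is linked to the slow coupling cosine with the designed slope
  fu <- s[!is.na(s$memory_decline), ]
  expect_equal(nrow(fu), 264)
  bd <- coef(lm(memory_decline ~ cos_slow, fu))[2]
  expect_lt(abs(unname(bd) - (-0.45)), 0.15)
  expect_equal(fu$rm_followup, fu$rm_baseline * (1 - fu$memory_decline))
  expect_error(cohort_truth(resid_sd = -1), "resid_sd")
  expect_error(cohort_truth(n_subjects = 5), "n_subjects")
})
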