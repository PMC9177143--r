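sw_fix <- data.frame(channel = "F3", t_start = 10, t_neg_peak = 10.3,
                     t_mid_cross = 10.5, t_pos_peak = 10.8, t_end = 11.1,
                     switcher = "slow", stringsAsFactors = FALSE)

test_that("phase hits the five landmarks exactly and interpolates linearly", {
  lm <- c(10, 10.3, 10.5, 10.8, 11.1)
  expect_identical(sw_phase_at(sw_fix, lm),
                   c(0, pi / 2, pi, 3 * pi / 2, 2 * pi))
  expect_equal(sw_phase_at(sw_fix, 10.15), pi / 4)
  tt <- seq(10, 11.1, by = 0.01)
  expect_true(all(diff(sw_phase_at(sw_fix, tt)) >= 0))
  expect_error(sw_phase_at(sw_fix, 9.9), "outside")
  degenerate <- transform(sw_fix, t_neg_peak = 10)
  expect_error(sw_phase_at(degenerate, 10.5), "degenerate")
})

test_that("spindle onsets inside a slow wave couple once, at the right phase", {
  spin <- data.frame(channel = "F3", onset = c(10.8, 12.5),
                     offset = c(11.8, 13.5), duration = 1,
                     stringsAsFactors = FALSE)
  ev <- match_spindles_to_sw(spin, sw_fix)
  expect_equal(nrow(ev), 1)                 # onset 1 s after the wave: no event
  expect_equal(ev$phase, 3 * pi / 2)        # onset at the positive peak
  expect_equal(ev$cos_phase, cos(3 * pi / 2))
  expect_equal(ev$switcher, "slow")
  expect_true(all(abs(ev$cos_phase - cos(ev$phase)) < 1e-12))
  # cross-channel onsets never couple
  spin_fz <- transform(spin, channel = "Fz")
  expect_equal(nrow(match_spindles_to_sw(spin_fz, sw_fix)), 0)
})

test_that("subject summary averages cosines per channel then across channels", {
  ev <- data.frame(channel = c("F3", "F3"), phase = c(pi / 2, 3 * pi / 2),
                   switcher = "slow", stringsAsFactors = FALSE)
  s <- suppressMessages(
    subject_coupling_summary(ev, list(slow = 10, fast = 5), 20))
  expect_equal(s$mean_cos_phase[s$switcher == "slow"], 0, tolerance = 1e-12)
  expect_true(is.na(s$mean_cos_phase[s$switcher == "fast"]))
  expect_equal(s$coupling_rate_sw[s$switcher == "slow"], 0.2)
  expect_equal(s$coupling_rate_spindle[s$switcher == "slow"], 0.1)
  ev0 <- transform(ev, phase = 0)
  s0 <- suppressMessages(
    subject_coupling_summary(ev0, list(slow = 10, fast = 5), 20))
  expect_equal(s0$mean_cos_phase[s0$switcher == "slow"], 1)
})

test_that("mean cosine of von Mises phases matches the closed-form moment", {
  set.seed(14)
  ph <- rvm(4000, 1.25 * pi, 4)
  ev <- data.frame(channel = "F3", phase = ph, switcher = "slow",
                   stringsAsFactors = FALSE)
  s <- suppressMessages(
    subject_coupling_summary(ev, list(slow = 5000, fast = 0), 5000))
  expected <- cos(1.25 * pi) * besselI(4, 1) / besselI(4, 0)
  expect_equal(s$mean_cos_phase[s$switcher == "slow"], expected,
               tolerance = 0.02)
})

test_that("coupled-spindle counts are conserved across switcher types", {
  rp <- subject_recipes(300, seed = 17)
  g <- generate_recording(rp$sw_recipes, rp$spindle_recipes, duration = 300,
                          seed = 17)
  res <- suppressMessages(run_subject(g$recording, g$hypnogram,
                                      sex = "female"))
  m <- structure(list(threshold = 1.45), class = "switcher_model")
  sw <- classify_switchers(res$sw_events, m)
  ev <- do.call(rbind, lapply(c("F3", "Fz", "F4"), function(ch) {
    match_spindles_to_sw(
      res$spindle_events[res$spindle_events$channel == ch, ],
      sw[sw$channel == ch, ])
  }))
  expect_equal(sum(ev$switcher == "slow") + sum(ev$switcher == "fast"),
               nrow(ev))
  expect_true(all(ev$phase >= 0 & ev$phase <= 2 * pi))
  expect_true(all(abs(ev$cos_phase - cos(ev$phase)) < 1e-12))
  bk <- coupling_bookkeeping(
    list(slow = sum(sw$switcher == "slow"), fast = sum(sw$switcher == "fast")),
    list(slow = sum(ev$switcher == "slow"), fast = sum(ev$switcher == "fast")),
    nrow(res$spindle_events))
  expect_equal(bk$total_coupled, nrow(ev))
})
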