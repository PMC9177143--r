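test_that("FIR band-pass preserves the passband and kills out-of-band content", {
  fs <- 200
  t <- seq(0, 30, by = 1 / fs)
  mid <- 2000:4000
  y1 <- fir_bandpass(sin(2 * pi * 1 * t), fs, 0.3, 4)
  expect_equal(sd(y1[mid]), sd(sin(2 * pi * 1 * t)[mid]), tolerance = 0.05)
  y20 <- fir_bandpass(sin(2 * pi * 20 * t), fs, 0.3, 4)
  atten_db <- 20 * log10(sd(y20[mid]) / sd(sin(2 * pi * 20 * t)[mid]))
  expect_lt(atten_db, -20)
  ydc <- fir_bandpass(rep(5, 6001), fs, 0.3, 4)
  expect_lt(max(abs(ydc[mid])), 0.05)
  expect_error(fir_bandpass(rnorm(100), fs, 4, 0.3), "band")
  expect_error(fir_bandpass(rnorm(100), fs, 10, 150), "band")
})

test_that("slow waves meeting all criteria are detected with exact landmarks", {
  fs <- 200
  # negative and positive halves of 400 ms each, peaks -45/+45 uV
  r <- sw_recipe("slow", at = 2, neg_amp = -45, pos_amp = 45,
                 durations = rep(0.2, 4))
  sig <- clean_sw_signal(list(r), 10, fs)
  sw <- detect_slow_waves(sig, fs, "female")
  expect_equal(nrow(sw), 1)
  truth <- cumsum(c(2, r$durations))
  got <- as.numeric(sw[1, c("t_start", "t_neg_peak", "t_mid_cross",
                            "t_pos_peak", "t_end")])
  expect_true(all(abs(got - truth) <= 1 / fs + 1e-9))
  expect_equal(sw$p2p, sw$pos_amp - sw$neg_amp)
  expect_equal(sw$frequency, 1 / sw$duration, tolerance = 1e-9)
})

test_that("sub-criterion candidates are rejected, super-criterion kept", {
  fs <- 200
  # p2p 65 uV < 70 uV female threshold
  low <- sw_recipe("slow", at = 2, neg_amp = -38, pos_amp = 27)
  expect_equal(nrow(detect_slow_waves(clean_sw_signal(list(low), 8, fs),
                                      fs, "female")), 0)
  # same wave passes the male criteria (p2p >= 60.5, neg <= -32)
  expect_equal(nrow(detect_slow_waves(clean_sw_signal(list(low), 8, fs),
                                      fs, "male")), 1)
  # 100 ms negative half-wave is outside 125-1500 ms
  short <- sw_recipe("slow", at = 2, neg_amp = -50, pos_amp = 50,
                     durations = c(0.05, 0.05, 0.3, 0.3))
  expect_equal(nrow(detect_slow_waves(clean_sw_signal(list(short), 8, fs),
                                      fs, "female")), 0)
  # positive deflection above 1000 ms is rejected
  long_pos <- sw_recipe("slow", at = 2, neg_amp = -50, pos_amp = 50,
                        durations = c(0.3, 0.3, 0.6, 0.6))
  expect_equal(nrow(detect_slow_waves(clean_sw_signal(list(long_pos), 8, fs),
                                      fs, "female")), 0)
  # p2p at 95% of threshold never detected; at 105% always (noise-free)
  at95 <- sw_recipe("slow", at = 2, neg_amp = -0.95 * 37.5,
                    pos_amp = -0.95 * 37.5 + 0.95 * 70)
  expect_equal(nrow(detect_slow_waves(clean_sw_signal(list(at95), 8, fs),
                                      fs, "female")), 0)
  at105 <- sw_recipe("slow", at = 2, neg_amp = -39, pos_amp = -39 + 1.05 * 70)
  expect_equal(nrow(detect_slow_waves(clean_sw_signal(list(at105), 8, fs),
                                      fs, "female")), 1)
})

test_that("transition frequency uses the half-cycle convention", {
  expect_equal(transition_frequency(list(t_neg_peak = 0.30, t_pos_peak = 0.75)),
               1 / 0.9, tolerance = 1e-9)
  expect_equal(transition_frequency(list(t_neg_peak = 0.30, t_pos_peak = 0.55)),
               2.0, tolerance = 1e-9)
  # a symmetric wave of total duration 0.906 s (cohort slow-switcher mean)
  # has transition frequency ~1.1 Hz, consistent with the cohort table
  expect_equal(transition_frequency(list(t_neg_peak = 0.906 / 4,
                                         t_pos_peak = 3 * 0.906 / 4)),
               1.1, tolerance = 0.01)
  expect_error(transition_frequency(list(t_neg_peak = 1, t_pos_peak = 1)),
               "non-positive")
})

test_that("switcher model recovers the analytic density intersection", {
  set.seed(31)
  x <- c(rnorm(2500, 1.1, 0.05), rnorm(2500, 2.0, 0.1))
  m <- fit_switcher_model(x)
  truth <- numeric_intersection(c(1.1, 2.0), c(0.05, 0.1), c(0.5, 0.5))
  expect_lt(abs(m$threshold - truth), 0.05)
  expect_true(m$threshold > m$means[1] && m$threshold < m$means[2])
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
  # independent cross-check of the mixture fit itself
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(m$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("switcher model converges to the intersection as n grows", {
  set.seed(77)
  x <- c(rnorm(14000, 1.1, 0.05), rnorm(6000, 2.0, 0.1))
  m <- fit_switcher_model(x)
  truth <- numeric_intersection(c(1.1, 2.0), c(0.05, 0.1), c(0.7, 0.3))
  expect_lt(abs(m$threshold - truth), 0.02)
})

test_that("switcher classification is a clean threshold split", {
  m <- structure(list(threshold = 1.2,
                      means = c(1.1, 2), sds = c(0.05, 0.1),
                      weights = c(0.7, 0.3)), class = "switcher_model")
  ev <- data.frame(transition_freq = c(1.1, 2.0, 1.2), channel = "F3",
                   switcher = "unassigned")
  out <- classify_switchers(ev, m)
  expect_equal(out$switcher, c("slow", "fast", "fast"))  # tie goes to fast
  expect_identical(classify_switchers(out, m), out)      # idempotent
  # conservation under random inputs
  set.seed(4)
  ev2 <- data.frame(transition_freq = runif(200, 0.8, 2.5), channel = "F3",
                    switcher = "unassigned")
  out2 <- classify_switchers(ev2, m)
  expect_equal(sum(out2$switcher == "slow") + sum(out2$switcher == "fast"),
               nrow(ev2))
  expect_error(fit_switcher_model(rnorm(20, 1.1, 0.05)), "50")
})

test_that("slow-wave density is count per minute averaged over channels", {
  ev <- data.frame(channel = rep("F3", 70), switcher = rep("slow", 70))
  expect_equal(sw_density(ev, 10)$total, 7)
  expect_equal(sw_density(ev[0, ], 10, channels = "F3")$total, 0)
  ev2 <- data.frame(channel = "F3",
                    switcher = c(rep("slow", 10), rep("fast", 5)))
  d <- sw_density(ev2, 5)
  expect_equal(d$slow, 2); expect_equal(d$fast, 1); expect_equal(d$total, 3)
  expect_error(sw_density(ev, 0), "positive")
})

test_that("detected events never overlap and keep landmark order under noise", {
  rp <- subject_recipes(240, seed = 5)
  g <- generate_recording(rp$sw_recipes, rp$spindle_recipes, duration = 240,
                          seed = 5)
  filt <- fir_bandpass(g$recording$data[, 1], 200, 0.3, 4)
  sw <- detect_slow_waves(filt, 200, "female")
  expect_gt(nrow(sw), 10)
  expect_true(all(diff(sw$t_start) > 0))
  expect_true(all(sw$t_end[-nrow(sw)] <= sw$t_start[-1] + 1e-9))
  with(sw, expect_true(all(t_start < t_neg_peak & t_neg_peak < t_mid_cross &
                           t_mid_cross < t_pos_peak & t_pos_peak < t_end)))
  expect_true(all(sw$neg_amp <= -37 & sw$p2p >= 70))
})
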