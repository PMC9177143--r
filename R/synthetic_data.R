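#' Slow-wave recipe
#'
#' Waveform geometry for one injected slow wave. Segment durations are the
#' four inter-landmark intervals (start to negative peak, negative peak to
#' mid zero crossing, mid crossing to positive peak, positive peak to end),
#' so the implied transition frequency is
#' `1 / (2 * (durations[2] + durations[3]))`.
#'
#' Defaults reproduce the cohort's mean waveforms: a slow switcher of total
#' duration 906 ms (transition ~1.1 Hz) with 104 uV peak-to-peak, or a fast
#' switcher of 670 ms (down-to-up half-cycle 250 ms, transition 2.0 Hz) with
#' 94 uV peak-to-peak.
#'
#' @param class `"slow"` or `"fast"`, selecting default geometry.
#' @param at placement time of the wave's start (ignition), seconds.
#' @param neg_amp negative-peak amplitude, uV (< 0).
#' @param pos_amp positive-peak amplitude, uV (> 0).
#' @param durations the four segment durations, seconds.
#' @param channel channel label, or NULL to inject on every channel.
#' @return list recipe for [generate_recording()].
#' @export
sw_recipe <- function(class = c("slow", "fast"), at = 0, neg_amp = NULL,
                      pos_amp = NULL, durations = NULL, channel = NULL) {
  class <- match.arg(class)
  if (is.null(durations))
    durations <- if (class == "slow") rep(0.2265, 4)
                 else c(0.21, 0.125, 0.125, 0.21)
  if (is.null(neg_amp)) neg_amp <- if (class == "slow") -52 else -47
  if (is.null(pos_amp)) pos_amp <- if (class == "slow") 52 else 47
  if (!(neg_amp < 0 && pos_amp > 0))
    stop("amplitude signs wrong: neg_amp must be < 0 and pos_amp > 0")
  stopifnot(all(durations > 0))
  list(class = class, at = at, neg_amp = neg_amp, pos_amp = pos_amp,
       durations = durations, channel = channel)
}

#' Spindle recipe
#'
#' @param freq carrier frequency, Hz (10-16).
#' @param duration burst duration, seconds (0.5-3 to be detectable).
#' @param amplitude peak carrier amplitude, uV.
#' @param at absolute onset time, seconds (ignored when phase-targeted).
#' @param sw_ref index of a slow-wave recipe to couple to, or NA.
#' @param phase requested onset phase on that slow wave, radians `[0, 2*pi]`.
#' @param channel channel label, or NULL for every channel.
#' @return list recipe for [generate_recording()].
#' @export
spindle_recipe <- function(freq = 13, duration = 1, amplitude = 25,
                           at = NA, sw_ref = NA, phase = NA,
                           channel = NULL) {
  stopifnot(freq >= 10, freq <= 16, duration > 0)
  if (is.na(at) && (is.na(sw_ref) || is.na(phase)))
    stop("spindle needs either an absolute time or (sw_ref, phase)")
  list(freq = freq, duration = duration, amplitude = amplitude, at = at,
       sw_ref = sw_ref, phase = phase, channel = channel)
}

#' Synthesise one slow-wave waveform with exact landmarks
#'
#' Piecewise quarter-cosine segments through the five landmarks (zero at
#' ignition, negative peak, zero at mid crossing, positive peak, zero at
#' termination). The slope is maximal at the zero crossings and zero at the
#' peaks, so landmark ground truth is exact by construction.
#'
#' @param recipe a [sw_recipe()].
#' @param fs sampling rate, Hz (>= 100).
#' @return list with `waveform` (uV, sampled at `fs` from the wave start)
#'   and `landmarks` (named vector of the five landmark times, seconds,
#'   relative to the wave start).
#' @export
synth_slow_wave <- function(recipe, fs) {
  stopifnot(fs >= 100)
  d <- recipe$durations
  if (recipe$neg_amp == 0 || recipe$pos_amp == 0)
    stop("zero amplitudes produce a flat, undetectable wave")
  if (!(recipe$neg_amp < 0 && recipe$pos_amp > 0))
    stop("amplitude signs wrong")
  lm <- cumsum(c(0, d))
  names(lm) <- c("t_start", "t_neg_peak", "t_mid_cross", "t_pos_peak",
                 "t_end")
  t <- seq(0, lm[5], by = 1 / fs)
  y <- numeric(length(t))
  s1 <- t < lm[2]
  y[s1] <- recipe$neg_amp * sin(pi / 2 * t[s1] / d[1])
  s2 <- t >= lm[2] & t < lm[3]
  y[s2] <- recipe$neg_amp * cos(pi / 2 * (t[s2] - lm[2]) / d[2])
  s3 <- t >= lm[3] & t < lm[4]
  y[s3] <- recipe$pos_amp * sin(pi / 2 * (t[s3] - lm[3]) / d[3])
  s4 <- t >= lm[4]
  y[s4] <- recipe$pos_amp * cos(pi / 2 * pmin((t[s4] - lm[4]) / d[4], 1))
  list(waveform = y, landmarks = lm)
}

#' 1/f^alpha (pink) background noise
#'
#' Gaussian noise spectrally shaped to a power-law spectrum by FFT filtering,
#' rescaled to the requested RMS. Pure function of the seed.
#'
#' @param n number of samples.
#' @param rms target root-mean-square amplitude, uV.
#' @param alpha spectral exponent (1 = pink).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, rms = 15, alpha = 1, seed = 1) {
  withr::with_seed(seed, {
    w <- stats::rnorm(n)
    X <- stats::fft(w)
    f <- c(1, seq_len(n - 1))
    f <- pmin(f, n - f + 1)          # symmetric frequency index
    X <- X / f^(alpha / 2)
    X[1] <- 0
    x <- Re(stats::fft(X, inverse = TRUE) / n)
    x * rms / stats::sd(x)
  })
}

#' Generate a ground-truthed synthetic sleep-EEG recording
#'
#' Injects slow waves and spindles into 1/f background noise on the frontal
#' channels, with spindles optionally placed at a requested phase of a
#' referenced slow wave (the phase convention of [sw_phase_at()] is inverted
#' exactly). Returns the recording, a hypnogram, and the complete ground
#' truth needed to score any detector.
#'
#' @param sw_recipes list of [sw_recipe()]s; `at` times must leave waves
#'   inside the recording and non-overlapping per channel.
#' @param spindle_recipes list of [spindle_recipe()]s.
#' @param duration recording duration, seconds (multiple of 30 recommended).
#' @param fs sampling rate, Hz (default 200).
#' @param noise list with `rms` (uV) and `alpha`; `rms = 0` gives a
#'   noise-free recording.
#' @param channels channel labels (default F3, Fz, F4).
#' @param hypnogram_stages stage labels for the 30-s epochs; default all N2.
#' @param seed integer seed; the generator is a pure function of it.
#' @return list with `recording` ([eeg_recording()]), `hypnogram`
#'   ([hypnogram()]), and `truth` (list: `sw` data.frame of injected
#'   slow-wave landmarks/amplitudes/classes, `spindles` data.frame with
#'   realised onsets and phases, `noise`, `seed`).
#' @export
generate_recording <- function(sw_recipes = list(), spindle_recipes = list(),
                               duration, fs = 200,
                               noise = list(rms = 15, alpha = 1),
                               channels = c("F3", "Fz", "F4"),
                               hypnogram_stages = NULL, seed = 1) {
  n <- round(duration * fs)
  n_ep <- ceiling(duration / 30)
  if (is.null(hypnogram_stages)) hypnogram_stages <- rep("N2", n_ep)
  hyp <- hypnogram(hypnogram_stages)

  # snap placements to the sample grid so truth landmarks are exact on it
  sw_recipes <- lapply(sw_recipes, function(r) {
    r$at <- round(r$at * fs) / fs
    r
  })
  sw_truth <- lapply(seq_along(sw_recipes), function(i) {
    r <- sw_recipes[[i]]
    lm <- cumsum(c(0, r$durations)) + r$at
    data.frame(sw_id = i, channel = if (is.null(r$channel)) "all" else r$channel,
               t_start = lm[1], t_neg_peak = lm[2], t_mid_cross = lm[3],
               t_pos_peak = lm[4], t_end = lm[5],
               neg_amp = r$neg_amp, pos_amp = r$pos_amp,
               transition_freq = 1 / (2 * (r$durations[2] + r$durations[3])),
               class = r$class, stringsAsFactors = FALSE)
  })
  sw_truth <- if (length(sw_truth)) do.call(rbind, sw_truth) else NULL
  if (!is.null(sw_truth)) {
    if (any(sw_truth$t_end > duration) || any(sw_truth$t_start < 0))
      stop("slow-wave placement outside the recording")
    o <- order(sw_truth$t_start)
    if (any(sw_truth$t_start[o][-1] < sw_truth$t_end[o][-nrow(sw_truth)]))
      stop("injected slow waves overlap")
    ep_idx <- floor(sw_truth$t_start / 30) + 1
    if (any(!hypnogram_stages[ep_idx] %in% c("N2", "N3")))
      stop("slow waves must fall in N2/N3 epochs")
  }

  sp_truth <- lapply(seq_along(spindle_recipes), function(i) {
    r <- spindle_recipes[[i]]
    if (!is.na(r$sw_ref)) {
      if (is.null(sw_truth) || r$sw_ref > nrow(sw_truth))
        stop("spindle references a non-existent slow wave")
      onset <- sw_time_at_phase(sw_truth[r$sw_ref, ], r$phase)
    } else {
      onset <- r$at
    }
    if (onset < 0 || onset + r$duration > duration)
      stop("infeasible spindle placement at ", round(onset, 3), " s")
    onset <- round(onset * fs) / fs   # snap to the sample grid
    data.frame(spindle_id = i,
               channel = if (is.null(r$channel)) "all" else r$channel,
               onset = onset, offset = onset + r$duration,
               duration = r$duration, freq = r$freq,
               amplitude = r$amplitude,
               phase = if (!is.na(r$sw_ref)) r$phase else NA_real_,
               sw_ref = r$sw_ref, stringsAsFactors = FALSE)
  })
  sp_truth <- if (length(sp_truth)) do.call(rbind, sp_truth) else NULL

  tgrid <- (seq_len(n) - 1) / fs
  clean <- numeric(n)
  if (!is.null(sw_truth)) {
    for (i in seq_len(nrow(sw_truth))) {
      w <- synth_slow_wave(sw_recipes[[i]], fs)
      i0 <- round(sw_truth$t_start[i] * fs) + 1
      idx <- i0:(i0 + length(w$waveform) - 1)
      keep <- idx <= n
      clean[idx[keep]] <- clean[idx[keep]] + w$waveform[keep]
    }
  }
  if (!is.null(sp_truth)) {
    for (i in seq_len(nrow(sp_truth))) {
      r <- spindle_recipes[[i]]
      i0 <- round(sp_truth$onset[i] * fs) + 1
      len <- round(r$duration * fs)
      idx <- i0:(i0 + len - 1)
      u <- seq(0, 1, length.out = len)
      # Tukey (tapered-cosine) envelope: waxing-waning plateau with a fast
      # onset, so the envelope threshold crossing stays near the true onset
      alpha <- 0.1
      env <- rep(1, len)
      ramp <- u < alpha / 2
      env[ramp] <- 0.5 * (1 - cos(2 * pi * u[ramp] / alpha))
      fall <- u > 1 - alpha / 2
      env[fall] <- 0.5 * (1 - cos(2 * pi * (1 - u[fall]) / alpha))
      burst <- r$amplitude * env * sin(2 * pi * r$freq * (u * r$duration))
      keep <- idx <= n & idx >= 1
      clean[idx[keep]] <- clean[idx[keep]] + burst[keep]
    }
  }

  data <- matrix(0, n, length(channels))
  for (ch in seq_along(channels)) {
    bg <- if (noise$rms > 0)
      pink_noise(n, rms = noise$rms, alpha = noise$alpha,
                 seed = seed * 1000L + ch) else numeric(n)
    data[, ch] <- clean + bg
  }
  rec <- eeg_recording(data, fs, channels, "synthetic, average reference")
  list(recording = rec, hypnogram = hyp,
       truth = list(sw = sw_truth, spindles = sp_truth, noise = noise,
                    seed = seed))
}

#' Build recipes for a realistic synthetic subject night
#'
#' Places slow waves at jittered regular times matching cohort densities
#' (about 5 slow and 2 fast switchers per minute), injects spindles at a
#' realistic density (about 8/minute), couples a fraction of them to slow
#' waves at von Mises-distributed phases, and returns recipe lists for
#' [generate_recording()].
#'
#' @param duration recording duration, seconds.
#' @param sw_per_min total slow-wave rate (slow + fast switchers), per
#'   minute.
#' @param p_slow proportion of slow switchers.
#' @param spindles_per_min spindle rate, per minute.
#' @param coupled_fraction fraction of spindles coupled to a slow-switcher
#'   wave.
#' @param phase_mu,phase_kappa von Mises parameters of the coupled onset
#'   phase on slow switchers (default: late depolarisation, mu = 1.25*pi,
#'   kappa = 4).
#' @param coupled_fraction_fast fraction of spindles coupled to a
#'   fast-switcher wave, with a more diffuse phase preference.
#' @param phase_mu_fast,phase_kappa_fast von Mises parameters of the onset
#'   phase on fast switchers (diffuse: kappa = 0.8).
#' @param seed integer seed.
#' @return list with `sw_recipes` and `spindle_recipes`.
#' @export
subject_recipes <- function(duration, sw_per_min = 7, p_slow = 0.7,
                            spindles_per_min = 8,
                            coupled_fraction = 0.25,
                            phase_mu = 1.25 * pi, phase_kappa = 4,
                            coupled_fraction_fast = 0.08,
                            phase_mu_fast = pi, phase_kappa_fast = 0.8,
                            seed = 1) {
  withr::with_seed(seed, {
    n_sw <- round(sw_per_min * duration / 60)
    slots <- seq(1.5, duration - 2.5, length.out = n_sw)
    slots <- slots + stats::runif(n_sw, -0.2, 0.2)
    classes <- sample(c("slow", "fast"), n_sw, replace = TRUE,
                      prob = c(p_slow, 1 - p_slow))
    sw_recipes <- lapply(seq_len(n_sw), function(i) {
      jit <- stats::rnorm(1, 0, 0.015)
      amp <- stats::runif(1, 0.9, 1.2)
      base <- sw_recipe(classes[i], at = slots[i])
      base$durations <- pmax(base$durations + jit, 0.08)
      base$neg_amp <- base$neg_amp * amp
      base$pos_amp <- base$pos_amp * amp
      base
    })
    n_sp <- round(spindles_per_min * duration / 60)
    n_coupled <- round(coupled_fraction * n_sp)
    slow_idx <- which(classes == "slow" & slots < duration - 4)
    targets <- sample(slow_idx, min(n_coupled, length(slow_idx)))
    coupled <- lapply(targets, function(j) {
      ph <- (phase_mu + rvonmises_one(phase_kappa)) %% (2 * pi)
      ph <- min(max(ph, 0.05), 2 * pi - 0.6)  # keep onset inside the wave
      spindle_recipe(sw_ref = j, phase = ph,
                     duration = stats::runif(1, 1.3, 2.3),
                     freq = stats::runif(1, 12, 14))
    })
    n_coupled_fast <- round(coupled_fraction_fast * n_sp)
    fast_idx <- which(classes == "fast" & slots < duration - 4)
    targets_fast <- sample(fast_idx, min(n_coupled_fast, length(fast_idx)))
    coupled_fast <- lapply(targets_fast, function(j) {
      ph <- (phase_mu_fast + rvonmises_one(phase_kappa_fast)) %% (2 * pi)
      ph <- min(max(ph, 0.05), 2 * pi - 0.9)
      spindle_recipe(sw_ref = j, phase = ph,
                     duration = stats::runif(1, 1.3, 2.3),
                     freq = stats::runif(1, 12, 14))
    })
    coupled <- c(coupled, coupled_fast)
    # uncoupled spindles go into the inter-wave gaps, up to two per gap,
    # spaced so bursts never overlap or merge into over-long envelope runs
    n_free <- n_sp - length(coupled)
    pool <- c(slots[setdiff(which(slots < duration - 4.5),
                            c(targets, targets_fast))] + 1.3,
              slots[slots < duration - 7.5] + 4.3)
    free_at <- sample(pool, min(n_free, length(pool))) +
      stats::runif(min(n_free, length(pool)), 0, 0.3)
    free <- lapply(free_at, function(a) {
      spindle_recipe(at = a, duration = stats::runif(1, 1.3, 2.3),
                     freq = stats::runif(1, 12, 14))
    })
    list(sw_recipes = sw_recipes, spindle_recipes = c(coupled, free))
  })
}

# one von Mises(0, kappa) draw via Best-Fisher rejection
rvonmises_one <- function(kappa) {
  if (kappa < 1e-8) return(stats::runif(1, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0)
      return(sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1)))
  }
}

#' Cohort simulation truth parameters
#'
#' Defaults emulate the study design: 100 subjects aged 50-70 (68% women),
#' TST ~ N(392.8, 45.9^2) minutes, education ~ N(15.2, 3^2) years, a
#' right-skewed (lognormal) Centiloid distribution, mean coupling cosine
#' generated per switcher type as a linear function of Centiloid plus a
#' subject random intercept and residual noise, and 2-year memory decline
#' generated from the slow-switcher coupling cosine in the 66-subject
#' follow-up subset. The default slow-type slope corresponds to a partial
#' correlation near 0.26 at n = 100 (semi-partial R2 about 0.07, the
#' scale of association the design targets); the fast-type slope is zero.
#'
#' @param n_subjects baseline sample size.
#' @param n_followup follow-up subsample size.
#' @param slope_slow,slope_fast cosine-on-Centiloid slopes per type.
#' @param intercept_slow,intercept_fast per-type mean cosine at Centiloid 0.
#' @param subject_sd SD of the per-subject random intercept.
#' @param resid_sd residual SD of the per-type cosine.
#' @param decline_slope slope of memory decline on the (centred)
#'   slow-switcher coupling cosine.
#' @param decline_mean,decline_sd mean and residual SD of memory decline.
#' @param centiloid_meanlog,centiloid_sdlog lognormal Centiloid parameters.
#' @param seed integer seed.
#' @return list of class `cohort_truth`.
#' @export
cohort_truth <- function(n_subjects = 100, n_followup = 66,
                         slope_slow = -0.0065, slope_fast = 0,
                         intercept_slow = -0.45, intercept_fast = -0.05,
                         subject_sd = 0.09, resid_sd = 0.12,
                         decline_slope = -0.45, decline_mean = 0.07,
                         decline_sd = 0.25,
                         centiloid_meanlog = log(10), centiloid_sdlog = 0.5,
                         seed = 1) {
  stopifnot(n_subjects >= 10, n_followup <= n_subjects, subject_sd >= 0,
            resid_sd > 0, decline_sd > 0)
  structure(as.list(environment()), class = "cohort_truth")
}

#' Generate a synthetic cohort table
#'
#' Draws subject covariates and per-type coupling cosines from the
#' generative model described in [cohort_truth()]. Reproduces exactly under
#' the same seed.
#'
#' @param truth a [cohort_truth()].
#' @return list with `subjects` (one row per subject: demographics,
#'   Centiloid, RM scores, memory decline), `long` (one row per subject x
#'   switcher type, ready for [fit_primary_model()]), and `truth`.
#' @export
generate_cohort <- function(truth = cohort_truth()) {
  stopifnot(inherits(truth, "cohort_truth"))
  withr::with_seed(truth$seed, {
    n <- truth$n_subjects
    subj <- data.frame(
      subject_id = sprintf("s%03d", seq_len(n)),
      age = round(stats::runif(n, 50, 70), 1),
      sex = sample(c("female", "male"), n, replace = TRUE,
                   prob = c(0.68, 0.32)),
      education = pmax(round(stats::rnorm(n, 15.2, 3.0)), 6),
      tst = round(pmin(pmax(stats::rnorm(n, 392.8, 45.9), 220), 510), 1),
      centiloid = round(stats::rlnorm(n, truth$centiloid_meanlog,
                                      truth$centiloid_sdlog), 2),
      stringsAsFactors = FALSE)
    b_subj <- stats::rnorm(n, 0, truth$subject_sd)
    cos_slow <- truth$intercept_slow + truth$slope_slow * subj$centiloid +
      b_subj + stats::rnorm(n, 0, truth$resid_sd)
    cos_fast <- truth$intercept_fast + truth$slope_fast * subj$centiloid +
      b_subj + stats::rnorm(n, 0, truth$resid_sd)
    subj$cos_slow <- pmin(pmax(cos_slow, -1), 1)
    subj$cos_fast <- pmin(pmax(cos_fast, -1), 1)
    subj$sw_duration_slow <- stats::rnorm(n, 0.906, 0.046)
    subj$sw_duration_fast <- stats::rnorm(n, 0.671, 0.046)

    subj$rm_baseline <- pmin(pmax(stats::rnorm(n, 0.5, 0.15), 0.05), 1)
    fu <- sort(sample(seq_len(n), truth$n_followup))
    decline <- truth$decline_mean +
      truth$decline_slope * (subj$cos_slow - mean(subj$cos_slow)) +
      stats::rnorm(n, 0, truth$decline_sd)
    subj$memory_decline <- NA_real_
    subj$memory_decline[fu] <- decline[fu]
    subj$rm_followup <- NA_real_
    subj$rm_followup[fu] <- subj$rm_baseline[fu] * (1 - decline[fu])

    long <- rbind(
      data.frame(subject_id = subj$subject_id, switcher = "slow",
                 mean_cos_phase = subj$cos_slow,
                 sw_duration = subj$sw_duration_slow,
                 subj[, c("age", "sex", "tst", "education", "centiloid")],
                 stringsAsFactors = FALSE),
      data.frame(subject_id = subj$subject_id, switcher = "fast",
                 mean_cos_phase = subj$cos_fast,
                 sw_duration = subj$sw_duration_fast,
                 subj[, c("age", "sex", "tst", "education", "centiloid")],
                 stringsAsFactors = FALSE))
    list(subjects = subj, long = long, truth = truth)
  })
}
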