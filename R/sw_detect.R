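#' Sex-adapted slow-wave detection criteria
#'
#' Amplitude criteria follow the age-adapted convention for older adults:
#' peak-to-peak >= 70 uV and negative peak <= -37 uV for women, >= 60.5 uV
#' and <= -32 uV for men (relaxed from the standard 75 / -40 uV). The
#' negative deflection must last 125-1500 ms and the positive deflection at
#' most 1000 ms.
#'
#' @param sex `"female"` or `"male"`.
#' @param p2p_min,neg_amp_max override the amplitude criteria (uV).
#' @param neg_dur_range allowed negative half-wave duration, seconds.
#' @param pos_dur_max maximum positive half-wave duration, seconds.
#' @return list of detection criteria.
#' @export
sw_criteria <- function(sex = c("female", "male"), p2p_min = NULL,
                        neg_amp_max = NULL, neg_dur_range = c(0.125, 1.5),
                        pos_dur_max = 1.0) {
  sex <- match.arg(sex)
  if (is.null(p2p_min)) p2p_min <- if (sex == "female") 70 else 60.5
  if (is.null(neg_amp_max)) neg_amp_max <- if (sex == "female") -37 else -32
  stopifnot(p2p_min > 0, neg_amp_max < 0)
  list(sex = sex, p2p_min = p2p_min, neg_amp_max = neg_amp_max,
       neg_dur_range = neg_dur_range, pos_dur_max = pos_dur_max)
}

# merge adjacent half-open intervals into contiguous blocks
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  out <- intervals[1, , drop = FALSE]
  for (i in seq_len(nrow(intervals))[-1]) {
    if (intervals$start[i] <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], intervals$end[i])
    } else {
      out <- rbind(out, intervals[i, ])
    }
  }
  out
}

# Zero crossings of x with plateau handling. A crossing between two
# consecutive non-zero samples of opposite sign is linearly interpolated; a
# run of exact zeros separating opposite signs yields a `reach` position
# (where the signal first attains zero) and a `leave` position (where it
# departs), so that a wave ending on a silent plateau ends where it reaches
# zero and the next wave starts where the signal leaves zero. Positions are
# fractional 0-based sample indices.
find_crossings <- function(x) {
  s <- sign(x)
  nz <- which(s != 0)
  if (length(nz) < 2)
    return(data.frame(dir = character(), reach = numeric(),
                      leave = numeric()))
  ch <- which(s[nz[-length(nz)]] * s[nz[-1]] < 0)
  if (length(ch) == 0)
    return(data.frame(dir = character(), reach = numeric(),
                      leave = numeric()))
  i <- nz[ch]
  j <- nz[ch + 1]
  adjacent <- j == i + 1
  p <- (i - 1) + x[i] / (x[i] - x[j])          # interpolated, adjacent case
  out <- data.frame(dir = ifelse(s[i] > 0, "down", "up"),
                    reach = ifelse(adjacent, p, i),     # first zero of plateau
                    leave = ifelse(adjacent, p, j - 2), # last zero of plateau
                    stringsAsFactors = FALSE)
  # a leading/trailing silent plateau acts as a crossing into/out of the wave
  first <- nz[1]
  if (first > 1)
    out <- rbind(data.frame(dir = if (s[first] < 0) "down" else "up",
                            reach = first - 2, leave = first - 2), out)
  last <- nz[length(nz)]
  if (last < length(x))
    out <- rbind(out, data.frame(dir = if (s[last] > 0) "down" else "up",
                                 reach = last, leave = last))
  out
}

# Remove crossing pairs delimiting half-waves shorter than min_gap samples:
# in a 0.3-4 Hz signal a half-wave of a few tens of milliseconds is a noise
# wiggle around zero, not the edge of a slow wave, and dropping the pair
# restores the enclosing wave's structure. Iterates until stable.
merge_wiggles <- function(cr, min_gap) {
  repeat {
    if (nrow(cr) < 2) return(cr)
    gaps <- cr$reach[-1] - cr$leave[-nrow(cr)]
    k <- which(gaps < min_gap)
    k <- k[cr$dir[k] != cr$dir[k + 1]]
    if (length(k) == 0) return(cr)
    drop <- unique(c(k[1], k[1] + 1))
    cr <- cr[-drop, , drop = FALSE]
  }
}

#' Detect slow waves on a band-filtered signal
#'
#' Candidate waves are consecutive negative-then-positive half-waves
#' delimited by zero crossings of the 0.3-4 Hz filtered signal: the wave
#' starts at a down-going zero crossing, crosses zero upward after the
#' negative (down-state) peak, and ends at the next down-going crossing after
#' the positive (up-state) peak. A candidate is kept iff it meets all four
#' amplitude/duration criteria of [sw_criteria()]. Crossing times are
#' linearly interpolated between samples.
#'
#' @param filtered signal already filtered 0.3-4 Hz (see [fir_bandpass()];
#'   raw input is not a detectable contract).
#' @param fs sampling rate, Hz.
#' @param sex `"female"` or `"male"`, selecting amplitude criteria.
#' @param segments an `analysis_segments` object (or NULL to scan the whole
#'   signal); detection runs within each contiguous block of selected epochs.
#' @param channel label stored with the events.
#' @param criteria detection criteria; defaults to [sw_criteria] for `sex`.
#' @param min_halfwave_s crossing pairs delimiting half-waves shorter than
#'   this (seconds) are treated as noise wiggles around zero and merged;
#'   default 0.1, below the 0.125 s minimum negative deflection.
#' @return data.frame of slow-wave events with landmark times `t_start`,
#'   `t_neg_peak`, `t_mid_cross`, `t_pos_peak`, `t_end` (seconds from
#'   recording start), amplitudes `neg_amp` (<= 0), `pos_amp` (>= 0), `p2p`,
#'   `duration`, `frequency` (= 1/duration), `transition_freq`
#'   (= 1/(2 (t_pos_peak - t_neg_peak))) and `switcher` (initially
#'   `"unassigned"`).
#' @export
detect_slow_waves <- function(filtered, fs, sex = c("female", "male"),
                              segments = NULL, channel = "F3",
                              criteria = NULL, min_halfwave_s = 0.1) {
  sex <- match.arg(sex)
  if (is.null(criteria)) criteria <- sw_criteria(sex)
  if (is.null(segments)) {
    blocks <- data.frame(start = 1L, end = length(filtered) + 1L)
  } else {
    blocks <- merge_intervals(segments$intervals)
  }
  rows <- list()
  for (bi in seq_len(nrow(blocks))) {
    i0 <- blocks$start[bi]
    i1 <- blocks$end[bi] - 1L
    if (i1 > length(filtered)) i1 <- length(filtered)
    if (i1 - i0 < 3) next
    x <- filtered[i0:i1]
    t0 <- (i0 - 1) / fs
    cr <- find_crossings(x)
    cr <- merge_wiggles(cr, min_gap = round(min_halfwave_s * fs))
    down <- cr[cr$dir == "down", , drop = FALSE]
    up <- cr[cr$dir == "up", , drop = FALSE]
    if (nrow(down) < 2) next
    for (j in seq_len(nrow(down) - 1)) {
      u <- which(up$reach > down$leave[j] & up$reach < down$reach[j + 1])
      if (length(u) != 1) next
      # sample index ranges of each half-wave (1-based into x)
      neg_idx <- (floor(down$leave[j]) + 2):(ceiling(up$reach[u]))
      pos_idx <- (floor(up$leave[u]) + 2):(ceiling(down$reach[j + 1]))
      if (length(neg_idx) < 1 || length(pos_idx) < 1) next
      t_start <- t0 + down$leave[j] / fs
      t_mid <- t0 + up$reach[u] / fs
      t_end <- t0 + down$reach[j + 1] / fs
      ni <- neg_idx[which.min(x[neg_idx])]
      pi_ <- pos_idx[which.max(x[pos_idx])]
      neg_amp <- x[ni]
      pos_amp <- x[pi_]
      t_neg <- t0 + (ni - 1) / fs
      t_pos <- t0 + (pi_ - 1) / fs
      neg_dur <- t_mid - t_start
      pos_dur <- t_end - t_mid
      p2p <- pos_amp - neg_amp
      if (p2p < criteria$p2p_min) next
      if (neg_amp > criteria$neg_amp_max) next
      if (neg_dur < criteria$neg_dur_range[1] ||
          neg_dur > criteria$neg_dur_range[2]) next
      if (pos_dur > criteria$pos_dur_max) next
      if (!(t_start < t_neg && t_neg < t_mid && t_mid < t_pos &&
            t_pos < t_end)) next
      rows[[length(rows) + 1]] <- data.frame(
        channel = channel, t_start = t_start, t_neg_peak = t_neg,
        t_mid_cross = t_mid, t_pos_peak = t_pos, t_end = t_end,
        neg_amp = neg_amp, pos_amp = pos_amp, p2p = p2p,
        duration = t_end - t_start, frequency = 1 / (t_end - t_start),
        transition_freq = 1 / (2 * (t_pos - t_neg)),
        switcher = "unassigned", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(channel = character(), t_start = numeric(),
                      t_neg_peak = numeric(), t_mid_cross = numeric(),
                      t_pos_peak = numeric(), t_end = numeric(),
                      neg_amp = numeric(), pos_amp = numeric(),
                      p2p = numeric(), duration = numeric(),
                      frequency = numeric(), transition_freq = numeric(),
                      switcher = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$t_start), ]
}

#' Down-to-up transition frequency of a slow wave
#'
#' The transition from the hyperpolarised (negative peak) to the depolarised
#' (positive peak) state spans half an oscillation cycle, so its
#' characteristic frequency is `1 / (2 * (t_pos_peak - t_neg_peak))`. For a
#' symmetric wave this equals the wave's overall frequency `1/duration`.
#'
#' @param sw one slow-wave event (a row of [detect_slow_waves()] output, or
#'   any list with `t_neg_peak` and `t_pos_peak`).
#' @return transition frequency, Hz.
#' @export
transition_frequency <- function(sw) {
  dt <- sw$t_pos_peak - sw$t_neg_peak
  if (any(dt <= 0)) stop("non-positive down-to-up transition duration")
  1 / (2 * dt)
}

#' Fit the two-Gaussian switcher model to transition frequencies
#'
#' Fits a two-component univariate Gaussian mixture by
#' expectation-maximisation and locates the classification threshold at the
#' intersection of the two weighted component densities lying strictly
#' between the two means (around 1.2 Hz on cohort-like data). EM is
#' initialised deterministically by splitting the sample at `init_split` Hz,
#' so the fit is reproducible without any random state.
#'
#' @param transition_freqs numeric vector of transition frequencies, Hz
#'   (pooled across subjects by default usage; >= 50 values required).
#' @param init_split initial split point for EM initialisation, Hz.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @return object of class `switcher_model`: list with `means`, `sds`,
#'   `weights` (slow component first), `threshold` (Hz), `loglik`, `n_iter`.
#' @export
fit_switcher_model <- function(transition_freqs, init_split = 1.2,
                               tol = 1e-8, max_iter = 500) {
  x <- transition_freqs[is.finite(transition_freqs)]
  if (length(x) < 50)
    stop("need >= 50 transition frequencies spanning both modes; ",
         "pool slow waves across subjects")
  lo <- x < init_split
  if (sum(lo) < 2 || sum(!lo) < 2)
    stop("transition frequencies do not span both sides of ", init_split,
         " Hz; pool more data")
  mu <- c(mean(x[lo]), mean(x[!lo]))
  sd_ <- pmax(c(stats::sd(x[lo]), stats::sd(x[!lo])), 1e-3)
  w <- c(mean(lo), 1 - mean(lo))
  ll_old <- -Inf
  n_iter <- 0
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd_[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd_[2])
    tot <- d1 + d2
    ll <- sum(log(tot))
    r <- d1 / tot
    w <- c(mean(r), 1 - mean(r))
    mu <- c(sum(r * x) / sum(r), sum((1 - r) * x) / sum(1 - r))
    sd_ <- sqrt(c(sum(r * (x - mu[1])^2) / sum(r),
                  sum((1 - r) * (x - mu[2])^2) / sum(1 - r)))
    n_iter <- it
    if (any(sd_ < 1e-4))
      stop("degenerate EM solution: a mixture component collapsed")
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {  # keep slow component first
    mu <- rev(mu); sd_ <- rev(sd_); w <- rev(w)
  }
  thr <- gaussian_intersection(mu, sd_, w)
  structure(list(means = mu, sds = sd_, weights = w, threshold = thr,
                 loglik = ll, n_iter = n_iter),
            class = "switcher_model")
}

#' Intersection of two weighted Gaussian densities between their means
#'
#' Solves `w1 N(x; m1, s1) = w2 N(x; m2, s2)` via the quadratic obtained by
#' equating log-densities and returns the root strictly between the means.
#'
#' @param means,sds,weights length-2 numeric vectors (first component must
#'   have the smaller mean).
#' @return the intersection abscissa.
#' @export
gaussian_intersection <- function(means, sds, weights) {
  m1 <- means[1]; m2 <- means[2]
  s1 <- sds[1]; s2 <- sds[2]
  w1 <- weights[1]; w2 <- weights[2]
  stopifnot(m1 < m2, s1 > 0, s2 > 0, w1 > 0, w2 > 0)
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log((w1 * s2) / (w2 * s1))
  if (abs(a) < 1e-14) {
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("no real intersection between component densities")
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) == 0)
    stop("no density intersection strictly between the two means")
  inside[1]
}

#' @export
print.switcher_model <- function(x, ...) {
  cat(sprintf(paste0("<switcher_model> slow: N(%.3f, %.3f^2) w=%.2f | ",
                     "fast: N(%.3f, %.3f^2) w=%.2f | threshold %.3f Hz\n"),
              x$means[1], x$sds[1], x$weights[1],
              x$means[2], x$sds[2], x$weights[2], x$threshold))
  invisible(x)
}

#' Label slow waves as slow or fast switchers
#'
#' `slow` iff `transition_freq < threshold`, else `fast` (a wave exactly at
#' the threshold is labelled fast; the rule is stable and measure-zero).
#' Idempotent.
#'
#' @param events slow-wave event data.frame.
#' @param model a fitted [fit_switcher_model()].
#' @return `events` with the `switcher` column filled.
#' @export
classify_switchers <- function(events, model) {
  stopifnot(inherits(model, "switcher_model"))
  events$switcher <- ifelse(events$transition_freq < model$threshold,
                            "slow", "fast")
  events
}

#' Slow-wave density per minute of N2/N3 sleep
#'
#' Counts per minute are computed per channel, then averaged across channels
#' (F3, Fz, F4 in the standard frontal montage).
#'
#' @param events slow-wave event data.frame (with `channel`, `switcher`).
#' @param n2n3_minutes selected N2/N3 time, minutes (> 0).
#' @param channels channels to average over; defaults to those present in
#'   `events`, or "F3" for an empty table.
#' @return list with `total`, `slow`, `fast` densities (events/minute).
#' @export
sw_density <- function(events, n2n3_minutes, channels = NULL) {
  if (n2n3_minutes <= 0) stop("n2n3_minutes must be positive")
  if (is.null(channels)) {
    channels <- unique(events$channel)
    if (length(channels) == 0) channels <- "F3"
  }
  per_chan <- function(sub) {
    vapply(channels, function(ch) sum(sub$channel == ch) / n2n3_minutes, 0)
  }
  list(total = mean(per_chan(events)),
       slow = mean(per_chan(events[events$switcher == "slow", , drop = FALSE])),
       fast = mean(per_chan(events[events$switcher == "fast", , drop = FALSE])))
}
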