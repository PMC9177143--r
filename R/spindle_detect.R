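#' Smoothed Hilbert envelope of a sigma-band signal
#'
#' Modulus of the analytic signal, smoothed with a centred moving average.
#' The default 0.2 s window is shorter than the minimum spindle duration
#' (0.5 s) but longer than one cycle of a 13 Hz spindle, so it removes
#' within-cycle ripple without blurring event boundaries.
#'
#' @param signal signal already band-pass filtered 10-16 Hz, microvolts.
#' @param fs sampling rate, Hz.
#' @param smooth_win smoothing window, seconds (must span >= 2 samples).
#' @return envelope, microvolts, same length as `signal`.
#' @export
spindle_envelope <- function(signal, fs, smooth_win = 0.2) {
  k <- round(smooth_win * fs)
  if (k < 2) stop("smoothing window shorter than 2 samples")
  moving_average(hilbert_envelope(signal), k)
}

#' Detect sleep spindles by percentile-thresholded envelope
#'
#' Filters the raw channel 10-16 Hz, computes the smoothed Hilbert envelope,
#' and sets the detection threshold at the given percentile (default 75th) of
#' the envelope over all non-flagged samples of the analysis segments.
#' Maximal supra-threshold runs lasting 0.5-3 s become spindles; the onset
#' ("ignition") is the first supra-threshold sample. Runs longer than 3 s are
#' discarded entirely, runs are never merged across sub-threshold gaps, and
#' runs cut by the edge of a contiguous block of selected epochs are
#' discarded.
#'
#' @param signal raw (unfiltered) channel, microvolts.
#' @param fs sampling rate, Hz.
#' @param segments an `analysis_segments` object from
#'   [select_analysis_segments()]; NULL scans the whole signal.
#' @param channel label stored with the events.
#' @param percentile envelope percentile defining the threshold (0-100).
#' @param dur_range admissible spindle duration, seconds.
#' @param smooth_win envelope smoothing window, seconds.
#' @param threshold absolute envelope threshold in microvolts, overriding the
#'   percentile rule (e.g. a threshold calibrated on a reference recording;
#'   a percentile threshold is always relative to the analysed recording and
#'   is inapplicable to event-free signal).
#' @return data.frame of spindle events: `channel`, `onset`, `offset`,
#'   `duration` (seconds from recording start), `peak_env`,
#'   `threshold_used` (microvolts).
#' @export
detect_spindles <- function(signal, fs, segments = NULL, channel = "F3",
                            percentile = 75, dur_range = c(0.5, 3),
                            smooth_win = 0.2, threshold = NULL) {
  empty <- data.frame(channel = character(), onset = numeric(),
                      offset = numeric(), duration = numeric(),
                      peak_env = numeric(), threshold_used = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(segments)) {
    blocks <- data.frame(start = 1L, end = length(signal) + 1L)
    flagged <- integer(0)
  } else {
    blocks <- merge_intervals(segments$intervals)
    flagged <- segments$flagged
    if (nrow(blocks) == 0) return(empty)
  }
  filt <- fir_bandpass(signal, fs, 10, 16)
  env <- spindle_envelope(filt, fs, smooth_win)

  if (is.null(threshold)) {
    sel <- unlist(lapply(seq_len(nrow(blocks)),
                         function(i) blocks$start[i]:(min(blocks$end[i] - 1L,
                                                          length(signal)))))
    ref <- setdiff(sel, flagged)
    thr <- stats::quantile(env[ref], percentile / 100, names = FALSE)
  } else {
    thr <- threshold
  }

  rows <- list()
  for (bi in seq_len(nrow(blocks))) {
    i0 <- blocks$start[bi]
    i1 <- min(blocks$end[bi] - 1L, length(signal))
    above <- env[i0:i1] > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      if (starts[k] == 1 || ends[k] == length(above)) next  # cut by edge
      dur <- r$lengths[k] / fs
      if (dur < dur_range[1] || dur > dur_range[2]) next
      a <- i0 + starts[k] - 1L
      b <- i0 + ends[k] - 1L
      rows[[length(rows) + 1]] <- data.frame(
        channel = channel, onset = (a - 1) / fs, offset = (b - 1) / fs + 1 / fs,
        duration = dur, peak_env = max(env[a:b]), threshold_used = thr,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Spindle density per minute of N2/N3 sleep
#'
#' @param events spindle event data.frame.
#' @param n2n3_minutes selected N2/N3 time, minutes (> 0).
#' @param channels channels to average over; defaults to those present.
#' @return spindles per minute, averaged across channels.
#' @export
spindle_density <- function(events, n2n3_minutes, channels = NULL) {
  if (n2n3_minutes <= 0) stop("n2n3_minutes must be positive")
  if (is.null(channels)) {
    channels <- unique(events$channel)
    if (length(channels) == 0) channels <- "F3"
  }
  mean(vapply(channels,
              function(ch) sum(events$channel == ch) / n2n3_minutes, 0))
}
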