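#' Band power of one epoch via Hann-tapered periodogram
#'
#' Integrates the modified (Hann-windowed) periodogram over the half-open
#' band `[lo, hi)`. The periodogram is normalised by the window energy, so
#' the integral over all frequencies equals the signal's mean power and a
#' pure sinusoid of amplitude A inside the band contributes `A^2/2`.
#'
#' @param signal one epoch of signal, microvolts.
#' @param fs sampling rate, Hz.
#' @param band numeric length-2, `c(lo, hi)` in Hz.
#' @return band power, microvolts squared.
#' @export
epoch_band_power <- function(signal, fs, band) {
  n <- length(signal)
  stopifnot(band[1] >= 0, band[2] > band[1], band[2] <= fs / 2)
  df <- fs / n
  if (df > band[2] - band[1])
    stop("epoch too short: frequency resolution ", signif(df, 3),
         " Hz exceeds band width")
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))  # Hann taper
  X <- stats::fft(signal * w)
  # one-sided PSD in uV^2/Hz, window-energy normalised
  n_half <- floor(n / 2) + 1
  psd <- (Mod(X[seq_len(n_half)])^2) / (fs * sum(w^2))
  psd[2:(n_half - 1)] <- 2 * psd[2:(n_half - 1)]
  freqs <- (seq_len(n_half) - 1) * df
  sel <- freqs >= band[1] & freqs < band[2]
  sum(psd[sel]) * df
}

#' Overnight cumulated band-power summary
#'
#' For every 30-s analysis epoch (contiguous sub-blocks of the selected N2/N3
#' segments; epochs containing flagged artifact samples are skipped),
#' computes power in the 0.5-1 Hz, 1-4 Hz and 0.5-4 Hz bands, sums across
#' epochs per band (cumulated power, the slow-wave-energy convention),
#' averages channels, and forms the ratio of cumulated 0.5-1 Hz over
#' cumulated 1-4 Hz power.
#'
#' @param recording an [eeg_recording()].
#' @param segments an `analysis_segments` object.
#' @param epoch_s epoch length in seconds (default 30).
#' @return list of class `band_power_summary`: `power` named vector of
#'   cumulated powers (`delta_low` 0.5-1 Hz, `delta_high` 1-4 Hz, `delta`
#'   0.5-4 Hz, in microvolts squared x epochs), `ratio_slow_fast`,
#'   `n_epochs`.
#' @export
overnight_summary <- function(recording, segments, epoch_s = 30) {
  stopifnot(inherits(recording, "eeg_recording"))
  blocks <- segments$intervals
  if (nrow(blocks) == 0) stop("no analysis segments: summary undefined")
  fs <- recording$fs
  ep_n <- round(epoch_s * fs)
  bands <- list(delta_low = c(0.5, 1), delta_high = c(1, 4),
                delta = c(0.5, 4))
  n_chan <- ncol(recording$data)
  acc <- matrix(0, n_chan, length(bands),
                dimnames = list(NULL, names(bands)))
  n_epochs <- 0
  for (bi in seq_len(nrow(blocks))) {
    i0 <- blocks$start[bi]
    i1 <- blocks$end[bi] - 1L
    n_sub <- floor((i1 - i0 + 1) / ep_n)
    for (k in seq_len(n_sub)) {
      a <- i0 + (k - 1) * ep_n
      b <- a + ep_n - 1L
      if (length(segments$flagged) > 0 &&
          any(segments$flagged >= a & segments$flagged <= b)) next
      n_epochs <- n_epochs + 1
      for (ch in seq_len(n_chan)) {
        x <- recording$data[a:b, ch]
        for (bn in seq_along(bands))
          acc[ch, bn] <- acc[ch, bn] + epoch_band_power(x, fs, bands[[bn]])
      }
    }
  }
  if (n_epochs == 0) stop("all epochs excluded: summary undefined")
  power <- colMeans(acc)
  if (power[["delta_high"]] <= 0)
    stop("zero 1-4 Hz power: ratio undefined")
  structure(list(power = power,
                 ratio_slow_fast = power[["delta_low"]] / power[["delta_high"]],
                 n_epochs = n_epochs),
            class = "band_power_summary")
}
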