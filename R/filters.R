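#' Zero-phase FIR band-pass filter
#'
#' Designs a linear-phase (windowed-sinc, Hamming) FIR band-pass filter and
#' applies it with group-delay compensation, so the output is effectively
#' zero-phase and the same length as the input. The default order is chosen
#' from the narrower of the lower band edge and half the bandwidth, giving a
#' transition band narrow enough that attenuation at the stated edges is
#' close to the half-power (-3 dB) point.
#'
#' @param x numeric signal, microvolts.
#' @param fs sampling rate, Hz.
#' @param low,high band edges, Hz; `0 < low < high < fs/2`.
#' @param order filter order (number of taps minus one, forced even);
#'   `NULL` selects `ceiling(3.3 * fs / tw)` with transition width
#'   `tw = min(low, (high - low)/2)`.
#' @return filtered signal, same length as `x`.
#' @export
fir_bandpass <- function(x, fs, low, high, order = NULL) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  if (is.null(order)) {
    tw <- min(low, (high - low) / 2)
    order <- ceiling(3.3 * fs / tw)
  }
  if (order %% 2 == 1) order <- order + 1
  b <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  gd <- order / 2
  y <- signal::fftfilt(b, c(x, numeric(gd)))
  y[(gd + 1):(gd + length(x))]
}

#' Analytic-signal envelope
#'
#' Modulus of the analytic signal obtained via the FFT construction of the
#' Hilbert transform (positive frequencies doubled, negative zeroed).
#'
#' @param x numeric signal (already band-limited for a meaningful envelope).
#' @return non-negative envelope, same length as `x`.
#' @keywords internal
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Centred moving-average smoother preserving length
#'
#' Window ends are averaged over the available samples (shrinking window),
#' so no NA padding is introduced.
#'
#' @param x numeric vector.
#' @param k window width in samples (>= 2).
#' @return smoothed vector, same length.
#' @keywords internal
moving_average <- function(x, k) {
  if (k < 2) stop("smoothing window must span at least 2 samples")
  n <- length(x)
  half_l <- floor((k - 1) / 2)
  half_r <- k - 1 - half_l
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
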