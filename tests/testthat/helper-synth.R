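# shared fixture builders

# a clean (noise-free) signal holding the given slow-wave recipes
clean_sw_signal <- function(recipes, duration, fs = 200) {
  sig <- numeric(round(duration * fs))
  for (r in recipes) {
    w <- synth_slow_wave(r, fs)$waveform
    i0 <- round(r$at * fs) + 1
    idx <- i0:(i0 + length(w) - 1)
    sig[idx] <- sig[idx] + w
  }
  sig
}

# sensitivity/precision of detected vs true event times at a tolerance (s)
match_rates <- function(detected, truth, tol = 0.1) {
  sens <- mean(vapply(truth, function(ts) any(abs(detected - ts) < tol), TRUE))
  prec <- mean(vapply(detected, function(ts) any(abs(truth - ts) < tol), TRUE))
  c(sens = sens, prec = prec)
}

# wrapped von Mises sample around mu
rvm <- function(n, mu, kappa) {
  (mu + vapply(seq_len(n), function(i) swcoupling:::rvonmises_one(kappa), 0)) %% (2 * pi)
}

# numeric intersection of two weighted normal densities between the means
numeric_intersection <- function(means, sds, weights) {
  f <- function(x) weights[1] * dnorm(x, means[1], sds[1]) -
    weights[2] * dnorm(x, means[2], sds[2])
  uniroot(f, c(means[1] + 1e-6, means[2] - 1e-6))$root
}
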