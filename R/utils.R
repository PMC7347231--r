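# internal helpers shared across modules

# linear resampling of a vector to a fixed length
resample_linear <- function(x, n_out) {
  n <- length(x)
  if (n == n_out) return(x)
  if (n == 1L) return(rep(x, n_out))
  stats::approx(seq_len(n), x, xout = seq(1, n, length.out = n_out))$y
}

# population (biased) moments; `sample_moments = TRUE` switches to the
# sample skewness / excess-free kurtosis definitions
moment_skewness <- function(x, sample_moments = FALSE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L || stats::sd(x) == 0) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  if (sample_moments && n > 2L) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

moment_kurtosis <- function(x, sample_moments = FALSE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L || stats::sd(x) == 0) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g2 <- mean((x - m)^4) / s2^2
  if (sample_moments && n > 3L) {
    ((n + 1) * (g2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3)) + 3
  } else {
    g2
  }
}

# largest off-zero autocovariance *peak* (local maximum of the
# autocorrelation over positive lags) relative to lag zero; the signal is
# mean-centred so constants score zero, and a monotone-decaying
# autocorrelation (linear ramps) has no off-zero peak and also scores zero
salience_ratio <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) return(NA_real_)
  xc <- x - mean(x)
  ac0 <- sum(xc^2)
  if (ac0 <= 0) return(0)
  ac <- vapply(seq_len(n - 1L), function(lag) {
    sum(xc[seq_len(n - lag)] * xc[(lag + 1L):n])
  }, numeric(1))
  full <- c(ac0, ac)                 # lags 0 .. n-1
  m <- length(ac)
  is_peak <- vapply(seq_len(m), function(l) {
    left <- full[l]                  # lag l-1
    right <- if (l < m) ac[l + 1L] else -Inf
    ac[l] > left && ac[l] >= right
  }, logical(1))
  if (!any(is_peak)) return(0)
  max(ac[is_peak]) / ac0
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
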