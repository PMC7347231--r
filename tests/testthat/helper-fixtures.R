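# fixtures built in code; all randomness seeded locally in the tests

# a degenerate profile producing exactly one deterministic call geometry
fixed_profile <- function(duration = 50, freq = 60, range = 0,
                          direction = "flat", p_breaks = c(1),
                          p_tremolo = 0, p_broadband = 0) {
  p_dir <- c(down = 0, flat = 0, up = 0)
  p_dir[direction] <- 1
  usv_profile("fixed",
              duration_ms = c(duration, 0), mean_freq_khz = c(freq, 0),
              freq_range_khz = c(range, 0), p_direction = p_dir,
              p_peaks = c(1), p_breaks = p_breaks,
              p_tremolo = p_tremolo, p_broadband = p_broadband)
}

# tonal-call profiles (no broadband or tremolo): used where the check is
# about tracker geometry rather than robustness to structured content
tonal_profiles <- function() {
  lapply(default_profiles(), function(p) {
    p$p_broadband <- 0
    p$p_tremolo <- 0
    p
  })
}

# spectrogram patch with a single constant-frequency ridge
ridge_matrix <- function(n_freq = 60, n_time = 40, row = 30, value = 10) {
  m <- matrix(0, n_freq, n_time)
  m[row, ] <- value
  m
}

# brute-force feature formula oracles (plain loops, independent of the
# package implementations)
bf_wiener_entropy <- function(m) {
  vals <- c()
  for (t in seq_len(ncol(m))) {
    x <- m[, t]
    if (all(x == 0)) next
    g <- 1
    for (v in x) g <- g * v^(1 / length(x))
    vals <- c(vals, g / (sum(x) / length(x)))
  }
  mean(vals)
}

bf_spectral_purity <- function(m) {
  vals <- c()
  for (t in seq_len(ncol(m))) {
    x <- m[, t]
    if (all(x == 0)) next
    med <- median(x)
    if (med <= 0) med <- min(x[x > 0])
    vals <- c(vals, max(x) / med)
  }
  mean(vals)
}

bf_salience_ratio <- function(x) {
  n <- length(x)
  xc <- x - sum(x) / n
  ac0 <- sum(xc * xc)
  if (ac0 <= 0) return(0)
  ac <- numeric(n - 1)
  for (lag in 1:(n - 1)) {
    s <- 0
    for (f in 1:(n - lag)) s <- s + xc[f] * xc[f + lag]
    ac[lag] <- s
  }
  # largest off-zero local maximum of the autocorrelation
  best <- NA_real_
  for (l in 1:(n - 1)) {
    left <- if (l == 1) ac0 else ac[l - 1]
    right <- if (l == n - 1) -Inf else ac[l + 1]
    if (ac[l] > left && ac[l] >= right) {
      if (is.na(best) || ac[l] > best) best <- ac[l]
    }
  }
  if (is.na(best)) 0 else best / ac0
}

bf_spectral_salience <- function(m) {
  vals <- c()
  for (t in seq_len(ncol(m))) {
    x <- m[, t]
    if (all(x == 0)) next
    vals <- c(vals, bf_salience_ratio(x))
  }
  mean(vals)
}

bf_weighted_mean_freq <- function(m, freq) {
  vals <- c()
  for (t in seq_len(ncol(m))) {
    x <- m[, t]
    if (sum(x) <= 0) next
    s <- 0
    for (f in seq_along(freq)) s <- s + freq[f] * x[f]
    vals <- c(vals, s / sum(x))
  }
  mean(vals)
}

bf_direction <- function(ff) {
  v <- ff[ff > 0]
  if (length(v) < 2) return(0L)
  m <- sum(diff(v)) / (length(v) - 1)
  if (abs(m) < 0.1) 0L else as.integer(sign(m))
}

# hand-built fundamental track object
make_track <- function(ff, fe = NULL, fp = 1 / 1.2) {
  if (is.null(fe)) fe <- ifelse(ff > 0, 1, NA_real_)
  structure(list(ff_khz = ff, fe = fe, frames = seq_along(ff),
                 frame_period_ms = fp),
            class = "fundamental_track")
}
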