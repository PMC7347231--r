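test_that("curvature-flow denoising removes speckle but preserves ridges", {
  set.seed(20)
  m <- matrix(0, 50, 60)
  m[sample(length(m), 40)] <- 10
  out <- denoise_curvature_flow(m, iterations = 10)
  expect_lt(sum(out^2) / sum(m^2), 0.10)

  rg <- matrix(0, 50, 60)
  for (j in 1:60) rg[25 + round(5 * sin(j / 10)), j] <- 10
  rgd <- denoise_curvature_flow(rg, 10)
  expect_gte(cor(apply(rg, 2, which.max), apply(rgd, 2, which.max)), 0.95)

  const <- matrix(5, 10, 10)
  expect_equal(denoise_curvature_flow(const, 5), const)
  expect_error(denoise_curvature_flow(matrix(-1, 5, 5)), "non-negative")
})

test_that("fundamental tracking recovers flat calls, gaps and outliers", {
  set.seed(21)
  w <- synthesize_call(sample_trajectory(fixed_profile(duration = 50,
                                                       freq = 60)))
  sp <- stft_magnitude(w)
  sp$values <- sp$values^2
  track <- extract_fundamental(sp)
  voiced <- track$ff_khz[track$ff_khz > 0]
  expect_true(all(abs(voiced - 60) <= 0.6))
  expect_equal(n_breaks(track), 0L)

  # call with an interior silent gap -> contiguous run of FF = 0
  trg <- sample_trajectory(fixed_profile(duration = 60, freq = 70,
                                         p_breaks = c(0, 1)))
  spg <- stft_magnitude(synthesize_call(trg))
  spg$values <- spg$values^2
  trackg <- extract_fundamental(denoise_curvature_flow(spg, 5))
  expect_equal(n_breaks(trackg), 1L)
  r <- rle(trackg$ff_khz == 0)
  expect_gte(max(r$lengths[r$values]), 2)

  # single-frame >5 kHz spike is replaced by neighbour interpolation
  spike <- matrix(0, 233, 9)
  freq <- usv_freq_axis()
  r60 <- which.min(abs(freq - 60))
  r70 <- which.min(abs(freq - 70))
  spike[r60, ] <- 100
  spike[r60, 5] <- 0
  spike[r70, 5] <- 100
  tr <- extract_fundamental(spike, freq_khz = freq)
  expect_equal(tr$ff_khz[tr$frames == 5 | seq_along(tr$ff_khz) == 5][1],
               freq[r60], tolerance = 0.61)

  expect_error(extract_fundamental(matrix(0, 233, 10),
                                   freq_khz = usv_freq_axis()), "track")
})

test_that("spectral marginal accumulates fundamental energy per bin", {
  freq <- usv_freq_axis()
  tr <- make_track(rep(60, 10), rep(3.5, 10))
  marg <- spectral_marginal(tr, freq)
  expect_length(marg, 233)
  expect_equal(sum(marg > 0), 1)
  expect_equal(max(marg), 3.5)

  # sweep covering a bin range: support exactly that range
  ffs <- freq[50:80]
  trs <- make_track(ffs, rep(1, length(ffs)))
  margs <- spectral_marginal(trs, freq)
  expect_equal(which(margs > 0), 50:80)

  allbreak <- make_track(rep(0, 5))
  expect_equal(spectral_marginal(allbreak, freq), numeric(233))
})

test_that("Wiener entropy follows the geometric/arithmetic mean ratio", {
  expect_equal(wiener_entropy(matrix(3, 10, 4)), 1)
  m <- matrix(c(1, 4), 2, 1)
  expect_equal(wiener_entropy(m), 2 / 2.5)
  withzero <- matrix(c(0, 1, 2, 3), 4, 1)
  expect_equal(wiener_entropy(withzero), 0)
  set.seed(22)
  r <- matrix(abs(rnorm(200)), 20, 10)
  expect_gte(wiener_entropy(r), 0)
  expect_lte(wiener_entropy(r), 1)
})

test_that("spectral salience detects periodic spectral structure", {
  ripple <- matrix(rep(sin(2 * pi * (1:50) / 5) + 1.5, 2), 50, 2)
  expect_equal(spectral_salience(ripple), bf_spectral_salience(ripple),
               tolerance = 1e-12)
  expect_gt(spectral_salience(ripple), 0.5)

  set.seed(23)
  noise <- matrix(abs(rnorm(233)), 233, 1)
  expect_lt(spectral_salience(noise), 0.2)

  two <- cbind(ripple[, 1], ripple[, 1])
  expect_equal(spectral_salience(two),
               bf_salience_ratio(ripple[, 1]), tolerance = 1e-12)
})

test_that("tremolo scoring responds to sinusoidal FF modulation", {
  mod <- make_track(70 + 5 * sin(2 * pi * (1:40) / 8))
  expect_gt(tremolo_score(mod), 0.5)
  expect_equal(tremolo_score(mod), bf_salience_ratio(mod$ff_khz),
               tolerance = 1e-12)
  expect_equal(tremolo_score(make_track(rep(70, 20))), 0)
  sweep <- make_track(seq(50, 80, length.out = 40))
  expect_lt(tremolo_score(sweep), tremolo_score(mod))
  expect_true(is.na(tremolo_score(make_track(c(60, 60, 60)))))
})

test_that("spectral purity is the max/median ratio with a positive floor", {
  expect_equal(spectral_purity(matrix(2, 8, 3)), 1)
  m <- matrix(1, 9, 1); m[5] <- 10
  expect_equal(spectral_purity(m), 10)
  two <- cbind(c(2, 1, 1), c(4, 1, 1))
  expect_equal(spectral_purity(two), 3)
  sparse <- matrix(0, 9, 1); sparse[3] <- 6; sparse[7] <- 2
  expect_equal(spectral_purity(sparse), 3)  # median 0 -> floor = 2
})

test_that("scalar features satisfy their algebraic invariants", {
  set.seed(24)
  w <- synthesize_call(sample_trajectory(fixed_profile(duration = 50,
                                                       freq = 60)))
  sp <- stft_magnitude(w)
  sp$values <- sp$values^2
  track <- extract_fundamental(sp)
  f <- scalar_features(track, sp)
  expect_equal(f$spectral_width_khz, 0)
  expect_equal(f$direction, 0L)
  expect_equal(f$start_freq_khz, f$end_freq_khz)
  expect_equal(f$mean_freq_ff_khz, 60, tolerance = 0.6)
  expect_equal(f$duration_ms, 50, tolerance = 2)
  expect_true(f$min_freq_khz <= f$mean_freq_ff_khz &&
                f$mean_freq_ff_khz <= f$max_freq_khz)
  expect_gte(f$wiener_entropy, 0); expect_lte(f$wiener_entropy, 1)
  expect_gte(f$spectral_purity, 1)

  # direction from hand-computed single-step differences
  tr <- make_track(c(50, 52, 51))
  sp2 <- matrix(1, 233, 3)
  f2 <- scalar_features(tr, sp2)
  expect_equal(f2$direction, 1L)

  # weighted mean frequency by symmetry
  m <- matrix(0, 233, 4)
  freq <- usv_freq_axis()
  m[which.min(abs(freq - 40)), ] <- 1
  m[which.min(abs(freq - 80)), ] <- 1
  spw <- structure(list(values = m, freq_khz = freq,
                        time_ms = 1:4, frame_period_ms = 1 / 1.2),
                   class = "usv_spectrogram")
  fw <- scalar_features(make_track(rep(60, 4)), spw)
  expect_equal(fw$mean_freq_weighted_khz, 60, tolerance = 0.01)
})

test_that("the extended vector has the documented 457-dim layout", {
  set.seed(25)
  scalars <- as.numeric(1:18)
  scores <- c(1, 0, 2, 0, 1, 0.5)
  marg <- list(ff_line = runif(100), time_marginal = runif(100),
               freq_marginal = runif(233))
  v <- assemble_extended_vector(scalars, scores, marg)
  expect_length(v, 457)
  expect_equal(unname(v[1:18]), scalars)
  expect_equal(unname(v[19:24]), scores)
  expect_equal(unname(v[25:124]), marg$ff_line)
  expect_equal(unname(v[125:357]), marg$freq_marginal)
  expect_equal(unname(v[358:457]), marg$time_marginal)

  zeromarg <- list(ff_line = numeric(100), time_marginal = numeric(100),
                   freq_marginal = numeric(233))
  vz <- assemble_extended_vector(scalars, scores, zeromarg)
  expect_true(all(vz[25:457] == 0))

  f <- tempfile(fileext = ".rds")
  saveRDS(v, f)
  expect_identical(readRDS(f), v)

  expect_error(assemble_extended_vector(scalars[1:5], scores, marg), "18")
  expect_error(assemble_extended_vector(scalars, scores,
                                        list(ff_line = 1:10,
                                             time_marginal = 1:10,
                                             freq_marginal = 1:10)))
})

test_that("marginals have fixed dimensions and are non-negative", {
  set.seed(26)
  tr <- make_track(c(rep(60, 30), rep(0, 5), rep(65, 30)),
                   c(rep(2, 30), rep(NA, 5), rep(3, 30)))
  ms <- marginal_set(tr)
  expect_length(ms$ff_line, 100)
  expect_length(ms$time_marginal, 100)
  expect_length(ms$freq_marginal, 233)
  expect_true(all(ms$time_marginal >= 0))
  expect_true(all(ms$freq_marginal >= 0))
  # short track: zero padding beyond the call
  expect_true(any(ms$ff_line == 0))
})

test_that("each formula matches brute-force evaluation on random matrices", {
  set.seed(27)
  freq <- seq(30, 49, length.out = 20)
  for (i in 1:25) {
    m <- matrix(abs(rnorm(400)) + 0.01, 20, 20)
    expect_equal(wiener_entropy(m), bf_wiener_entropy(m),
                 tolerance = 1e-9)
    expect_equal(spectral_purity(m), bf_spectral_purity(m),
                 tolerance = 1e-9)
    expect_equal(spectral_salience(m), bf_spectral_salience(m),
                 tolerance = 1e-9)
    sp <- structure(list(values = m, freq_khz = freq, time_ms = 1:20,
                         frame_period_ms = 1 / 1.2),
                    class = "usv_spectrogram")
    tr <- make_track(freq[apply(m, 2, which.max)])
    f <- scalar_features(tr, sp)
    expect_equal(f$mean_freq_weighted_khz, bf_weighted_mean_freq(m, freq),
                 tolerance = 1e-9)
    expect_equal(f$direction, bf_direction(tr$ff_khz))
  }
})

test_that("feature recovery holds on noiseless tonal calls", {
  set.seed(28)
  rec <- feature_recovery_experiment(n_calls = 40,
                                     profiles = tonal_profiles())
  expect_gte(mean(rec$duration_ok), 0.95)
  expect_gte(mean(rec$freq_ok), 0.95)
  expect_gte(mean(rec$sw_ok), 0.95)
  expect_gte(mean(rec$breaks_ok), 0.95)
  expect_gte(mean(rec$direction_ok), 0.95)
})
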