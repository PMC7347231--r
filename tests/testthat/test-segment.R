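test_that("high-pass filter matches the analytic Butterworth magnitude", {
  fs <- 300000
  t <- seq(0, 0.05, by = 1 / fs)
  # DC is removed
  out <- highpass(rep(1, 10000))
  expect_lt(max(abs(tail(out, 5000))), 1e-6)
  # 60 kHz (f/fc = 2.4): amplitude preserved within 1%
  tone60 <- sin(2 * pi * 60000 * t)
  out60 <- highpass(tone60)
  amp <- sqrt(2) * sd(out60[5000:length(out60)])
  expect_equal(amp, 1, tolerance = 0.01)
  # 10 kHz (f/fc = 0.4): ~32 dB attenuation for a 4th-order filter
  tone10 <- sin(2 * pi * 10000 * t)
  out10 <- highpass(tone10)
  att_db <- -20 * log10(sqrt(2) * sd(out10[5000:length(out10)]))
  expect_equal(att_db, -20 * log10(1 / sqrt(1 + 2.5^8)), tolerance = 1)
  expect_error(highpass(tone10, cutoff_khz = 200), "Nyquist")
})

test_that("spectrogram frame geometry follows the window/hop arithmetic", {
  w <- rnorm(300000)
  sp <- stft_magnitude(w)
  expect_equal(ncol(sp$values), floor((300000 - 500) / 250) + 1)  # 1199
  expect_equal(ncol(sp$values), 1199)
  expect_equal(nrow(sp$values), 233)
  expect_equal(sp$frame_period_ms, 250 / 300, tolerance = 1e-12)
  expect_equal(diff(sp$freq_khz[1:2]), 0.6)
  expect_true(all(sp$values >= 0))
  expect_true(!is.unsorted(sp$freq_khz) && !is.unsorted(sp$time_ms))
  expect_error(stft_magnitude(rnorm(100)), "shorter")

  tone <- sin(2 * pi * 60000 * seq(0, 0.02, by = 1 / 300000))
  spt <- stft_magnitude(tone)
  expect_equal(length(unique(apply(spt$values, 2, which.max))), 1)
})

test_that("sparsification zeroes exactly the bins below the percentile", {
  m <- matrix(sample(1:100), 10, 10)
  s <- sparsify(m, 70)
  expect_true(all(s[m <= 69] == 0))
  expect_true(all(s[m >= 70] == m[m >= 70]))

  eq <- matrix(5, 4, 4)
  expect_equal(sparsify(eq, 70), eq)

  set.seed(10)
  r <- matrix(runif(10000), 100, 100)
  expect_equal(mean(sparsify(r, 70) == 0), 0.70, tolerance = 0.01)
})

test_that("energy criterion keeps frames that exceed the recording-wide quantile", {
  set.seed(11)
  m <- matrix(abs(rnorm(233 * 500)), 233, 500)
  mask <- energy_gate(m, 99.8)
  thr <- quantile(m, 0.998, type = 1, names = FALSE)
  expect_equal(mask, apply(m, 2, max) > thr)

  loud <- matrix(1, 50, 20)
  loud[25, 7] <- 10
  expect_true(energy_gate(loud, 99.8)[7])
  expect_false(any(energy_gate(matrix(0, 10, 10), 99.8)))
})

test_that("continuity criterion accumulates peak-track displacement", {
  flat <- ridge_matrix()
  cand <- tibble::tibble(start_frame = 1L, end_frame = 40L)
  expect_true(continuity_gate(flat, cand))

  # peak jumping 20 bins per frame: min accumulated 80 >= 15 -> fail
  jump <- matrix(0, 60, 20)
  for (t in 1:20) jump[if (t %% 2) 10 else 30, t] <- 5
  expect_false(continuity_gate(jump, tibble::tibble(start_frame = 1L,
                                                    end_frame = 20L)))

  # sweep at 1 bin/frame: accumulated 4 < 15 -> pass
  sweep <- matrix(0, 60, 20)
  for (t in 1:20) sweep[10 + t, t] <- 5
  expect_true(continuity_gate(sweep, tibble::tibble(start_frame = 1L,
                                                    end_frame = 20L)))

  # single-frame candidates pass by convention
  expect_true(continuity_gate(flat, tibble::tibble(start_frame = 3L,
                                                   end_frame = 3L)))
})

test_that("frequency criterion uses the energy-weighted mean", {
  cfg <- segmentation_config()
  tone <- stft_magnitude(sin(2 * pi * 60000 * seq(0, 0.02, 1 / 3e5)), cfg)
  cand <- tibble::tibble(start_frame = 1L, end_frame = ncol(tone$values))
  expect_true(frequency_gate(tone, cand))

  # energy centred at 20 kHz fails; equal energy at 20 and 40 kHz passes
  low <- tone
  low$values[] <- 0
  r20 <- which.min(abs(low$freq_khz - 20))
  r40 <- which.min(abs(low$freq_khz - 40))
  low$values[r20, ] <- 1
  expect_false(frequency_gate(low, cand))
  low$values[r40, ] <- 1
  expect_true(frequency_gate(low, cand))

  zero <- tone
  zero$values[] <- 0
  expect_false(frequency_gate(zero, cand))
})

test_that("gap merging is strict, chainable and idempotent", {
  cands <- tibble::tibble(
    start_frame = c(1L, 20L, 50L), end_frame = c(10L, 30L, 60L),
    onset_ms = c(0, 20, 55), offset_ms = c(10, 35, 70))
  m <- merge_candidates(cands, 15)   # gaps are 10 and 20 ms
  expect_equal(nrow(m), 2)
  expect_equal(m$onset_ms, c(0, 55))
  expect_equal(m$offset_ms[1], 35)

  exact <- tibble::tibble(start_frame = c(1L, 5L), end_frame = c(2L, 8L),
                          onset_ms = c(0, 25), offset_ms = c(10, 30))
  expect_equal(nrow(merge_candidates(exact, 15)), 2)

  chain <- tibble::tibble(
    start_frame = seq(1L, by = 10L, length.out = 5),
    end_frame = seq(5L, by = 10L, length.out = 5),
    onset_ms = seq(0, by = 15, length.out = 5),
    offset_ms = seq(10, by = 15, length.out = 5))
  merged <- merge_candidates(chain, 15)
  expect_equal(nrow(merged), 1)
  expect_identical(merge_candidates(merged, 15), merged)
})

test_that("fixed-size images are truncated, rescaled and left-aligned", {
  set.seed(12)
  cfg <- segmentation_config()
  w <- synthesize_call(sample_trajectory(fixed_profile(duration = 150,
                                                       freq = 70)))
  sp <- sparsify(stft_magnitude(w, cfg), 70)
  cand <- tibble::tibble(start_frame = 1L, end_frame = ncol(sp$values))
  img <- to_fixed_image(sp, cand, cfg)
  expect_true(img$truncated)
  expect_equal(img$duration_ms, 100)
  expect_equal(img$occupied, round(100 * 100 / 233))  # 43
  expect_true(all(dim(img$image) == c(100, 100)))
  expect_true(all(img$image[, (img$occupied + 1):100] == 0))
  expect_true(max(img$image) == 255 && min(img$image) >= 0)

  zero <- sp
  zero$values[] <- 0
  z <- to_fixed_image(zero, cand, cfg)
  expect_true(all(z$image == 0))
  expect_error(to_fixed_image(sp, tibble::tibble(start_frame = 5L,
                                                 end_frame = 4L), cfg))
})

test_that("the criteria are order-insensitive independent predicates", {
  set.seed(13)
  profs <- default_profiles()
  specs <- lapply(1:8, function(i) sample_trajectory(profs[[1 + i %% 2]]))
  durs <- vapply(specs, function(s) s$duration_ms, numeric(1))
  rec <- render_recording(specs, schedule_calls(durs), snr_db = 25)
  cfg <- segmentation_config()
  spec <- sparsify(stft_magnitude(highpass(rec$waveform), cfg),
                   cfg$sparsify_percentile)
  cands <- find_candidates(energy_gate(spec, cfg$energy_quantile), spec)
  pc <- vapply(seq_len(nrow(cands)),
               function(i) continuity_gate(spec, cands[i, ]), logical(1))
  pf <- vapply(seq_len(nrow(cands)),
               function(i) frequency_gate(spec, cands[i, ]), logical(1))
  # both orders of filtering give the same accepted set
  expect_equal(which(pc & pf), which(pf & pc))
  expect_equal(cands[pc & pf, ], cands[pf & pc, ])
})

test_that("segmentation recovers scheduled calls and rejects low-frequency content", {
  set.seed(14)
  profs <- default_profiles()
  specs <- lapply(1:12, function(i) sample_trajectory(profs[[1 + i %% 2]]))
  durs <- vapply(specs, function(s) s$duration_ms, numeric(1))
  rec <- render_recording(specs, schedule_calls(durs), snr_db = 25)
  seg <- segment_recording(rec)
  sc <- segmentation_score(seg$segments, rec$annotations)
  expect_gte(sc$f1, 0.85)
  # no accepted segment has mean frequency below 25 kHz
  for (i in seq_len(nrow(seg$segments))) {
    expect_true(frequency_gate(seg$spectrogram, seg$segments[i, ], 25))
  }
  # determinism: identical input -> identical images
  seg2 <- segment_recording(rec)
  expect_identical(seg$images[[1]]$image, seg2$images[[1]]$image)
})
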