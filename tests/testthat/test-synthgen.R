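test_that("degenerate profiles produce the requested geometry and labels", {
  set.seed(1)
  tr <- sample_trajectory(fixed_profile(duration = 50, freq = 60))
  expect_s3_class(tr, "usv_trajectory")
  expect_equal(tr$duration_ms, 50)
  expect_equal(tr$labels$direction, 0L)
  expect_equal(tr$labels$n_breaks, 0L)
  expect_equal(tr$labels$broadband, 0)

  up <- sample_trajectory(fixed_profile(freq = 65, range = 30,
                                        direction = "up"))
  expect_equal(up$labels$direction, 1L)
  expect_equal(up$knots_khz[1], 50)
  expect_equal(up$knots_khz[2], 80)

  down <- sample_trajectory(fixed_profile(freq = 65, range = 30,
                                          direction = "down"))
  expect_equal(down$labels$direction, -1L)
})

test_that("sampled trajectories satisfy the domain invariants", {
  set.seed(2)
  profs <- default_profiles()
  for (i in 1:200) {
    tr <- sample_trajectory(profs[[1 + i %% 2]])
    expect_true(all(tr$knots_khz > 25 & tr$knots_khz <= 125))
    expect_true(tr$duration_ms >= 10 && tr$duration_ms <= 150)
    expect_equal(tr$labels$n_breaks, nrow(tr$gaps))
    net <- tr$knots_khz[length(tr$knots_khz)] - tr$knots_khz[1]
    if (abs(net) >= 1) expect_equal(tr$labels$direction, as.integer(sign(net)))
    if (nrow(tr$gaps)) expect_true(all(tr$gaps$len_ms >= 2))
  }
})

test_that("nonlinear profiles have class-matched marginals but a separating interaction", {
  set.seed(3)
  profs <- nonlinear_profiles()
  n <- 2000
  draw <- function(p) {
    t(vapply(seq_len(n), function(i) {
      tr <- sample_trajectory(p)
      c(duration = tr$duration_ms,
        f1 = mean(tr$path$f0_khz[1] + tr$path$f1_khz[1]) / 2,
        f2 = mean(tr$path$f0_khz[2] + tr$path$f1_khz[2]) / 2,
        mean_f = mean(tr$knots_khz))
    }, numeric(4)))
  }
  a <- draw(profs$A)
  b <- draw(profs$B)
  for (j in 1:4) {
    p <- wilcox.test(a[, j], b[, j])$p.value
    expect_gt(p, 0.01)
  }
  # the interaction (band agreement between the two halves) separates
  agree <- function(m) mean((m[, "f1"] > 72) == (m[, "f2"] > 72))
  expect_gt(agree(a), 0.95)
  expect_lt(agree(b), 0.05)
})

test_that("synthesized tones follow the requested trajectory", {
  set.seed(4)
  tr <- sample_trajectory(fixed_profile(duration = 50, freq = 60))
  w <- synthesize_call(tr)
  expect_length(w, 15000)
  sp <- stft_magnitude(w)
  peaks <- sp$freq_khz[apply(sp$values, 2, which.max)]
  expect_true(all(abs(peaks - 60) <= 0.6))

  # up-sweep 50 -> 80 kHz over 60 ms: sweep rate 0.5 kHz/ms +- 10%
  tr2 <- sample_trajectory(fixed_profile(duration = 60, freq = 65,
                                         range = 30, direction = "up"))
  sp2 <- stft_magnitude(synthesize_call(tr2))
  pk <- sp2$freq_khz[apply(sp2$values, 2, which.max)]
  fit <- coef(lm(pk ~ sp2$time_ms))[2]
  expect_lt(abs(fit - 0.5) / 0.5, 0.10)
})

test_that("break gaps are rendered as interior silence", {
  set.seed(5)
  tr <- sample_trajectory(fixed_profile(duration = 60, freq = 70,
                                        p_breaks = c(0, 1)))
  expect_equal(tr$labels$n_breaks, 1L)
  w <- synthesize_call(tr)
  a <- round(tr$gaps$start_ms[1] * 300) + 2
  b <- round((tr$gaps$start_ms[1] + tr$gaps$len_ms[1]) * 300) - 2
  expect_true(all(w[a:b] == 0))
  expect_gt(mean(w[1:(a - 200)]^2), 0)
})

test_that("aliasing trajectories are rejected", {
  tr <- sample_trajectory(fixed_profile(freq = 60))
  expect_error(synthesize_call(tr, sample_rate = 100000), "Nyquist")
})

test_that("rendered recordings honor the schedule and SNR contract", {
  set.seed(6)
  empty <- render_recording(list(), numeric(0), snr_db = 20,
                            duration_ms = 1000)
  expect_length(empty$waveform, 300000)
  expect_gt(sd(empty$waveform), 0)

  specs <- lapply(1:3, function(i) sample_trajectory(fixed_profile()))
  rec <- render_recording(specs, c(100, 300, 500), snr_db = 30)
  expect_equal(nrow(rec$annotations), 3)
  expect_equal(rec$annotations$onset_ms, c(100, 300, 500))

  expect_error(render_recording(specs, c(100, 120, 500)), "overlap")
})

test_that("noise floor matches the requested SNR", {
  set.seed(7)
  specs <- lapply(1:10, function(i) sample_trajectory(fixed_profile()))
  rec <- render_recording(specs, seq(100, by = 200, length.out = 10),
                          snr_db = 20, amplitude_jitter = c(1, 1))
  # noise-only tail
  tail_seg <- rec$waveform[(length(rec$waveform) - 5000):length(rec$waveform)]
  expect_equal(sd(tail_seg), rec$noise_sd, tolerance = 0.1)
})

test_that("labeled datasets are reproducible and honor imbalance", {
  set.seed(8)
  profs <- default_profiles()
  d1 <- make_labeled_dataset(profs, n_per_individual = 6,
                             n_individuals_per_class = 2, imbalance = 1.32)
  set.seed(8)
  d2 <- make_labeled_dataset(profs, n_per_individual = 6,
                             n_individuals_per_class = 2, imbalance = 1.32)
  expect_identical(d1$duration_ms, d2$duration_ms)
  expect_identical(d1$image[[5]], d2$image[[5]])
  counts <- table(d1$class)
  expect_equal(unname(counts["female"] / counts["male"]),
               1.32, tolerance = 0.15)
  expect_true(all(dim(d1$image[[1]]) == c(100, 100)))
  expect_true(max(d1$image[[1]]) <= 255 && min(d1$image[[1]]) >= 0)
})

test_that("WAV files round-trip", {
  set.seed(9)
  w <- runif(5000, -0.5, 0.5)
  f <- tempfile(fileext = ".wav")
  write_wav(w, f, sample_rate = 300000)
  rec <- read_wav(f)
  expect_equal(rec$sample_rate, 300000)
  expect_equal(rec$waveform, w, tolerance = 1e-4)
})
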