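#' Class-conditioned parameter profiles for synthetic USVs
#'
#' A profile describes the sampling distributions of every call parameter
#' for one emitter class (sex, strain or individual): duration, mean
#' frequency, frequency range, direction/peak/break usage, tremolo and
#' broadband content, and relative amplitude. Continuous parameters are
#' given as `c(mean, sd)` pairs; count-valued parameters as probability
#' vectors over 0, 1, 2, ... occurrences.
#'
#' With `nonlinear` set, class identity is carried by the *relation*
#' between the two halves of a two-part call rather than by any marginal:
#' each half is a sweep placed in a low or high frequency band (fair coin
#' for the first half), and the class determines only whether the second
#' half's band matches or crosses the first (`parity`). Every marginal
#' parameter distribution (durations, band membership, centre
#' frequencies, sweep directions and extents) is then identical across
#' classes; only the joint band configuration separates them. An optional
#' `duration_leak_ms` adds a small marginal duration shift on top (see
#' [surrogate_profiles()]).
#'
#' @param name Class label.
#' @param duration_ms,mean_freq_khz,freq_range_khz,break_gap_ms,
#'   tremolo_depth_khz,tremolo_rate_hz,broadband_khz `c(mean, sd)` pairs.
#' @param p_direction Probabilities of a descending / flat / ascending call
#'   (used when no peaks are drawn).
#' @param p_peaks,p_breaks Probability vectors over 0, 1, 2, ... peaks/breaks.
#' @param p_tremolo,p_broadband Bernoulli probabilities.
#' @param amplitude Mean relative amplitude of the class.
#' @param nonlinear `NULL`, or a list with `parity` (0 = second half's
#'   band matches the first, 1 = crossed), `half_dur` (`c(mean, sd)` ms
#'   per half), `bands` (list of two kHz ranges), `sweep` (`c(mean, sd)`
#'   sweep extent in kHz) and `duration_leak_ms` (marginal shift).
#' @return An object of class `usv_profile`.
#' @seealso [default_profiles()], [nonlinear_profiles()], [sample_trajectory()]
#' @export
usv_profile <- function(name,
                        duration_ms = c(60, 20),
                        mean_freq_khz = c(75, 10),
                        freq_range_khz = c(20, 8),
                        p_direction = c(down = 0.3, flat = 0.3, up = 0.4),
                        p_peaks = c(0.75, 0.18, 0.07),
                        p_breaks = c(0.65, 0.25, 0.10),
                        break_gap_ms = c(5, 2),
                        p_tremolo = 0.10,
                        tremolo_depth_khz = c(5, 1.5),
                        tremolo_rate_hz = c(80, 20),
                        p_broadband = 0.2,
                        broadband_khz = c(10, 3),
                        amplitude = 1,
                        nonlinear = NULL) {
  stopifnot(length(duration_ms) == 2, length(mean_freq_khz) == 2,
            abs(sum(p_direction) - 1) < 1e-8,
            abs(sum(p_peaks) - 1) < 1e-8, abs(sum(p_breaks) - 1) < 1e-8)
  structure(
    list(name = name, duration_ms = duration_ms,
         mean_freq_khz = mean_freq_khz, freq_range_khz = freq_range_khz,
         p_direction = p_direction, p_peaks = p_peaks, p_breaks = p_breaks,
         break_gap_ms = break_gap_ms, p_tremolo = p_tremolo,
         tremolo_depth_khz = tremolo_depth_khz,
         tremolo_rate_hz = tremolo_rate_hz, p_broadband = p_broadband,
         broadband_khz = broadband_khz, amplitude = amplitude,
         nonlinear = nonlinear),
    class = "usv_profile")
}

#' Default female/male profiles
#'
#' Two profiles whose class differences follow the qualitative directions
#' reported for C57BL/6 mice: males tend towards shorter calls with lower
#' mean frequency, a wider frequency range and more broadband content;
#' females towards longer, slightly higher calls. `effect` scales every
#' between-class shift (0 = identical classes).
#'
#' @param effect Multiplier on all between-class mean shifts.
#' @return Named list of two [usv_profile()] objects.
#' @export
default_profiles <- function(effect = 1) {
  list(
    female = usv_profile(
      "female",
      duration_ms = c(60 + 8 * effect, 20),
      mean_freq_khz = c(75 + 3 * effect, 10),
      freq_range_khz = c(22 - 4 * effect, 8),
      p_broadband = clamp(0.25 - 0.10 * effect, 0, 1),
      amplitude = 1 + 0.08 * effect),
    male = usv_profile(
      "male",
      duration_ms = c(60 - 8 * effect, 20),
      mean_freq_khz = c(75 - 3 * effect, 10),
      freq_range_khz = c(22 + 4 * effect, 8),
      p_broadband = clamp(0.25 + 0.10 * effect, 0, 1),
      amplitude = 1 - 0.08 * effect)
  )
}

#' Profiles whose class signal is a nonlinear feature combination
#'
#' `nonlinear_profiles()`: both classes share identical marginal
#' distributions for every call parameter; class identity is carried only
#' by the *parity* of the two halves' frequency bands (matched vs
#' crossed). No single parameter - and no single time-frequency bin of
#' the rendered image - separates the classes; only the joint
#' configuration of the two call parts does, which requires an
#' interaction-sensitive classifier.
#'
#' `surrogate_profiles()` layers a small marginal duration shift
#' (6 ms against a per-call duration spread of roughly 8 ms) on top of
#' the parity signal, so that a linear classifier sits just above chance
#' while nonlinear classifiers can exploit the dominant interaction -
#' the qualitative regime reported for real spectrogram-based sex
#' classification.
#'
#' @param half_dur `c(mean, sd)` of each half's duration (ms).
#' @param bands List of two `c(lo, hi)` kHz ranges the per-half centre
#'   frequencies are drawn from.
#' @param sweep `c(mean, sd)` of the sweep extent (kHz).
#' @param duration_leak_ms Added to class A's half durations.
#' @return Named list of two [usv_profile()] objects (`A` = repeated
#'   direction, `B` = mirrored).
#' @export
nonlinear_profiles <- function(half_dur = c(30, 6),
                               bands = list(low = c(40, 60),
                                            high = c(85, 105)),
                               sweep = c(25, 5),
                               duration_leak_ms = 0) {
  base <- function(name, parity, leak) {
    usv_profile(
      name,
      p_peaks = c(1), p_breaks = c(1), p_tremolo = 0, p_broadband = 0,
      nonlinear = list(parity = parity, half_dur = half_dur,
                       bands = bands, sweep = sweep,
                       duration_leak_ms = leak))
  }
  list(A = base("A", 0L, duration_leak_ms), B = base("B", 1L, 0))
}

#' @rdname nonlinear_profiles
#' @export
surrogate_profiles <- function(duration_leak_ms = 6) {
  nonlinear_profiles(duration_leak_ms = duration_leak_ms)
}

rnorm2 <- function(p) stats::rnorm(1, p[1], p[2])

#' Sample a call trajectory from a class profile
#'
#' Draws one frequency-modulated call specification: a piecewise
#' (flat/up/down, optionally sinusoidally modulated) trajectory in the
#' 25-125 kHz band, 10-150 ms long, with optional silent breaks and
#' broadband content. Ground-truth labels (direction, peaks, breaks,
#' broadband, tremolo, complexity) are derived deterministically from the
#' sampled geometry. Uses R's RNG; seed with [set.seed()].
#'
#' @param profile An [usv_profile()].
#' @return An object of class `usv_trajectory`: fields `duration_ms`,
#'   `knots_khz` (trajectory control points), `segments` (tibble with
#'   `shape`, `start_freq`, `end_freq`, `tremolo_depth`, `tremolo_rate`),
#'   `gaps` (tibble of silent intervals), `broadband_khz`, `amplitude` and
#'   `labels`.
#' @export
sample_trajectory <- function(profile) {
  if (!inherits(profile, "usv_profile")) stop("`profile` must be an usv_profile")
  nl <- profile$nonlinear
  if (!is.null(nl)) return(sample_trajectory_nonlinear(profile, nl))
  duration <- rnorm2(profile$duration_ms)
  f_mean <- rnorm2(profile$mean_freq_khz)
  duration <- clamp(duration, 10, 150)
  f_mean <- clamp(f_mean, 30, 115)
  f_range <- clamp(rnorm2(profile$freq_range_khz), 0, 60)

  n_peaks <- sample.int(length(profile$p_peaks), 1L, prob = profile$p_peaks) - 1L
  if (n_peaks > 0L) {
    f_range <- max(f_range, 8)
    lo <- clamp(f_mean - f_range / 2, 26, 120)
    hi <- clamp(f_mean + f_range / 2, lo + 8, 124)
    knots <- c(lo, rep(c(hi, lo), n_peaks))
  } else {
    dir_draw <- sample.int(3L, 1L, prob = profile$p_direction) - 2L  # -1/0/1
    if (dir_draw == 0L || f_range < 2) {
      knots <- c(f_mean, f_mean)
    } else {
      f_range <- max(f_range, 3)
      a <- clamp(f_mean - f_range / 2, 26, 124)
      b <- clamp(f_mean + f_range / 2, 26, 124)
      knots <- if (dir_draw > 0) c(a, b) else c(b, a)
    }
  }

  tremolo <- stats::runif(1) < profile$p_tremolo
  trem_depth <- if (tremolo) clamp(rnorm2(profile$tremolo_depth_khz), 2, 10) else 0
  trem_rate <- if (tremolo) clamp(rnorm2(profile$tremolo_rate_hz), 40, 160) else 0

  broadband <- stats::runif(1) < profile$p_broadband
  bb_width <- if (broadband) clamp(rnorm2(profile$broadband_khz), 4, 25) else 0

  n_breaks <- sample.int(length(profile$p_breaks), 1L, prob = profile$p_breaks) - 1L
  # a call must keep >= 4 ms of voiced signal between break gaps
  max_breaks <- max(0L, floor((duration - 4) / (2 + 4)))
  n_breaks <- min(n_breaks, max_breaks)
  gaps <- tibble::tibble(start_ms = numeric(0), len_ms = numeric(0))
  if (n_breaks > 0L) {
    centers <- (seq_len(n_breaks) / (n_breaks + 1)) * duration
    centers <- centers + stats::runif(n_breaks, -0.05, 0.05) * duration
    lens <- clamp(stats::rnorm(n_breaks, profile$break_gap_ms[1],
                               profile$break_gap_ms[2]), 2, 12)
    start <- clamp(centers - lens / 2, 2, duration - lens - 2)
    gaps <- tibble::tibble(start_ms = start, len_ms = lens)
  }

  nseg <- length(knots) - 1L
  seg_shape <- ifelse(abs(diff(knots)) < 1e-9, "flat",
                      ifelse(diff(knots) > 0, "up", "down"))
  if (tremolo) seg_shape[] <- "sinusoidal"
  segments <- tibble::tibble(
    shape = seg_shape,
    start_freq = knots[-length(knots)],
    end_freq = knots[-1],
    tremolo_depth = trem_depth,
    tremolo_rate = trem_rate)

  net <- knots[length(knots)] - knots[1]
  labels <- list(
    direction = if (abs(net) < 1) 0L else as.integer(sign(net)),
    n_peaks = n_peaks,
    n_breaks = nrow(gaps),
    broadband = as.numeric(broadband),
    tremolo = as.numeric(tremolo),
    complex = clamp((n_peaks + nrow(gaps)) / 4 +
                      0.25 * tremolo + 0.25 * broadband, 0, 1))

  amp <- max(profile$amplitude, 0.05)
  knot_t <- seq(0, duration, length.out = length(knots))
  path <- tibble::tibble(
    t0_ms = knot_t[-length(knot_t)], t1_ms = knot_t[-1],
    f0_khz = knots[-length(knots)], f1_khz = knots[-1])
  structure(
    list(duration_ms = duration, knots_khz = knots, segments = segments,
         path = path, gaps = gaps, broadband_khz = bb_width, amplitude = amp,
         labels = labels),
    class = "usv_trajectory")
}

# two-part call whose class is the parity of the two halves' frequency
# bands (matched vs crossed); every marginal parameter - half durations,
# per-half band membership, centre frequencies, sweep directions and
# extents - is class-balanced by construction, so only the joint
# configuration of the two parts carries class information
sample_trajectory_nonlinear <- function(profile, nl) {
  d1 <- clamp(stats::rnorm(1, nl$half_dur[1], nl$half_dur[2]), 12, 70) +
    nl$duration_leak_ms / 2
  d2 <- clamp(stats::rnorm(1, nl$half_dur[1], nl$half_dur[2]), 12, 70) +
    nl$duration_leak_ms / 2
  band1 <- sample.int(2L, 1L)
  band2 <- if (nl$parity == 0L) band1 else 3L - band1
  mk <- function(band) {
    dir <- sample(c(-1, 1), 1)
    centre <- stats::runif(1, nl$bands[[band]][1], nl$bands[[band]][2])
    ext <- clamp(stats::rnorm(1, nl$sweep[1], nl$sweep[2]), 10, 40)
    f0 <- clamp(centre - dir * ext / 2, 27, 123)
    f1 <- clamp(centre + dir * ext / 2, 27, 123)
    c(f0, f1)
  }
  s1 <- mk(band1)
  s2 <- mk(band2)
  path <- tibble::tibble(
    t0_ms = c(0, d1), t1_ms = c(d1, d1 + d2),
    f0_khz = c(s1[1], s2[1]), f1_khz = c(s1[2], s2[2]))
  segments <- tibble::tibble(
    shape = ifelse(path$f1_khz >= path$f0_khz, "up", "down"),
    start_freq = path$f0_khz, end_freq = path$f1_khz,
    tremolo_depth = 0, tremolo_rate = 0)
  knots <- c(s1, s2)
  net <- s2[2] - s1[1]
  labels <- list(
    direction = if (abs(net) < 1) 0L else as.integer(sign(net)),
    n_peaks = 0L, n_breaks = 0L, broadband = 0, tremolo = 0, complex = 0.5)
  structure(
    list(duration_ms = d1 + d2, knots_khz = knots, segments = segments,
         path = path, gaps = tibble::tibble(start_ms = numeric(0),
                                            len_ms = numeric(0)),
         broadband_khz = 0, amplitude = max(profile$amplitude, 0.05),
         labels = labels),
    class = "usv_trajectory")
}

#' Synthesize the waveform of one call
#'
#' Renders a phase-continuous frequency-modulated tone following the
#' trajectory, inserts silence at break gaps (with short tapers), and
#' realizes broadband content by amplitude-modulating the carrier with
#' low-pass noise, which spreads energy into a band of the requested width
#' around the instantaneous frequency.
#'
#' @param spec An `usv_trajectory` from [sample_trajectory()].
#' @param sample_rate Samples per second; must exceed twice the maximum
#'   instantaneous frequency.
#' @return Numeric waveform of `round(duration_ms * sample_rate / 1000)`
#'   samples.
#' @export
synthesize_call <- function(spec, sample_rate = USV_SAMPLE_RATE) {
  stopifnot(inherits(spec, "usv_trajectory"))
  n <- round(spec$duration_ms * sample_rate / 1000)
  t_ms <- (seq_len(n) - 1) / sample_rate * 1000
  # piecewise-linear instantaneous frequency; the path may be
  # discontinuous between consecutive pieces (two-part calls)
  f_khz <- numeric(n)
  path <- spec$path
  for (i in seq_len(nrow(path))) {
    sel <- t_ms >= path$t0_ms[i] & (t_ms < path$t1_ms[i] | i == nrow(path))
    span <- max(path$t1_ms[i] - path$t0_ms[i], 1e-9)
    u <- (t_ms[sel] - path$t0_ms[i]) / span
    f_khz[sel] <- path$f0_khz[i] + u * (path$f1_khz[i] - path$f0_khz[i])
  }
  trem <- spec$segments$tremolo_depth[1]
  if (trem > 0) {
    f_khz <- f_khz + trem * sin(2 * pi * spec$segments$tremolo_rate[1] *
                                  t_ms / 1000)
  }
  f_max <- max(f_khz) * 1000 + spec$broadband_khz * 1000 / 2
  if (f_max >= sample_rate / 2) {
    stop("trajectory reaches ", round(f_max / 1000, 1),
         " kHz, at or above Nyquist (", sample_rate / 2000, " kHz)")
  }
  phase <- 2 * pi * cumsum(f_khz * 1000) / sample_rate
  wave <- sin(phase)
  if (spec$broadband_khz > 0) {
    m <- lowpass_noise(n, cutoff_hz = spec$broadband_khz * 1000 / 2,
                       sample_rate = sample_rate)
    wave <- wave * (1 + 1.2 * m)
  }
  # onset/offset tapers (1 ms) against spectral splatter
  ramp <- min(round(sample_rate / 1000), floor(n / 2))
  env <- rep(1, n)
  env[seq_len(ramp)] <- seq(0, 1, length.out = ramp)
  env[n - seq_len(ramp) + 1] <- seq(0, 1, length.out = ramp)
  wave <- wave * env
  # silent break gaps with 0.3 ms tapers
  if (nrow(spec$gaps) > 0) {
    tap <- max(2L, round(0.3 * sample_rate / 1000))
    for (i in seq_len(nrow(spec$gaps))) {
      a <- max(1L, round(spec$gaps$start_ms[i] * sample_rate / 1000))
      b <- min(n, round((spec$gaps$start_ms[i] + spec$gaps$len_ms[i]) *
                          sample_rate / 1000))
      wave[a:b] <- 0
      pre <- max(1L, a - tap):max(1L, a - 1L)
      post <- min(n, b + 1L):min(n, b + tap)
      wave[pre] <- wave[pre] * seq(1, 0, length.out = length(pre))
      wave[post] <- wave[post] * seq(0, 1, length.out = length(post))
    }
  }
  0.3 * spec$amplitude * wave
}

# white noise low-passed by FFT masking; unit standard deviation
lowpass_noise <- function(n, cutoff_hz, sample_rate) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) / n * sample_rate
  freqs <- pmin(freqs, sample_rate - freqs)
  X[freqs > cutoff_hz] <- 0
  m <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(m)
  if (s > 0) m / s else m
}

#' Render a recording of scheduled calls over a noise floor
#'
#' Places synthesized calls at the scheduled onsets in a continuous
#' waveform and adds white Gaussian background noise at the requested
#' signal-to-noise ratio relative to the mean call power. Call amplitudes
#' are additionally jittered by a uniform `[0.5, 1.5]` factor, emulating
#' uncontrolled mouse-microphone distance.
#'
#' @param specs List of `usv_trajectory` objects.
#' @param onsets_ms Call onsets (ms); scheduled calls must not overlap.
#' @param snr_db Signal-to-noise ratio in dB (mean call power over noise
#'   power). `Inf` renders a noiseless recording.
#' @param duration_ms Total duration; defaults to last offset + 50 ms.
#' @param sample_rate Samples per second.
#' @param labels Optional tibble of per-call metadata (e.g. class,
#'   individual) bound onto the annotation table.
#' @param amplitude_jitter Range of the per-call amplitude factor.
#' @return An object of class `usv_recording`: `waveform`, `sample_rate`,
#'   `snr_db` and an `annotations` tibble (onset/offset/duration in ms plus
#'   the trajectory ground-truth labels).
#' @export
render_recording <- function(specs, onsets_ms, snr_db = 20,
                             duration_ms = NULL,
                             sample_rate = USV_SAMPLE_RATE,
                             labels = NULL,
                             amplitude_jitter = c(0.5, 1.5)) {
  stopifnot(length(specs) == length(onsets_ms))
  ord <- order(onsets_ms)
  specs <- specs[ord]
  onsets_ms <- onsets_ms[ord]
  if (!is.null(labels)) labels <- labels[ord, , drop = FALSE]
  durs <- vapply(specs, function(s) s$duration_ms, numeric(1))
  offs <- onsets_ms + durs
  if (length(onsets_ms) > 1 && any(onsets_ms[-1] < offs[-length(offs)])) {
    stop("scheduled calls overlap")
  }
  total_ms <- duration_ms %||% (if (length(offs)) max(offs) + 50 else 1000)
  if (length(offs) && total_ms < max(offs)) stop("recording shorter than schedule")
  n <- round(total_ms * sample_rate / 1000)
  wave <- numeric(n)
  powers <- numeric(length(specs))
  for (i in seq_along(specs)) {
    w <- synthesize_call(specs[[i]], sample_rate)
    w <- w * stats::runif(1, amplitude_jitter[1], amplitude_jitter[2])
    a <- round(onsets_ms[i] * sample_rate / 1000) + 1L
    b <- a + length(w) - 1L
    wave[a:b] <- wave[a:b] + w
    powers[i] <- mean(w^2)
  }
  noise_sd <- 0
  if (is.finite(snr_db)) {
    p_call <- if (length(powers)) mean(powers) else 1e-4
    noise_sd <- sqrt(p_call / 10^(snr_db / 10))
    wave <- wave + stats::rnorm(n, sd = noise_sd)
  }
  ann <- tibble::tibble(
    call = seq_along(specs),
    onset_ms = onsets_ms,
    offset_ms = offs,
    duration_ms = durs,
    direction = vapply(specs, function(s) s$labels$direction, integer(1)),
    n_peaks = vapply(specs, function(s) s$labels$n_peaks, integer(1)),
    n_breaks = vapply(specs, function(s) s$labels$n_breaks, integer(1)),
    broadband = vapply(specs, function(s) s$labels$broadband, numeric(1)),
    tremolo = vapply(specs, function(s) s$labels$tremolo, numeric(1)),
    complex = vapply(specs, function(s) s$labels$complex, numeric(1)))
  if (!is.null(labels)) ann <- dplyr::bind_cols(ann, tibble::as_tibble(labels))
  structure(
    list(waveform = wave, sample_rate = sample_rate, snr_db = snr_db,
         noise_sd = noise_sd, annotations = ann, specs = specs),
    class = "usv_recording")
}

#' Schedule non-overlapping call onsets
#'
#' @param durations_ms Call durations.
#' @param gap_range_ms Uniform range of silent gaps between consecutive
#'   calls; the default reproduces a calling rate of roughly three calls
#'   per second. The lower bound should exceed the 15 ms merge gap if the
#'   calls are meant to stay separate.
#' @return Vector of onsets (ms).
#' @export
schedule_calls <- function(durations_ms, gap_range_ms = c(150, 450)) {
  gaps <- stats::runif(length(durations_ms), gap_range_ms[1], gap_range_ms[2])
  onsets <- cumsum(c(gaps[1], head(durations_ms, -1) + gaps[-1]))
  onsets
}

#' Generate a labeled dataset of call images with ground truth
#'
#' Draws `n_per_individual` calls for each of `n_individuals_per_class`
#' synthetic individuals per class, synthesizes each call, and converts it
#' to the fixed 100 x 100 uint8 image representation used by the
#' classifiers. Per-call ground-truth labels and basic parameters are
#' returned alongside. Fully reproducible under [set.seed()].
#'
#' @param profiles Named list of [usv_profile()] objects (one per class).
#' @param n_per_individual Calls per individual (first class; others are
#'   scaled by `imbalance`).
#' @param n_individuals_per_class Integer (recycled across classes).
#' @param imbalance Ratio of first-class to other-class call counts
#'   (e.g. 1.32 for 32% more first-class calls).
#' @param snr_db Per-call SNR used when adding background noise to each
#'   call snippet; `Inf` for noiseless images.
#' @param config A [segmentation_config()] controlling the spectrogram and
#'   image geometry.
#' @return A tibble with one row per call: `class`, `individual`,
#'   ground-truth trajectory labels and parameters, and list-columns
#'   `image` (100 x 100 matrices, values 0-255) and `spec`.
#' @export
make_labeled_dataset <- function(profiles, n_per_individual = 50,
                                 n_individuals_per_class = 2,
                                 imbalance = 1, snr_db = Inf,
                                 config = segmentation_config()) {
  stopifnot(length(profiles) >= 1, n_per_individual >= 1)
  classes <- names(profiles)
  if (is.null(classes)) classes <- vapply(profiles, function(p) p$name, "")
  n_ind <- rep_len(n_individuals_per_class, length(profiles))
  rows <- list()
  for (ci in seq_along(profiles)) {
    n_calls <- if (ci == 1) n_per_individual else
      max(1L, round(n_per_individual / imbalance))
    for (ii in seq_len(n_ind[ci])) {
      ind_id <- paste0(classes[ci], "_", ii)
      for (k in seq_len(n_calls)) {
        spec <- sample_trajectory(profiles[[ci]])
        wave <- synthesize_call(spec)
        if (is.finite(snr_db)) {
          wave <- wave + stats::rnorm(length(wave),
                                      sd = sqrt(mean(wave^2) / 10^(snr_db / 10)))
        }
        img <- call_image(wave, config)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          class = classes[ci], individual = ind_id,
          duration_ms = spec$duration_ms,
          mean_freq_khz = with(spec$path, sum((t1_ms - t0_ms) *
            (f0_khz + f1_khz) / 2) / sum(t1_ms - t0_ms)),
          freq_range_khz = diff(range(spec$knots_khz)),
          direction = spec$labels$direction,
          n_peaks = spec$labels$n_peaks,
          n_breaks = spec$labels$n_breaks,
          broadband = spec$labels$broadband,
          tremolo = spec$labels$tremolo,
          complex = spec$labels$complex,
          amplitude = spec$amplitude,
          image = list(img$image),
          spec = list(spec))
      }
    }
  }
  dplyr::bind_rows(rows)
}
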