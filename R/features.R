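#' Curvature-flow denoising
#'
#' Smooths a spectrogram patch with a level-set min/max curvature flow:
#' isolated speckle (high level-line curvature in every direction) erodes
#' within a few iterations while the call's extended spectral ridge, flat
#' along its length, is left nearly unchanged.
#'
#' @param spec An `usv_spectrogram` or non-negative matrix.
#' @param iterations Number of flow steps.
#' @param dt Time step.
#' @param minmax Use the min/max switch (pixels brighter than their
#'   surroundings may only erode, darker only fill); `FALSE` gives plain
#'   curvature flow.
#' @return Same type as `spec`.
#' @export
denoise_curvature_flow <- function(spec, iterations = 10, dt = 0.075,
                                   minmax = TRUE) {
  v <- spec_values(spec)
  if (any(v < 0)) stop("spectrogram values must be non-negative")
  set_spec_values(spec, curvature_flow_cpp(v, iterations, dt, minmax))
}

# Prewitt gradient-magnitude edge map; threshold follows the usual
# convention of a fixed multiple of the mean gradient magnitude
prewitt_edges <- function(v, threshold = NULL) {
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 3 || nc < 3) return(matrix(FALSE, nr, nc))
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- v
  p[1, ] <- p[2, ]; p[nr + 2, ] <- p[nr + 1, ]
  p[, 1] <- p[, 2]; p[, nc + 2] <- p[, nc + 1]
  sub <- function(di, dj) p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  gx <- (sub(-1, 1) + sub(0, 1) + sub(1, 1)) -
    (sub(-1, -1) + sub(0, -1) + sub(1, -1))
  gy <- (sub(1, -1) + sub(1, 0) + sub(1, 1)) -
    (sub(-1, -1) + sub(-1, 0) + sub(-1, 1))
  g <- sqrt(gx^2 + gy^2)
  thr <- threshold %||% (4 * mean(g))
  g > thr
}

#' Fundamental-frequency track
#'
#' Locates the call's fundamental line in a (denoised) spectrogram patch.
#' A Prewitt edge map delimits the temporal range to frames containing at
#' least one background-to-sound transition; within that range the
#' fundamental frequency FF(t) of an edge-bearing frame is the frequency
#' of the bin with maximal amplitude, frames without an edge between two
#' edge-bearing frames are marked as breaks (FF = 0), and a single-frame
#' value differing by more than 5 kHz from both voiced neighbours is
#' replaced by their interpolation. The fundamental energy FE(t) is the
#' patch value at FF(t) wherever FF(t) > 0. Only the band above
#' `min_freq_khz` is considered, since mouse USVs essentially never occur
#' (or show harmonics) below it.
#'
#' @param spec An `usv_spectrogram` (patch) or matrix (then `freq_khz`
#'   must be supplied).
#' @param freq_khz Frequency axis for bare matrices.
#' @param min_freq_khz Lower band edge.
#' @param edge_threshold Optional fixed edge threshold (default: four
#'   times the mean gradient magnitude).
#' @param min_frame_frac A frame is voiced only if its peak magnitude is
#'   at least this fraction of the strongest frame's peak; excludes
#'   silent gap frames whose edge-bearing onset/offset transients would
#'   otherwise be tracked at arbitrary frequencies.
#' @return An object of class `fundamental_track`: `ff_khz` (0 marks a
#'   break), `fe` (energy at the fundamental; `NA` at breaks), `frames`
#'   (patch frame indices spanned), `frame_period_ms`.
#' @export
extract_fundamental <- function(spec, freq_khz = NULL, min_freq_khz = 25,
                                edge_threshold = NULL,
                                min_frame_frac = 0.01) {
  v <- spec_values(spec)
  if (is.null(freq_khz)) {
    freq_khz <- if (inherits(spec, "usv_spectrogram")) spec$freq_khz else
      stop("`freq_khz` required for a bare matrix")
  }
  fp <- if (inherits(spec, "usv_spectrogram")) spec$frame_period_ms else 1 / 1.2
  band <- freq_khz > min_freq_khz
  vb <- v[band, , drop = FALSE]
  fb <- freq_khz[band]
  edges <- prewitt_edges(vb, edge_threshold)
  fmax <- apply(vb, 2, max)
  has_edge <- apply(edges, 2, any) & fmax >= min_frame_frac * max(fmax)
  if (!any(has_edge)) stop("no edges found: empty track")
  t1 <- which(has_edge)[1]
  t2 <- rev(which(has_edge))[1]
  idx <- t1:t2
  ff <- numeric(length(idx))
  fe <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    t <- idx[k]
    if (has_edge[t]) {
      r <- which.max(vb[, t])
      ff[k] <- fb[r]
      fe[k] <- vb[r, t]
    }                     # else break frame: ff stays 0
  }
  # single-frame outlier replacement (one pass)
  if (length(ff) >= 3) {
    for (k in 2:(length(ff) - 1)) {
      if (ff[k] > 0 && ff[k - 1] > 0 && ff[k + 1] > 0 &&
          abs(ff[k] - ff[k - 1]) > 5 && abs(ff[k] - ff[k + 1]) > 5) {
        ff[k] <- (ff[k - 1] + ff[k + 1]) / 2
        fe[k] <- (fe[k - 1] + fe[k + 1]) / 2
      }
    }
  }
  structure(list(ff_khz = ff, fe = fe, frames = idx, frame_period_ms = fp),
            class = "fundamental_track")
}

#' @export
print.fundamental_track <- function(x, ...) {
  cat("fundamental_track: ", length(x$ff_khz), " frames, ",
      sum(x$ff_khz > 0), " voiced, ", n_breaks(x), " break(s)\n", sep = "")
  invisible(x)
}

#' Count breaks and peaks of a fundamental track
#'
#' Breaks are contiguous runs of at least `min_frames` unvoiced frames
#' (FF = 0) inside the track - genuine gaps span at least 2 ms, i.e.
#' more than two frames, while a single dropped frame is amplitude
#' flicker. Peaks are interior local maxima of the voiced fundamental
#' with at least `prominence_khz` drop on both sides.
#'
#' @param track A `fundamental_track`.
#' @param min_frames Minimum run length counted as a break.
#' @param prominence_khz Minimum prominence of a counted peak.
#' @return Integer count.
#' @export
n_breaks <- function(track, min_frames = 2L) {
  r <- rle(track$ff_khz == 0)
  sum(r$values & r$lengths >= min_frames)
}

#' @rdname n_breaks
#' @export
n_peaks <- function(track, prominence_khz = 3) {
  ff <- track$ff_khz[track$ff_khz > 0]
  n <- length(ff)
  if (n < 3) return(0L)
  count <- 0L
  k <- 2L
  while (k < n) {
    if (ff[k] >= ff[k - 1] && ff[k] >= ff[k + 1]) {
      left <- max(ff[k] - min(ff[1:k]), 0)
      right <- max(ff[k] - min(ff[k:n]), 0)
      if (min(left, right) >= prominence_khz) {
        count <- count + 1L
        # skip to the next valley so a plateau counts once
        j <- k + 1L
        while (j < n && ff[j] >= ff[j + 1]) j <- j + 1L
        k <- j
      }
    }
    k <- k + 1L
  }
  count
}

#' Spectral marginal of a call
#'
#' Temporal average of the fundamental energy per frequency bin: each
#' voiced frame contributes FE(t) to the bin containing FF(t), and the
#' accumulated energy is divided by the number of voiced frames. Returned
#' on the full fixed 233-bin axis so calls are comparable.
#'
#' @param track A `fundamental_track`.
#' @param freq_khz The 233-bin frequency axis the marginal lives on.
#' @return Numeric vector of length 233.
#' @export
spectral_marginal <- function(track, freq_khz = usv_freq_axis()) {
  out <- numeric(length(freq_khz))
  voiced <- which(track$ff_khz > 0)
  if (!length(voiced)) return(out)
  for (t in voiced) {
    b <- which.min(abs(freq_khz - track$ff_khz[t]))
    out[b] <- out[b] + track$fe[t]
  }
  out / length(voiced)
}

#' The fixed 233-bin frequency axis (10.8-150 kHz, 600 Hz spacing)
#' @export
usv_freq_axis <- function() {
  n_bins <- USV_WIN_LEN %/% 2L + 1L
  ((n_bins - USV_N_FREQ):(n_bins - 1L)) * (USV_SAMPLE_RATE / USV_WIN_LEN / 1000)
}

#' Wiener entropy (spectral flatness)
#'
#' Per frame, the ratio of the geometric to the arithmetic mean of the
#' spectral magnitudes (1 for a flat, noise-like spectrum; 0 whenever any
#' bin of the support is zero, as for a pure tone on a sparsified
#' spectrogram); the temporal average over non-empty frames is returned.
#'
#' @param spec Matrix or `usv_spectrogram` (columns = frames).
#' @return Scalar in `[0, 1]`.
#' @export
wiener_entropy <- function(spec) {
  v <- spec_values(spec)
  per_frame <- apply(v, 2, function(x) {
    if (all(x == 0)) return(NA_real_)
    g <- if (any(x == 0)) 0 else exp(mean(log(x)))
    g / mean(x)
  })
  mean(per_frame, na.rm = TRUE)
}

#' Spectral salience
#'
#' Per frame, the ratio between the largest off-zero peak and the zero-lag
#' peak of the across-frequency autocorrelation (mean-centred, so flat or
#' aperiodic spectra score near zero); the temporal average over non-empty
#' frames is returned. High values indicate periodic spectral structure.
#'
#' @param spec Matrix or `usv_spectrogram`.
#' @return Scalar `<= 1`.
#' @export
spectral_salience <- function(spec) {
  v <- spec_values(spec)
  if (nrow(v) < 2) stop("need at least 2 frequency bins")
  per_frame <- apply(v, 2, function(x) {
    if (all(x == 0)) return(NA_real_)
    salience_ratio(x)
  })
  mean(per_frame, na.rm = TRUE)
}

#' Tremolo score
#'
#' Applies the salience estimate to the voiced fundamental-frequency
#' sequence FF(t): a sinusoidally modulated fundamental produces a strong
#' off-zero autocorrelation peak at the modulation period. FF is
#' mean-centred before autocorrelation, so a constant fundamental scores
#' exactly 0.
#'
#' @param track A `fundamental_track`.
#' @return Scalar, or `NA` for tracks with fewer than 4 voiced frames.
#' @export
tremolo_score <- function(track) {
  ff <- track$ff_khz[track$ff_khz > 0]
  if (length(ff) < 4) return(NA_real_)
  salience_ratio(ff)
}

#' Spectral purity
#'
#' Temporal average of the per-frame ratio of the maximal to the median
#' spectral magnitude; at least 1, and large for narrow-band tonal calls.
#' Frames whose median is zero (typical after sparsification) use the
#' smallest positive value of the frame as the denominator floor.
#'
#' @param spec Matrix or `usv_spectrogram`.
#' @return Scalar `>= 1`.
#' @export
spectral_purity <- function(spec) {
  v <- spec_values(spec)
  per_frame <- apply(v, 2, function(x) {
    if (all(x == 0)) return(NA_real_)
    med <- stats::median(x)
    if (med <= 0) med <- min(x[x > 0])
    max(x) / med
  })
  mean(per_frame, na.rm = TRUE)
}

#' Automatic scalar features of one call
#'
#' The 18 automatic single-value properties: spectral width
#' `max(FF) - min(FF)`, duration (first to last frame of the spectral
#' line, breaks included), start/end/min/max frequency, the two mean-
#' frequency estimates (mean of the voiced FF, and the intensity-weighted
#' average over the raw spectrogram), skewness and kurtosis of FE(t) and
#' of the spectral marginal, direction (sign of the mean single-step FF
#' difference over voiced frames), Wiener entropy, spectral salience,
#' tremolo, mean fundamental energy, and spectral purity.
#'
#' @param track A `fundamental_track`.
#' @param spec The spectrogram patch the track was extracted from.
#' @param sample_moments Use sample instead of population moments.
#' @return One-row tibble with 18 columns.
#' @export
scalar_features <- function(track, spec, sample_moments = FALSE) {
  v <- spec_values(spec)
  freq <- if (inherits(spec, "usv_spectrogram")) spec$freq_khz else
    usv_freq_axis()[seq_len(nrow(v))]
  ff <- track$ff_khz
  voiced <- ff > 0
  ffv <- ff[voiced]
  fev <- track$fe[voiced]
  T_frames <- length(ff)
  marg <- spectral_marginal(track, freq)
  csum <- colSums(v)
  ok <- csum > 0
  mean_w <- if (any(ok)) {
    mean(colSums(v[, ok, drop = FALSE] * freq) / csum[ok])
  } else NA_real_
  # sign of the mean single-step difference; a dead zone of 0.1 kHz
  # absorbs frequency-bin quantization jitter on flat or symmetric calls
  dirv <- if (length(ffv) >= 2) {
    m <- mean(diff(ffv))
    if (abs(m) < 0.1) 0L else as.integer(sign(m))
  } else 0L
  degenerate <- length(fev) < 2
  tibble::tibble(
    duration_ms = T_frames * track$frame_period_ms,
    spectral_width_khz = if (length(ffv)) max(ffv) - min(ffv) else NA_real_,
    start_freq_khz = if (length(ffv)) ffv[1] else NA_real_,
    end_freq_khz = if (length(ffv)) ffv[length(ffv)] else NA_real_,
    min_freq_khz = if (length(ffv)) min(ffv) else NA_real_,
    max_freq_khz = if (length(ffv)) max(ffv) else NA_real_,
    mean_freq_ff_khz = if (length(ffv)) mean(ffv) else NA_real_,
    mean_freq_weighted_khz = mean_w,
    temporal_skewness = if (degenerate) NA_real_ else
      moment_skewness(fev, sample_moments),
    temporal_kurtosis = if (degenerate) NA_real_ else
      moment_kurtosis(fev, sample_moments),
    spectral_skewness = moment_skewness(marg, sample_moments),
    spectral_kurtosis = moment_kurtosis(marg, sample_moments),
    direction = dirv,
    wiener_entropy = wiener_entropy(v),
    spectral_salience = spectral_salience(v),
    tremolo = tremolo_score(track),
    spectral_energy = if (length(fev)) mean(fev) else NA_real_,
    spectral_purity = spectral_purity(v))
}

#' 1-D marginals of a call
#'
#' The three fixed-dimension vectors fed to the semi-convolutional
#' network: the fundamental line FF(t) and the fundamental-energy line
#' FE(t), both cut/zero-padded to the 100 ms span and resampled to 100
#' points (zeros mark breaks and padding), and the 233-bin spectral
#' marginal.
#'
#' @param track A `fundamental_track`.
#' @param freq_khz Frequency axis for the spectral marginal.
#' @return List with `ff_line` (100), `time_marginal` (100) and
#'   `freq_marginal` (233).
#' @export
marginal_set <- function(track, freq_khz = usv_freq_axis()) {
  fp <- track$frame_period_ms
  n_full <- as.integer(round(100 / fp))       # frames in 100 ms
  ff <- track$ff_khz
  fe <- ifelse(track$ff_khz > 0, track$fe, 0)
  fix_len <- function(x) {
    if (length(x) >= n_full) x[seq_len(n_full)] else c(x, rep(0, n_full - length(x)))
  }
  list(ff_line = resample_linear(fix_len(ff), 100),
       time_marginal = resample_linear(fix_len(fe), 100),
       freq_marginal = spectral_marginal(track, freq_khz))
}

#' Assemble the 457-dimensional extended feature vector
#'
#' Fixed layout: 24 scalar properties (18 automatic + the 6 scored
#' properties: direction, peaks, breaks, broadband, tremolo, complexity),
#' then the 100-point fundamental line, the 233-bin frequency marginal and
#' the 100-point time marginal - 457 values in total.
#'
#' @param scalars One-row tibble or numeric vector of the 18 automatic
#'   features (in [scalar_features()] order).
#' @param scores Numeric vector of the 6 scored properties, in the order
#'   direction, peaks, breaks, broadband, tremolo, complex.
#' @param marginals A [marginal_set()] list.
#' @return Named numeric vector of length 457.
#' @export
assemble_extended_vector <- function(scalars, scores, marginals) {
  s <- as.numeric(unlist(scalars, use.names = FALSE))
  if (length(s) != 18) stop("expected 18 automatic scalar features, got ", length(s))
  if (length(scores) != 6) stop("expected 6 scored properties, got ", length(scores))
  if (length(marginals$ff_line) != 100 ||
      length(marginals$time_marginal) != 100 ||
      length(marginals$freq_marginal) != 233) {
    stop("marginal dimensions must be 100/100/233")
  }
  out <- c(s, as.numeric(scores), marginals$ff_line, marginals$freq_marginal,
           marginals$time_marginal)
  names(out) <- c(
    names(scalar_feature_names()),
    c("score_direction", "score_peaks", "score_breaks", "score_broadband",
      "score_tremolo", "score_complex"),
    paste0("ff_", 1:100), paste0("fmarg_", 1:233), paste0("tmarg_", 1:100))
  out
}

scalar_feature_names <- function() {
  stats::setNames(1:18, c(
    "duration_ms", "spectral_width_khz", "start_freq_khz", "end_freq_khz",
    "min_freq_khz", "max_freq_khz", "mean_freq_ff_khz",
    "mean_freq_weighted_khz", "temporal_skewness", "temporal_kurtosis",
    "spectral_skewness", "spectral_kurtosis", "direction", "wiener_entropy",
    "spectral_salience", "tremolo", "spectral_energy", "spectral_purity"))
}

#' Extract the full feature set of one call
#'
#' Convenience wrapper running denoising, fundamental tracking, scalar
#' features, break/peak counts and marginals on a call spectrogram patch.
#' Feature formulas operate on the power spectrogram `S = |STFT|^2`.
#'
#' @param spec An `usv_spectrogram` patch (magnitude) or matrix.
#' @param denoise_iterations Curvature-flow iterations (0 to skip).
#' @param power Square the magnitudes before analysis.
#' @return One-row tibble: 18 automatic scalars plus `n_breaks`, `n_peaks`
#'   and list-columns `marginals` and `track`.
#' @export
extract_features <- function(spec, denoise_iterations = 10, power = TRUE) {
  v <- spec_values(spec)
  if (power) v <- v^2
  spec2 <- set_spec_values(spec, v)
  if (denoise_iterations > 0) {
    spec2 <- denoise_curvature_flow(spec2, denoise_iterations)
  }
  track <- extract_fundamental(spec2)
  feats <- scalar_features(track, spec2)
  feats$n_breaks <- n_breaks(track)
  feats$n_peaks <- n_peaks(track)
  feats$marginals <- list(marginal_set(track))
  feats$track <- list(track)
  feats
}
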