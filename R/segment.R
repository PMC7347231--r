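#' Segmentation configuration
#'
#' Parameters of the call-extraction pipeline: a 4th-order Butterworth
#' high-pass at 25 kHz, a magnitude spectrogram from 500-sample (1.67 ms)
#' windows with 50% overlap (frame rate 1.2 kHz), percentile
#' sparsification, a recording-wide spectral-energy criterion, a
#' spectral-continuity criterion on the per-frame peak track, a mean-
#' frequency criterion, merging of detections separated by less than
#' 15 ms, and export to left-aligned 100 x 100 uint8 images with calls
#' truncated at 100 ms.
#'
#' @param hp_order,hp_cutoff_khz High-pass filter order and cutoff.
#' @param win_len,overlap STFT window length (samples) and fractional
#'   overlap.
#' @param window STFT window function (`"hann"` or `"rect"`).
#' @param sparsify_percentile Recording-wide percentile below which
#'   spectrogram bins are zeroed.
#' @param energy_quantile Recording-wide quantile (percent) a frame's
#'   maximum bin must exceed to count as call energy.
#' @param continuity_window Number of consecutive peak-track steps summed
#'   by the continuity criterion (4 steps, about 3.3 ms).
#' @param continuity_threshold Maximum accumulated peak displacement, in
#'   frequency-bin units.
#' @param min_mean_freq_khz Minimum energy-weighted mean frequency.
#' @param merge_gap_ms Detections closer than this are merged.
#' @param image_size Output image side length.
#' @param max_duration_ms Calls longer than this are truncated.
#' @param sample_rate Expected audio sample rate.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(hp_order = 4L, hp_cutoff_khz = 25,
                                win_len = 500L, overlap = 0.5,
                                window = c("hann", "rect"),
                                sparsify_percentile = 70,
                                energy_quantile = 99.8,
                                continuity_window = 4L,
                                continuity_threshold = 15,
                                min_mean_freq_khz = 25,
                                merge_gap_ms = 15,
                                image_size = 100L,
                                max_duration_ms = 100,
                                sample_rate = USV_SAMPLE_RATE) {
  stopifnot(overlap > 0, overlap < 1,
            sparsify_percentile > 0, sparsify_percentile < 100,
            energy_quantile > 0, energy_quantile < 100,
            merge_gap_ms > 0, max_duration_ms > 0)
  structure(
    list(hp_order = hp_order, hp_cutoff_khz = hp_cutoff_khz,
         win_len = as.integer(win_len), overlap = overlap,
         window = match.arg(window),
         sparsify_percentile = sparsify_percentile,
         energy_quantile = energy_quantile,
         continuity_window = as.integer(continuity_window),
         continuity_threshold = continuity_threshold,
         min_mean_freq_khz = min_mean_freq_khz,
         merge_gap_ms = merge_gap_ms,
         image_size = as.integer(image_size),
         max_duration_ms = max_duration_ms,
         sample_rate = as.integer(sample_rate)),
    class = "segmentation_config")
}

#' High-pass filter a recording
#'
#' Butterworth high-pass (causal direct-form filtering) removing
#' low-frequency environmental noise below the USV band.
#'
#' @param waveform Numeric vector.
#' @param sample_rate Samples per second.
#' @param order Filter order.
#' @param cutoff_khz Cutoff frequency in kHz (must be below Nyquist).
#' @return Filtered waveform.
#' @export
highpass <- function(waveform, sample_rate = USV_SAMPLE_RATE, order = 4L,
                     cutoff_khz = 25) {
  nyq <- sample_rate / 2
  if (cutoff_khz * 1000 >= nyq) {
    stop("cutoff (", cutoff_khz, " kHz) at or above Nyquist (",
         nyq / 1000, " kHz)")
  }
  bf <- signal::butter(order, cutoff_khz * 1000 / nyq, type = "high")
  as.numeric(signal::filter(bf, waveform))
}

#' Magnitude spectrogram
#'
#' Short-time Fourier transform magnitude on the fixed frame grid:
#' `win_len`-sample windows advanced by `win_len * (1 - overlap)` samples
#' (defaults: 500 and 250 at 300 kHz, i.e. a 1.2 kHz frame rate). Of the
#' 251 non-negative-frequency bins of a 500-point transform the top 233
#' are kept (10.8-150 kHz at 600 Hz spacing), which excludes the
#' low-frequency rows the high-pass filter has emptied.
#'
#' @param waveform Numeric vector, at least one window long.
#' @param config A [segmentation_config()].
#' @return An object of class `usv_spectrogram`: `values` (233 x T
#'   non-negative magnitude matrix, rows in ascending frequency),
#'   `freq_khz`, `time_ms` (frame centers) and `frame_period_ms`.
#' @export
stft_magnitude <- function(waveform, config = segmentation_config()) {
  win <- config$win_len
  hop <- as.integer(round(win * (1 - config$overlap)))
  n <- length(waveform)
  if (n < win) stop("waveform shorter than one window (", win, " samples)")
  starts <- seq(1L, n - win + 1L, by = hop)
  frames <- matrix(waveform[outer(0:(win - 1L), starts, `+`)], nrow = win)
  if (config$window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1L)) / (win - 1L))
    frames <- frames * w
  }
  spec <- Mod(stats::mvfft(frames))[1:(win %/% 2 + 1L), , drop = FALSE]
  n_bins <- win %/% 2 + 1L                      # 251 for win = 500
  keep <- (n_bins - USV_N_FREQ + 1L):n_bins     # top 233 bins
  df <- config$sample_rate / win / 1000         # 0.6 kHz
  structure(
    list(values = spec[keep, , drop = FALSE],
         freq_khz = (keep - 1L) * df,
         time_ms = (starts - 1L + win / 2) / config$sample_rate * 1000,
         frame_period_ms = hop / config$sample_rate * 1000,
         sample_rate = config$sample_rate),
    class = "usv_spectrogram")
}

#' @export
print.usv_spectrogram <- function(x, ...) {
  cat("usv_spectrogram: ", nrow(x$values), " x ", ncol(x$values),
      " (", round(min(x$freq_khz), 1), "-", round(max(x$freq_khz), 1),
      " kHz, ", round(max(x$time_ms)), " ms)\n", sep = "")
  invisible(x)
}

#' Percentile sparsification
#'
#' Zeroes every bin strictly below the recording-wide percentile of the
#' magnitude distribution (inverse-ECDF percentile, so with the default 70
#' on a continuous-valued spectrogram about 70% of bins are zeroed).
#'
#' @param spec An `usv_spectrogram` or bare matrix.
#' @param percentile Percentile in (0, 100).
#' @return Same type as `spec`.
#' @export
sparsify <- function(spec, percentile = 70) {
  v <- spec_values(spec)
  if (!length(v)) stop("empty spectrogram")
  thr <- stats::quantile(v, percentile / 100, type = 1, names = FALSE)
  v[v < thr] <- 0
  set_spec_values(spec, v)
}

spec_values <- function(spec) {
  if (inherits(spec, "usv_spectrogram")) spec$values else as.matrix(spec)
}
set_spec_values <- function(spec, v) {
  if (inherits(spec, "usv_spectrogram")) { spec$values <- v; spec } else v
}

#' Spectral-energy criterion
#'
#' Keeps a frame iff any of its frequency bins exceeds the recording-wide
#' `quantile` of all bins; reflects the rarity of call energy among mostly
#' silent background bins.
#'
#' @param spec Sparsified spectrogram (or matrix).
#' @param quantile Percent, e.g. 99.8.
#' @return Logical vector over frames.
#' @export
energy_gate <- function(spec, quantile = 99.8) {
  v <- spec_values(spec)
  if (!length(v)) return(logical(0))
  if (all(v == 0)) return(rep(FALSE, ncol(v)))
  thr <- stats::quantile(v, quantile / 100, type = 1, names = FALSE)
  apply(v, 2, max) > thr
}

#' Candidate intervals from a frame mask
#'
#' Contiguous runs of energy-passing frames become segment candidates.
#'
#' @param mask Logical frame mask.
#' @param spec Spectrogram providing the time axis.
#' @return Tibble with `start_frame`, `end_frame`, `onset_ms`, `offset_ms`.
#' @export
find_candidates <- function(mask, spec) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  fp <- spec$frame_period_ms %||% 1
  t0 <- spec$time_ms %||% (seq_along(mask) * fp)
  tibble::tibble(
    start_frame = starts[keep], end_frame = ends[keep],
    onset_ms = t0[starts[keep]] - fp / 2,
    offset_ms = t0[ends[keep]] + fp / 2)
}

#' Spectral-continuity criterion
#'
#' Tracks the frequency bin of maximal magnitude across the candidate's
#' frames, accumulates absolute bin displacements over windows of
#' `window` consecutive steps (about 3.3 ms), and accepts the candidate iff
#' the minimum accumulated displacement is below `threshold` bins - i.e.
#' the central spectral line holds still somewhere within the candidate.
#' Candidates with a single frame pass by convention.
#'
#' @param spec Spectrogram (or matrix).
#' @param candidate One-row tibble (or list) with `start_frame`/`end_frame`.
#' @param window Steps per accumulation window.
#' @param threshold Bin-displacement threshold.
#' @return Logical.
#' @export
continuity_gate <- function(spec, candidate, window = 4L, threshold = 15) {
  v <- spec_values(spec)
  idx <- candidate$start_frame:candidate$end_frame
  if (length(idx) < 2L) return(TRUE)
  peaks <- apply(v[, idx, drop = FALSE], 2, which.max)
  d <- abs(diff(peaks))
  if (length(d) >= window) {
    acc <- stats::filter(d, rep(1, window), sides = 2)
    acc <- acc[!is.na(acc)]
    if (!length(acc)) acc <- sum(d)
  } else {
    acc <- sum(d)
  }
  min(acc) < threshold
}

#' Mean-frequency criterion
#'
#' Accepts the candidate iff the energy-weighted mean frequency of its
#' patch is at least `min_mean_freq_khz`; rejects residual low-frequency
#' noise that leaked past the high-pass filter. Zero-energy candidates
#' fail.
#'
#' @param spec An `usv_spectrogram`.
#' @param candidate One-row tibble with frame bounds.
#' @param min_mean_freq_khz Threshold in kHz.
#' @return Logical.
#' @export
frequency_gate <- function(spec, candidate, min_mean_freq_khz = 25) {
  v <- spec$values[, candidate$start_frame:candidate$end_frame, drop = FALSE]
  tot <- sum(v)
  if (tot <= 0) return(FALSE)
  mean_f <- sum(spec$freq_khz * rowSums(v)) / tot
  mean_f >= min_mean_freq_khz
}

#' Merge candidates separated by short gaps
#'
#' Consecutive candidates whose offset-to-onset gap is strictly below
#' `gap_ms` are merged into one spanning candidate; a call briefly
#' interrupted by a breath or break is treated as a single vocalization.
#' Idempotent.
#'
#' @param candidates Tibble sorted by onset.
#' @param gap_ms Merge threshold (strict `<`).
#' @return Tibble of merged candidates.
#' @export
merge_candidates <- function(candidates, gap_ms = 15) {
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  stopifnot(!is.unsorted(candidates$onset_ms))
  group <- cumsum(c(1, as.numeric(
    candidates$onset_ms[-1] - candidates$offset_ms[-n] >= gap_ms)))
  candidates |>
    dplyr::mutate(.grp = group) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      start_frame = min(.data$start_frame),
      end_frame = max(.data$end_frame),
      onset_ms = min(.data$onset_ms),
      offset_ms = max(.data$offset_ms),
      .groups = "drop") |>
    dplyr::select(-".grp")
}

#' Fixed-size call image
#'
#' Cuts the candidate's spectrogram patch at 100 ms, expresses it on the
#' native N x 233 grid (N = duration in ms), rescales it by the common
#' factor 100/233 on both axes (preserving the aspect ratio) to M x 100
#' with `M = round(N * 100 / 233)`, left-aligns it in a 100 x 100 frame
#' and maps intensities linearly from `[0, max]` to 0-255 integers.
#'
#' @param spec An `usv_spectrogram`.
#' @param candidate One-row tibble with `start_frame`/`end_frame`.
#' @param config A [segmentation_config()].
#' @return An object of class `voc_image`: `image` (100 x 100 matrix of
#'   0-255 integers, rows = frequency, columns = time, content in columns
#'   `1:occupied`), `occupied`, `truncated`, `duration_ms`.
#' @export
to_fixed_image <- function(spec, candidate, config = segmentation_config()) {
  f1 <- candidate$start_frame
  f2 <- candidate$end_frame
  if (is.na(f1) || is.na(f2) || f2 < f1) stop("empty candidate")
  fp <- spec$frame_period_ms
  duration <- (f2 - f1 + 1L) * fp
  truncated <- duration > config$max_duration_ms
  if (truncated) {
    f2 <- f1 + as.integer(ceiling(config$max_duration_ms / fp)) - 1L
    duration <- config$max_duration_ms
  }
  patch <- spec$values[, f1:f2, drop = FALSE]
  n_ms <- max(1L, round(duration))
  side <- config$image_size
  m_cols <- max(1L, min(side, round(n_ms * side / USV_N_FREQ)))
  img <- matrix(0, side, side)
  if (any(patch > 0)) {
    # EBImage treats the first dimension as x; resize to side rows x m cols
    scaled <- EBImage::resize(patch, w = side, h = m_cols)
    scaled[scaled < 0] <- 0
    img[, seq_len(m_cols)] <- scaled
    img <- round(img / max(img) * 255)
  }
  structure(
    list(image = img, occupied = m_cols, truncated = truncated,
         duration_ms = duration),
    class = "voc_image")
}

# direct call-to-image path used by the synthetic dataset generator:
# spectrogram of one call snippet, per-call sparsification, full-extent image
call_image <- function(waveform, config = segmentation_config()) {
  spec <- stft_magnitude(waveform, config)
  spec <- sparsify(spec, config$sparsify_percentile)
  cand <- tibble::tibble(start_frame = 1L, end_frame = ncol(spec$values))
  to_fixed_image(spec, cand, config)
}

#' Segment a recording into vocalizations
#'
#' Full extraction pipeline: high-pass filtering, magnitude spectrogram,
#' recording-wide sparsification, the spectral-energy criterion forming
#' candidates from contiguous energetic frames, the spectral-continuity
#' and mean-frequency criteria filtering them, merging of detections
#' closer than 15 ms, and fixed-size image export.
#'
#' @param waveform Numeric vector (or an `usv_recording`).
#' @param config A [segmentation_config()].
#' @return A list of class `usv_segmentation`: `segments` (tibble with
#'   onset/offset/duration, criterion flags and `truncated`), `images`
#'   (list of [to_fixed_image()] results for accepted segments) and
#'   `spectrogram` (the sparsified recording spectrogram).
#' @export
segment_recording <- function(waveform, config = segmentation_config()) {
  if (inherits(waveform, "usv_recording")) waveform <- waveform$waveform
  wave <- highpass(waveform, config$sample_rate, config$hp_order,
                   config$hp_cutoff_khz)
  spec <- stft_magnitude(wave, config)
  spec <- sparsify(spec, config$sparsify_percentile)
  mask <- energy_gate(spec, config$energy_quantile)
  cands <- find_candidates(mask, spec)
  if (nrow(cands) == 0) {
    return(structure(list(
      segments = tibble::tibble(onset_ms = numeric(0), offset_ms = numeric(0),
                                duration_ms = numeric(0), truncated = logical(0)),
      images = list(), spectrogram = spec), class = "usv_segmentation"))
  }
  pass_cont <- vapply(seq_len(nrow(cands)), function(i) {
    continuity_gate(spec, cands[i, ], config$continuity_window,
                    config$continuity_threshold)
  }, logical(1))
  pass_freq <- vapply(seq_len(nrow(cands)), function(i) {
    frequency_gate(spec, cands[i, ], config$min_mean_freq_khz)
  }, logical(1))
  accepted <- cands[pass_cont & pass_freq, , drop = FALSE]
  merged <- merge_candidates(accepted, config$merge_gap_ms)
  images <- lapply(seq_len(nrow(merged)), function(i) {
    to_fixed_image(spec, merged[i, ], config)
  })
  segments <- merged |>
    dplyr::mutate(
      duration_ms = .data$offset_ms - .data$onset_ms,
      truncated = vapply(images, function(im) im$truncated, logical(1)))
  structure(list(segments = segments, images = images, spectrogram = spec),
            class = "usv_segmentation")
}

#' Match detected segments against annotated calls
#'
#' Greedy one-to-one matching: a detection matches an annotation when
#' their temporal overlap covers at least `min_overlap` of the annotated
#' call. Returns precision, recall and F1.
#'
#' @param segments Tibble with `onset_ms`/`offset_ms` (detections).
#' @param annotations Tibble with `onset_ms`/`offset_ms` (ground truth).
#' @param min_overlap Minimum fractional overlap of the annotation.
#' @return Tibble with `n_detected`, `n_annotated`, `matched`, `precision`,
#'   `recall`, `f1`.
#' @export
segmentation_score <- function(segments, annotations, min_overlap = 0.5) {
  nd <- nrow(segments)
  na <- nrow(annotations)
  used <- rep(FALSE, nd)
  matched <- 0L
  for (i in seq_len(na)) {
    ov <- pmin(segments$offset_ms, annotations$offset_ms[i]) -
      pmax(segments$onset_ms, annotations$onset_ms[i])
    frac <- ov / (annotations$offset_ms[i] - annotations$onset_ms[i])
    frac[used] <- -Inf
    j <- which.max(frac)
    if (nd > 0 && length(j) && frac[j] >= min_overlap) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  precision <- if (nd > 0) matched / nd else 0
  recall <- if (na > 0) matched / na else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(n_detected = nd, n_annotated = na, matched = matched,
                 precision = precision, recall = recall, f1 = f1)
}
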