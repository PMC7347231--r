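#' Experiment configuration
#'
#' Declarative description of an end-to-end synthetic experiment:
#' generation, segmentation check, feature extraction, classifier
#' training and evaluation. A seed is mandatory - every downstream stage
#' draws from the one seeded RNG stream.
#'
#' @param seed Integer seed (required).
#' @param profiles `"default"` (sex-like marginal effects) or
#'   `"nonlinear"` (class signal in the parameter interaction).
#' @param effect Effect-size multiplier for the default profiles.
#' @param n_per_individual,n_individuals_per_class Dataset size.
#' @param snr_db Per-call SNR for image generation.
#' @param units Convolutional units of the (reduced) network.
#' @param epochs Training epochs (single stage at lr 1e-3).
#' @param test_fraction Held-out fraction for evaluation.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(seed, profiles = c("default", "nonlinear"),
                              effect = 1, n_per_individual = 30,
                              n_individuals_per_class = 2, snr_db = Inf,
                              units = 8, epochs = 3, test_fraction = 0.2) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("experiment_config requires an explicit `seed`")
  }
  structure(
    list(seed = as.integer(seed), profiles = match.arg(profiles),
         effect = effect, n_per_individual = n_per_individual,
         n_individuals_per_class = n_individuals_per_class,
         snr_db = snr_db, units = units, epochs = epochs,
         test_fraction = test_fraction),
    class = "experiment_config")
}

#' Run an end-to-end synthetic experiment
#'
#' Generates a labeled dataset, extracts features from a subsample,
#' trains the reduced spectrogram network plus ridge and SVM baselines on
#' a random train/test split, and evaluates everything. When `out_dir` is
#' given, writes `manifest.json` (config + session fingerprint),
#' `dataset.csv`, `features.csv` and `evaluation.csv`; reruns with the
#' same config reproduce the tables exactly.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory.
#' @return List with `dataset` (ground-truth tibble without list-columns),
#'   `features`, `evaluation` and `config`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  profiles <- switch(config$profiles,
                     default = default_profiles(config$effect),
                     nonlinear = nonlinear_profiles())
  ds <- make_labeled_dataset(profiles, config$n_per_individual,
                             config$n_individuals_per_class,
                             snr_db = config$snr_db)
  n <- nrow(ds)
  feats <- purrr::map_dfr(sample.int(n, min(n, 40)), function(i) {
    spec <- image_as_spectrogram(ds$image[[i]])
    f <- tryCatch(extract_features(spec, denoise_iterations = 2),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    dplyr::select(f, -"marginals", -"track") |>
      dplyr::mutate(row = i, class = ds$class[i], .before = 1)
  })

  n_test <- max(2L, round(config$test_fraction * n))
  test <- sort(sample.int(n, n_test))
  train <- setdiff(seq_len(n), test)
  input <- network_input(images = ds$image)
  tr_in <- list(streams = list(input$streams[[1]][, train, drop = FALSE]),
                scalars = NULL)
  te_in <- list(streams = list(input$streams[[1]][, test, drop = FALSE]),
                scalars = NULL)
  proto <- tibble::tibble(stage = 1L, epochs = config$epochs, lr = 1e-3,
                          dropout = 0, lr_end = NA_real_)
  net <- build_network(conv_net_spec(units = config$units,
                                     fc_units = rep(config$units, 3)))
  net <- train_network(net, tr_in, ds$class[train], protocol = proto)
  pred_net <- predict(net, te_in, type = "class")
  X <- t(input$streams[[1]])
  ridge <- ridge_classify(X[train, ], ds$class[train], lambda = 10)
  svm <- svm_classify(X[train, ], ds$class[train], kernel = "quadratic")
  evals <- list(
    cnn = evaluate_predictions(ds$class[test], pred_net, scheme = "random-holdout"),
    ridge = evaluate_predictions(ds$class[test], predict(ridge, X[test, ]),
                                 scheme = "random-holdout"),
    svm = evaluate_predictions(ds$class[test], predict(svm, X[test, ]),
                               scheme = "random-holdout"))
  evaluation <- purrr::imap_dfr(evals, function(ev, nm) {
    dplyr::mutate(generics::glance(ev), classifier = nm, .before = 1)
  })
  dataset <- dplyr::select(ds, -"image", -"spec")
  out <- list(dataset = dataset, features = feats, evaluation = evaluation,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(
      config = unclass(config),
      package_version = as.character(utils::packageVersion("usvnet")),
      r_version = R.version.string,
      config_hash = digest_config(config))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    utils::write.csv(dataset, file.path(out_dir, "dataset.csv"),
                     row.names = FALSE)
    utils::write.csv(feats, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(evaluation, file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)
  }
  out
}

# stable fingerprint of a config (no external digest dependency)
digest_config <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2^31
}

#' Reinterpret a stored call image as a spectrogram patch
#'
#' The fixed 100 x 100 images carry the call left-aligned on a rescaled
#' 100-row frequency axis; for feature extraction the occupied part is
#' mapped back onto the native 233-bin axis and a 100 ms time base.
#'
#' @param image `voc_image` or 100 x 100 matrix.
#' @return An `usv_spectrogram`.
#' @export
image_as_spectrogram <- function(image) {
  img <- if (inherits(image, "voc_image")) image$image else as.matrix(image)
  occ <- which(colSums(img) > 0)
  m <- if (length(occ)) max(occ) else 1L
  n_ms <- max(3L, round(m * USV_N_FREQ / nrow(img)))
  n_frames <- max(4L, round(n_ms * 1.2))
  patch <- EBImage::resize(img[, seq_len(m), drop = FALSE],
                           w = USV_N_FREQ, h = n_frames)
  patch[patch < 0] <- 0
  structure(
    list(values = patch, freq_khz = usv_freq_axis(),
         time_ms = (seq_len(n_frames) - 0.5) / 1.2,
         frame_period_ms = 1 / 1.2, sample_rate = USV_SAMPLE_RATE),
    class = "usv_spectrogram")
}
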