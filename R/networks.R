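#' Network architectures
#'
#' Declarative specifications of the three classifier families:
#'
#' * `conv_net_spec()`: the spectrogram classifier - 6 convolutional
#'   layers (kernels 10x10, 5x5, 3x3, 3x3, 3x3, 3x3; strides 2, 2, 1, 1,
#'   1, 1; 256 units each) followed by 3 fully connected layers of 120
#'   units (80 for the broadband variant) and a sigmoid or softmax head.
#' * `dense_net_spec()`: the feature classifier - 4 fully connected
#'   layers of 70 units on a 9-dimensional input, sigmoid output.
#' * `semi_conv_net_spec()`: the extended-feature classifier - three
#'   parallel 1-D convolutional stacks (kernels 7, 5, 3, 3, 3; strides
#'   2, 2, 1, 1, 1; 32 units) over the 100-point fundamental line, the
#'   100-point time marginal and the 233-bin frequency marginal, whose
#'   outputs are concatenated with the 24 scalar properties into 3 fully
#'   connected layers of 90 units, sigmoid output.
#'
#' Every hidden layer is batch-normalized with ReLU activation;
#' convolutions use "same" padding (no pooling); weights are Xavier
#' (Glorot-uniform) initialized. `units`/`fc_units` can be reduced for
#' scaled-down experiments without changing the architecture.
#'
#' @param out_dim Output head dimension (1 for binary sex/strain/broadband;
#'   4 for peaks/breaks; 3 for direction; number of individuals for
#'   identity).
#' @param out_activation `"sigmoid"` (binary) or `"softmax"`.
#' @param units Convolutional units per layer.
#' @param fc_units Fully connected layer widths.
#' @param input Input image size (rows, columns).
#' @param input_dim Input dimension of the dense network.
#' @return A list of class `usv_network_spec`.
#' @export
conv_net_spec <- function(out_dim = 1, out_activation = c("sigmoid", "softmax"),
                          units = 256, fc_units = c(120, 120, 120),
                          input = c(100, 100)) {
  out_activation <- match.arg(out_activation)
  if (out_activation == "sigmoid" && out_dim != 1) {
    stop("sigmoid head requires out_dim = 1")
  }
  kernels <- list(c(10, 10), c(5, 5), c(3, 3), c(3, 3), c(3, 3), c(3, 3))
  strides <- c(2, 2, 1, 1, 1, 1)
  layers <- purrr::map2(kernels, strides, function(k, s) {
    list(kernel = as.integer(k), stride = as.integer(s),
         units = as.integer(units))
  })
  structure(
    list(kind = "conv2d",
         streams = list(list(shape = as.integer(c(input, 1)), layers = layers)),
         scalar_dim = 0L, fc_units = as.integer(fc_units),
         out_dim = as.integer(out_dim), out_activation = out_activation),
    class = "usv_network_spec")
}

#' @rdname conv_net_spec
#' @export
dense_net_spec <- function(input_dim = 9, units = 70, out_dim = 1,
                           out_activation = c("sigmoid", "softmax")) {
  structure(
    list(kind = "dense", streams = list(),
         scalar_dim = as.integer(input_dim),
         fc_units = as.integer(rep(units, 4)),
         out_dim = as.integer(out_dim),
         out_activation = match.arg(out_activation)),
    class = "usv_network_spec")
}

#' @rdname conv_net_spec
#' @export
semi_conv_net_spec <- function(units = 32, fc_units = c(90, 90, 90),
                               out_dim = 1,
                               out_activation = c("sigmoid", "softmax")) {
  kernels <- list(7L, 5L, 3L, 3L, 3L)
  strides <- c(2, 2, 1, 1, 1)
  stack <- function(len) {
    list(shape = c(1L, as.integer(len), 1L),
         layers = purrr::map2(kernels, strides, function(k, s) {
           list(kernel = c(1L, k), stride = as.integer(s),
                units = as.integer(units))
         }))
  }
  structure(
    list(kind = "semiconv",
         streams = list(stack(100), stack(100), stack(233)),
         scalar_dim = 24L, fc_units = as.integer(fc_units),
         out_dim = as.integer(out_dim),
         out_activation = match.arg(out_activation)),
    class = "usv_network_spec")
}

#' Training protocols
#'
#' The staged Adam protocols (epochs, learning rate, dropout probability;
#' batch size 64 throughout):
#'
#' * `"spectrogram"`: 3 stages - (40, 1e-3, 0.0), (25, 1e-4, 0.5),
#'   (25, 1e-5, 0.7) - used for the spectrogram-to-sex/individual nets.
#' * `"spectrogram_features"`: 2 stages - (40, 1e-3, 0.0),
#'   (25, 1e-4, 0.5).
#' * `"features"`: 2 stages - (150, 1e-3, 0.0) and (200, quadratic decay
#'   from 1e-3 to 1e-5, 0.5).
#' * `"extended_features"`: 4 stages - (50, 1e-3, 0.0), (100, 1e-4, 0.3),
#'   (100, 1e-5, 0.5), (100, 2e-6, 0.5).
#' * `"reduced"`: the single-stage scaled-down protocol used for the
#'   synthetic surrogate experiments - 5 epochs at the stage-1 settings
#'   (lr 1e-3, no dropout).
#'
#' @param name Protocol name.
#' @return Tibble with `stage`, `epochs`, `lr`, `dropout` and `lr_end`
#'   (`NA` except for decaying stages).
#' @export
train_protocol <- function(name = c("spectrogram", "spectrogram_features",
                                    "features", "extended_features",
                                    "reduced")) {
  name <- match.arg(name)
  p <- switch(name,
    spectrogram = tibble::tibble(
      epochs = c(40, 25, 25), lr = c(1e-3, 1e-4, 1e-5),
      dropout = c(0, 0.5, 0.7), lr_end = NA_real_),
    spectrogram_features = tibble::tibble(
      epochs = c(40, 25), lr = c(1e-3, 1e-4),
      dropout = c(0, 0.5), lr_end = NA_real_),
    features = tibble::tibble(
      epochs = c(150, 200), lr = c(1e-3, 1e-3),
      dropout = c(0, 0.5), lr_end = c(NA_real_, 1e-5)),
    extended_features = tibble::tibble(
      epochs = c(50, 100, 100, 100), lr = c(1e-3, 1e-4, 1e-5, 2e-6),
      dropout = c(0, 0.3, 0.5, 0.5), lr_end = NA_real_),
    reduced = tibble::tibble(
      epochs = 5, lr = 1e-3, dropout = 0, lr_end = NA_real_))
  dplyr::mutate(p, stage = dplyr::row_number(), .before = 1)
}

#' Build a network from a specification
#'
#' Instantiates Xavier-initialized parameters (using R's RNG, so call
#' [set.seed()] first for reproducibility).
#'
#' @param spec An `usv_network_spec`.
#' @return An object of class `usv_network`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "usv_network_spec"))
  params <- nn_init_cpp(unclass(spec))
  structure(list(spec = spec, params = params, trained = FALSE,
                 loss_trace = numeric(0), levels = NULL),
            class = "usv_network")
}

#' @export
print.usv_network <- function(x, ...) {
  cat("usv_network (", x$spec$kind, "): ",
    length(x$spec$streams), " conv stream(s), fc ",
    paste(x$spec$fc_units, collapse = "/"), ", head ",
    x$spec$out_activation, "-", x$spec$out_dim, "; ",
    format(n_parameters(x), big.mark = ","), " parameters",
    if (x$trained) " (trained)" else " (untrained)", "\n", sep = "")
  invisible(x)
}

#' Parameter counts of a network
#'
#' `n_parameters()` totals every trainable parameter. `layer_shapes()`
#' details per-layer geometry and counts; for convolutional and fully
#' connected layers `weights` counts the kernel/weight matrix and `shift`
#' the additive per-unit offset (the batch-norm shift, which plays the
#' role of the bias), with the batch-norm scale listed separately.
#'
#' @param model An `usv_network`.
#' @return A scalar, or a tibble for `layer_shapes()`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) {
    if (is.list(p)) length(p$gamma) + length(p$beta) else length(p)
  }, numeric(1)))
}

#' @rdname n_parameters
#' @export
layer_shapes <- function(model) {
  spec <- model$spec
  rows <- list()
  for (s in seq_along(spec$streams)) {
    st <- spec$streams[[s]]
    h <- st$shape[1]; w <- st$shape[2]; cin <- st$shape[3]
    for (l in seq_along(st$layers)) {
      ly <- st$layers[[l]]
      oh <- ceiling(h / ly$stride); ow <- ceiling(w / ly$stride)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = paste0("s", s, "_CV", l),
        kernel = paste(ly$kernel, collapse = "x"),
        stride = ly$stride, units = ly$units,
        out_h = oh, out_w = ow,
        weights = prod(ly$kernel) * cin * ly$units,
        shift = ly$units, bn_scale = ly$units)
      h <- oh; w <- ow; cin <- ly$units
    }
  }
  din <- spec$scalar_dim +
    sum(vapply(spec$streams, function(st) {
      h <- st$shape[1]; w <- st$shape[2]
      for (ly in st$layers) { h <- ceiling(h / ly$stride); w <- ceiling(w / ly$stride) }
      h * w * st$layers[[length(st$layers)]]$units
    }, numeric(1)))
  for (l in seq_along(spec$fc_units)) {
    u <- spec$fc_units[l]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      layer = paste0("FC", l), kernel = "-", stride = 1L, units = u,
      out_h = 1L, out_w = 1L, weights = din * u, shift = u, bn_scale = u)
    din <- u
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    layer = "output", kernel = "-", stride = 1L, units = spec$out_dim,
    out_h = 1L, out_w = 1L, weights = din * spec$out_dim,
    shift = spec$out_dim, bn_scale = 0L)
  dplyr::bind_rows(rows)
}

# normalize labels to 0-based integers + level names
encode_labels <- function(labels, out_dim) {
  f <- as.factor(labels)
  y <- as.integer(f) - 1L
  k <- length(levels(f))
  if (out_dim == 1 && k != 2) stop("sigmoid head requires 2 classes, got ", k)
  if (out_dim > 1 && k > out_dim) {
    stop("more classes (", k, ") than head dimension (", out_dim, ")")
  }
  list(y = y, levels = levels(f))
}

#' Assemble network inputs
#'
#' Converts package objects to the matrix-per-stream format the training
#' engine consumes (one column per sample; image intensities scaled to
#' `[0, 1]`).
#'
#' @param images List of 100 x 100 matrices (0-255), or the `image`
#'   list-column of [make_labeled_dataset()].
#' @param features Numeric matrix/data frame (samples x variables) for the
#'   dense network.
#' @param extended Matrix of 457-dimensional extended vectors
#'   (samples x 457, [assemble_extended_vector()] layout).
#' @return A list with `streams` (list of d x n matrices) and `scalars`
#'   (p x n matrix or `NULL`).
#' @export
network_input <- function(images = NULL, features = NULL, extended = NULL) {
  if (!is.null(images)) {
    x <- vapply(images, function(im) {
      v <- as.numeric(if (inherits(im, "voc_image")) im$image else im)
      v / 255
    }, numeric(length(as.numeric(if (inherits(images[[1]], "voc_image"))
      images[[1]]$image else images[[1]]))))
    return(list(streams = list(x), scalars = NULL))
  }
  if (!is.null(features)) {
    m <- t(as.matrix(features))
    return(list(streams = list(), scalars = m))
  }
  if (!is.null(extended)) {
    m <- as.matrix(extended)
    stopifnot(ncol(m) == 457)
    return(list(streams = list(t(m[, 25:124, drop = FALSE]),
                               t(m[, 358:457, drop = FALSE]),
                               t(m[, 125:357, drop = FALSE])),
                scalars = t(m[, 1:24, drop = FALSE])))
  }
  stop("provide one of images/features/extended")
}

#' Train a network
#'
#' Runs the staged Adam protocol with batch size 64, batch-norm statistics
#' updated in training mode, class-weighted cross-entropy and optional
#' on-the-fly augmentation. Randomness (shuffling, dropout, augmentation)
#' comes from R's RNG; seed with [set.seed()].
#'
#' @param model An `usv_network`.
#' @param input A [network_input()] list.
#' @param labels Class labels (factor/character/integer).
#' @param protocol A [train_protocol()] tibble (or its name).
#' @param batch_size Minibatch size.
#' @param class_weights `NULL` for occurrence-based weights (inverse class
#'   frequency, mean 1), a named vector, or `"equal"`.
#' @param augment `NULL` or an [augment_config()] applied on the fly.
#' @return The trained `usv_network` (with `loss_trace` per epoch).
#' @export
train_network <- function(model, input, labels, protocol = "reduced",
                          batch_size = 64, class_weights = NULL,
                          augment = NULL) {
  stopifnot(inherits(model, "usv_network"))
  if (is.character(protocol)) protocol <- train_protocol(protocol)
  enc <- encode_labels(labels, model$spec$out_dim)
  k <- length(enc$levels)
  w <- if (is.null(class_weights)) {
    cw <- class_weights(labels)
    as.numeric(cw[enc$levels])
  } else if (identical(class_weights, "equal")) {
    rep(1, k)
  } else {
    as.numeric(class_weights[enc$levels])
  }
  stages <- cbind(protocol$epochs, protocol$lr, protocol$dropout,
                  if ("lr_end" %in% names(protocol)) protocol$lr_end else NA_real_)
  cb <- NULL
  if (!is.null(augment)) {
    kind <- model$spec$kind
    cb <- function(streams, scalars) {
      augment_batch(streams, scalars, config = augment, kind = kind)
    }
  }
  fit <- nn_train_cpp(unclass(model$spec), model$params, input$streams,
                      if (is.null(input$scalars)) NULL else input$scalars,
                      enc$y, stages, as.integer(batch_size), w, cb)
  model$params <- fit$params
  model$loss_trace <- c(model$loss_trace, fit$loss_trace)
  model$trained <- TRUE
  model$levels <- enc$levels
  model
}

#' Predict from a trained network
#'
#' @param object An `usv_network`.
#' @param input A [network_input()] list.
#' @param type `"prob"` for class probabilities, `"class"` for labels.
#' @param ... Unused.
#' @return Matrix of probabilities (n x heads) or a label vector.
#' @export
predict.usv_network <- function(object, input, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- nn_predict_cpp(unclass(object$spec), object$params, input$streams,
                      if (is.null(input$scalars)) NULL else input$scalars)
  if (type == "prob") return(p)
  lev <- object$levels %||% as.character(seq_len(max(2, ncol(p))) - 1L)
  if (object$spec$out_dim == 1) {
    lev[as.integer(p[, 1] >= 0.5) + 1L]
  } else {
    lev[max.col(p[, seq_along(lev), drop = FALSE])]
  }
}

#' Layer activations of a network
#'
#' Eval-mode post-ReLU responses of every layer to the given inputs;
#' convolutional maps are flattened per sample.
#'
#' @param model A (typically trained) `usv_network`.
#' @param input A [network_input()] list.
#' @return Named list of matrices (units x samples), tagged `s1_CV1` ...
#'   `FC3`, `output`.
#' @export
network_activations <- function(model, input) {
  nn_activations_cpp(unclass(model$spec), model$params, input$streams,
                     if (is.null(input$scalars)) NULL else input$scalars)
}
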