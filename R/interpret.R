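#' Activation sparsity
#'
#' Fraction of inactive units, `1 - active/total`, where a unit is active
#' when its post-ReLU response is strictly positive. Invariant to positive
#' rescaling of the activations.
#'
#' @param activation Numeric vector/matrix/array of (post-ReLU) responses.
#' @return Scalar in `[0, 1]`.
#' @export
activation_sparsity <- function(activation) {
  if (!length(activation)) stop("empty activation tensor")
  mean(activation <= 0)
}

#' Within- and across-class activation correlations
#'
#' Mean pairwise Pearson correlation between flattened per-sample
#' activation vectors, within each class and across the two classes.
#' Constant vectors (zero variance) are excluded from the pairs.
#'
#' @param activations Matrix (units x samples).
#' @param classes Class label per sample (exactly two classes).
#' @return Tibble with `within_1`, `within_2`, `across` and the class
#'   names.
#' @export
activation_correlations <- function(activations, classes) {
  classes <- as.character(classes)
  lev <- unique(classes)
  if (length(lev) != 2) stop("exactly two classes required")
  ok <- apply(activations, 2, stats::sd) > 0
  if (sum(ok & classes == lev[1]) < 2 || sum(ok & classes == lev[2]) < 2) {
    stop("need >= 2 non-constant samples per class")
  }
  C <- stats::cor(activations[, ok, drop = FALSE])
  cl <- classes[ok]
  off <- function(m) m[lower.tri(m)]
  i1 <- cl == lev[1]
  tibble::tibble(
    class_1 = lev[1], class_2 = lev[2],
    within_1 = mean(off(C[i1, i1, drop = FALSE])),
    within_2 = mean(off(C[!i1, !i1, drop = FALSE])),
    across = mean(C[i1, !i1, drop = FALSE]))
}

# stream-1 conv geometry of a network, with per-layer input shapes
conv_stack_geometry <- function(model) {
  st <- model$spec$streams[[1]]
  h <- st$shape[1]; w <- st$shape[2]; c <- st$shape[3]
  purrr::map(seq_along(st$layers), function(l) {
    ly <- st$layers[[l]]
    g <- list(shape = as.integer(c(h, w, c)), layer = ly)
    h <<- ceiling(h / ly$stride); w <<- ceiling(w / ly$stride)
    c <<- ly$units
    g
  })
}

#' Linear convolution map and its adjoint
#'
#' The raw linear building blocks of the deconvolution analysis: apply one
#' convolutional layer's weight matrix to an input (columns = channels,
#' rows = positions in column-major image order), or back-project a
#' feature map through the transposed weights. For any input `x` and
#' feature-space vector `g`, `sum(conv_forward_map(..., x) * g)` equals
#' `sum(x * conv_backproject(..., g))` - the back-projection is the exact
#' adjoint operator.
#'
#' @param shape Input shape `c(H, W, C)`.
#' @param layer Layer spec: list with `kernel` (`c(kh, kw)`), `stride`,
#'   `units`.
#' @param W Weight matrix (`kh*kw*C` x `units`).
#' @param x Input matrix (`H*W` x `C`).
#' @param g Feature map (`oH*oW` x `units`).
#' @return Feature map / input-space map.
#' @export
conv_forward_map <- function(shape, layer, W, x) {
  conv_apply_cpp(as.integer(shape), layer, W, as.matrix(x))
}

#' @rdname conv_forward_map
#' @export
conv_backproject <- function(shape, layer, W, g) {
  conv_adjoint_cpp(as.integer(shape), layer, W, as.matrix(g))
}

#' Deconvolution of a network's representation
#'
#' Back-projects the feature map of a chosen convolutional layer (all
#' units, or one unit with the rest zeroed) into input space by applying
#' the transposed layer weights sequentially through all preceding layers,
#' honoring strides and padding. The forward pass uses the trained
#' network's batch-norm statistics and ReLU; the backward pass uses plain
#' transposed weights by default, with `mode = "relu"` additionally
#' rectifying the backward signal at each layer and `mode = "guided"`
#' also gating by the forward activations.
#'
#' @param model A trained `usv_network` with a convolutional stream.
#' @param image 100 x 100 matrix (0-255 or `[0, 1]`).
#' @param layer Convolutional layer index (1-based).
#' @param neuron Optional unit index; `NULL` back-projects the whole map.
#' @param mode Backward variant.
#' @return A matrix of the input shape (class `deconv_map`).
#' @export
deconvolve <- function(model, image, layer, neuron = NULL,
                       mode = c("transpose", "relu", "guided")) {
  mode <- match.arg(mode)
  if (!length(model$spec$streams)) stop("model has no convolutional stream")
  geom <- conv_stack_geometry(model)
  if (layer < 1 || layer > length(geom)) stop("invalid layer index")
  img <- as.matrix(image)
  if (max(img) > 1) img <- img / 255
  x <- matrix(as.numeric(img), ncol = 1)
  acts <- vector("list", layer)
  for (l in seq_len(layer)) {
    W <- model$params[[paste0("s0_conv", l, "_W")]]
    bn <- model$params[[paste0("s0_conv", l, "_bn")]]
    pre <- conv_forward_map(geom[[l]]$shape, geom[[l]]$layer, W, x)
    pre <- sweep(pre, 2, bn$rmean, "-")
    pre <- sweep(pre, 2, sqrt(bn$rvar + 1e-5), "/")
    pre <- sweep(pre, 2, bn$gamma, "*")
    pre <- sweep(pre, 2, bn$beta, "+")
    acts[[l]] <- pmax(pre, 0)
    x <- acts[[l]]
  }
  g <- acts[[layer]]
  if (!is.null(neuron)) {
    if (neuron < 1 || neuron > ncol(g)) stop("invalid neuron index")
    keep <- g[, neuron]
    g <- matrix(0, nrow(g), ncol(g))
    g[, neuron] <- keep
  }
  for (l in rev(seq_len(layer))) {
    if (mode %in% c("relu", "guided")) g <- pmax(g, 0)
    if (mode == "guided" && l < layer) g <- g * (acts[[l]] > 0)
    W <- model$params[[paste0("s0_conv", l, "_W")]]
    g <- conv_backproject(geom[[l]]$shape, geom[[l]]$layer, W, g)
  }
  shp <- geom[[1]]$shape
  structure(matrix(g[, 1], shp[1], shp[2]), class = c("deconv_map", "matrix"))
}

#' Correlation between a deconvolved map and the original stimulus
#'
#' @param map Deconvolved input-space map.
#' @param original The original image (same shape).
#' @return Pearson correlation over pixels, `NA` if either is constant.
#' @export
representation_correlation <- function(map, original) {
  m <- as.numeric(map)
  o <- as.numeric(original)
  if (length(m) != length(o)) stop("shape mismatch")
  if (stats::sd(m) == 0 || stats::sd(o) == 0) return(NA_real_)
  stats::cor(m, o)
}

#' PCA embedding
#'
#' Projection onto the leading principal components (centred, unscaled).
#'
#' @param x Matrix (samples x variables).
#' @param out_dim Number of components.
#' @return An object of class `usv_embedding` with `coords`
#'   (n x out_dim), `method`, `params` and `explained_variance`.
#' @export
pca_embed <- function(x, out_dim = 3) {
  x <- as.matrix(x)
  if (nrow(x) <= out_dim) stop("need more samples than output dimensions")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = out_dim)
  if (ncol(p$x) < out_dim) stop("requested dimension exceeds data rank")
  structure(
    list(coords = p$x[, seq_len(out_dim), drop = FALSE], method = "pca",
         params = list(out_dim = out_dim),
         explained_variance = p$sdev^2 / sum(p$sdev^2),
         rotation = p$rotation),
    class = "usv_embedding")
}

#' t-SNE embedding
#'
#' Exact t-distributed stochastic neighbour embedding (Student-t map
#' affinities, per-point perplexity calibration, early exaggeration),
#' optionally preceded by PCA reduction (the convention is dimension 9 for
#' feature vectors and 100 for spectrograms). Deterministic under
#' [set.seed()].
#'
#' @param x Matrix (samples x variables).
#' @param out_dim Map dimension (default 3).
#' @param perplexity Target perplexity (requires `n > 3 * perplexity`).
#' @param pca_dim Optional PCA pre-reduction dimension.
#' @param max_iter,eta,exaggeration,exaggeration_iter Optimizer settings.
#' @return An `usv_embedding` with `coords` (n x out_dim).
#' @export
tsne_embed <- function(x, out_dim = 3, perplexity = 30, pca_dim = NULL,
                       max_iter = 500, eta = 200, exaggeration = 12,
                       exaggeration_iter = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= 3 * perplexity) stop("need n > 3 * perplexity")
  if (!is.null(pca_dim) && pca_dim < ncol(x)) {
    x <- pca_embed(x, min(pca_dim, n - 1))$coords
  }
  # duplicate rows make perplexity calibration degenerate; jitter them
  dup <- duplicated(x)
  if (any(dup)) {
    x[dup, ] <- x[dup, ] + stats::rnorm(sum(dup) * ncol(x),
                                        sd = 1e-8 * (stats::sd(x) + 1e-12))
  }
  y0 <- matrix(stats::rnorm(n * out_dim, sd = 1e-4), n, out_dim)
  coords <- tsne_cpp(x, y0, perplexity, max_iter, eta, exaggeration,
                     exaggeration_iter)
  colnames(coords) <- paste0("dim", seq_len(out_dim))
  structure(
    list(coords = coords, method = "tsne",
         params = list(out_dim = out_dim, perplexity = perplexity,
                       pca_dim = pca_dim, max_iter = max_iter)),
    class = "usv_embedding")
}

#' @export
print.usv_embedding <- function(x, ...) {
  cat("usv_embedding (", x$method, "): ", nrow(x$coords), " x ",
      ncol(x$coords), "\n", sep = "")
  invisible(x)
}

#' Leave-one-out nearest-neighbour decoding
#'
#' Each point is classified by the label of its nearest other point
#' (Euclidean distance; distance ties resolved to the lowest index).
#'
#' @param embedding An `usv_embedding` or coordinate matrix.
#' @param labels Label per point.
#' @return Percent correct (0-100).
#' @export
knn_loo_decode <- function(embedding, labels) {
  coords <- if (inherits(embedding, "usv_embedding")) embedding$coords else
    as.matrix(embedding)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 points")
  stopifnot(length(labels) == n)
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  100 * mean(labels[nn] == labels)
}

#' Class density difference on an embedding
#'
#' Kernel density estimates for the two classes on a common 2-D grid
#' (first two embedding dimensions by default), each normalized to unit
#' mass, then subtracted: positive regions are dominated by the first
#' class, negative by the second, and the field integrates to ~0.
#'
#' @param embedding `usv_embedding` or coordinate matrix.
#' @param labels Two-class label vector.
#' @param bandwidth Bandwidth (scalar or per-dim); default Scott's rule.
#' @param n_grid Grid resolution per axis.
#' @param dims Which two embedding dimensions to use.
#' @return List of class `density_difference`: `x`, `y`, `z` (first minus
#'   second class), `classes`, `bandwidth`.
#' @export
density_difference <- function(embedding, labels, bandwidth = NULL,
                               n_grid = 50, dims = c(1, 2)) {
  coords <- if (inherits(embedding, "usv_embedding")) embedding$coords else
    as.matrix(embedding)
  coords <- coords[, dims, drop = FALSE]
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("exactly two classes required")
  if (is.null(bandwidth)) {
    # Scott's rule in 2-D: sigma * n^(-1/6), per axis
    bandwidth <- vapply(1:2, function(j) {
      stats::sd(coords[, j]) * nrow(coords)^(-1 / 6)
    }, numeric(1))
  }
  bandwidth <- rep_len(bandwidth, 2)
  lims <- c(range(coords[, 1]), range(coords[, 2]))
  pad <- c(-1, 1) * 3 * bandwidth[1]
  lims[1:2] <- lims[1:2] + pad
  lims[3:4] <- lims[3:4] + c(-1, 1) * 3 * bandwidth[2]
  dens <- lapply(lev, function(cl) {
    # kde2d's h is the full kernel width convention (h/4 = sd)
    MASS::kde2d(coords[labels == cl, 1], coords[labels == cl, 2],
                h = bandwidth * 4, n = n_grid, lims = lims)
  })
  cell <- diff(dens[[1]]$x[1:2]) * diff(dens[[1]]$y[1:2])
  z1 <- dens[[1]]$z / (sum(dens[[1]]$z) * cell)
  z2 <- dens[[2]]$z / (sum(dens[[2]]$z) * cell)
  structure(list(x = dens[[1]]$x, y = dens[[1]]$y, z = z1 - z2,
                 classes = lev, bandwidth = bandwidth),
            class = "density_difference")
}
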