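#' Augmentation configuration
#'
#' On-the-fly modifications applied to each training sample: clipping of
#' the start and end (jointly up to `clip_frac` of the occupied duration),
#' intensity amplification by a uniform random coefficient, and additive
#' Gaussian noise with variance drawn uniformly from `noise_var` (on the
#' `[0, 1]` normalized intensity scale). For the 1-D streams of the
#' semi-convolutional network the fundamental line and time marginal get
#' clip + noise only (no amplification) and the frequency marginal gets
#' amplification in `freq_amp_range` + noise only.
#'
#' @param clip_frac Maximum clipped fraction of the occupied duration.
#' @param amp_range Amplification range for 2-D images.
#' @param noise_var Range of the Gaussian noise variance.
#' @param freq_amp_range Amplification range for the frequency marginal.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(clip_frac = 0.10, amp_range = c(0.5, 1.5),
                           noise_var = c(0, 0.01),
                           freq_amp_range = c(0.8, 1.2)) {
  structure(list(clip_frac = clip_frac, amp_range = amp_range,
                 noise_var = noise_var, freq_amp_range = freq_amp_range),
            class = "augment_config")
}

# clip a fraction of the occupied columns from start/end and left-shift
clip_columns <- function(m, clip_frac) {
  occ <- which(colSums(abs(m)) > 0)
  if (!length(occ) || clip_frac <= 0) return(m)
  n_occ <- length(occ)
  total <- stats::runif(1, 0, clip_frac) * n_occ
  a <- round(stats::runif(1, 0, total))
  b <- round(total) - a
  keep <- occ[seq.int(1 + a, length.out = max(1, n_occ - a - b))]
  out <- matrix(0, nrow(m), ncol(m))
  out[, seq_along(keep)] <- m[, keep, drop = FALSE]
  out
}

#' Augment a single call image
#'
#' Pure function of the input and R's RNG state; labels are untouched.
#' Expects intensities on the `[0, 1]` scale.
#'
#' @param img 100 x 100 matrix in `[0, 1]` (columns = time).
#' @param config An [augment_config()].
#' @return Augmented matrix, clipped to `[0, 1]`.
#' @export
augment_image <- function(img, config = augment_config()) {
  out <- clip_columns(img, config$clip_frac)
  amp <- stats::runif(1, config$amp_range[1], config$amp_range[2])
  v <- stats::runif(1, config$noise_var[1], config$noise_var[2])
  out <- out * amp
  if (v > 0) out <- out + stats::rnorm(length(out), sd = sqrt(v))
  clamp(out, 0, 1)
}

# per-stream augmentation used as the training callback;
# streams carry flattened samples in columns
augment_batch <- function(streams, scalars, config = augment_config(),
                          kind = c("conv2d", "semiconv", "dense")) {
  kind <- match.arg(kind)
  if (kind == "conv2d") {
    x <- streams[[1]]
    side <- as.integer(sqrt(nrow(x)))
    for (j in seq_len(ncol(x))) {
      x[, j] <- as.numeric(augment_image(matrix(x[, j], side, side), config))
    }
    streams[[1]] <- x
  } else if (kind == "semiconv") {
    aug1d <- function(x, amp_range = NULL) {
      for (j in seq_len(ncol(x))) {
        v <- matrix(x[, j], 1)
        v <- clip_columns(v, config$clip_frac)
        if (!is.null(amp_range)) {
          v <- v * stats::runif(1, amp_range[1], amp_range[2])
        }
        nv <- stats::runif(1, config$noise_var[1], config$noise_var[2])
        if (nv > 0) v <- v + stats::rnorm(length(v), sd = sqrt(nv))
        x[, j] <- pmax(as.numeric(v), 0)
      }
      x
    }
    streams[[1]] <- aug1d(streams[[1]])                          # ff line
    streams[[2]] <- aug1d(streams[[2]])                          # time marginal
    streams[[3]] <- aug1d(streams[[3]], config$freq_amp_range)   # freq marginal
  }
  list(streams = streams, scalars = scalars)
}

#' Occurrence-based class weights
#'
#' Per-class loss weights inversely proportional to class frequency
#' (normalized to mean 1), so every class contributes equally to the
#' expected loss despite imbalanced counts.
#'
#' @param labels Vector of class labels (at least two classes).
#' @return Named numeric vector of weights.
#' @export
class_weights <- function(labels) {
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 classes")
  w <- 1 / as.numeric(counts)
  w <- w / mean(w)
  stats::setNames(w, names(counts))
}

#' Leave-one-subject-out folds
#'
#' One fold per individual: the test set is all calls of that individual,
#' the training set everything else, so individual-specific cues cannot
#' inflate class-level performance estimates.
#'
#' @param subjects Vector of per-call subject (individual) identifiers.
#' @return Tibble with `fold`, `subject`, and list-columns `test`/`train`
#'   of row indices.
#' @export
split_leave_one_subject <- function(subjects) {
  ids <- unique(subjects)
  if (length(ids) < 2) stop("need at least 2 subjects")
  tibble::tibble(
    fold = seq_along(ids),
    subject = ids,
    test = purrr::map(ids, function(id) which(subjects == id)),
    train = purrr::map(ids, function(id) which(subjects != id)))
}

#' Random non-overlapping folds
#'
#' A permutation draw splits the indices into `k` disjoint test sets of
#' near-equal size covering the data.
#'
#' @param n Number of samples.
#' @param k Number of folds.
#' @return Tibble with `fold` and list-columns `test`/`train`.
#' @export
split_random_folds <- function(n, k = 10) {
  if (n < k) stop("need n >= k")
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  tibble::tibble(
    fold = seq_len(k),
    test = purrr::map(seq_len(k), function(i) sort(perm[starts[i]:ends[i]])),
    train = purrr::map(seq_len(k), function(i) sort(perm[-(starts[i]:ends[i])])))
}

#' Shuffle labels (chance control)
#'
#' Random permutation of the label vector; the label multiset is
#' preserved. A classifier trained on shuffled labels should perform at
#' chance, showing that real performance is not over-learning of an
#' arbitrary set.
#'
#' @param labels Vector.
#' @return Permuted vector.
#' @export
shuffle_labels <- function(labels) {
  labels[sample.int(length(labels))]
}

# downsample the larger classes so all classes match the smallest count
balance_indices <- function(y) {
  counts <- table(y)
  n_min <- min(counts)
  idx <- unlist(lapply(names(counts), function(cl) {
    i <- which(y == cl)
    if (length(i) > n_min) sample(i, n_min) else i
  }), use.names = FALSE)
  sort(idx)
}

#' Ridge-regression classifier
#'
#' Direct normal-equations solve `w = (X'X + lambda I)^-1 X' y` on 0/1
#' targets with an (equally penalized) intercept column; predictions
#' threshold the linear score at 0.5. Training classes are balanced by
#' downsampling the larger class.
#'
#' @param x Numeric matrix (samples x features).
#' @param y Binary labels (factor/character/0-1).
#' @param lambda Ridge penalty (`lambda > 0` guarantees solvability).
#' @param balance Downsample the larger class before fitting.
#' @return An object of class `ridge_model`.
#' @export
ridge_classify <- function(x, y, lambda = 1, balance = TRUE) {
  x <- as.matrix(x)
  f <- as.factor(y)
  if (length(levels(f)) != 2) stop("ridge_classify requires exactly 2 classes")
  if (balance) {
    keep <- balance_indices(f)
    x <- x[keep, , drop = FALSE]
    f <- f[keep]
  }
  yy <- as.numeric(f) - 1
  X <- cbind(1, x)
  w <- tryCatch({
    if (lambda > 0 && ncol(X) > nrow(X)) {
      # identical ridge solution through the dual identity
      # (X'X + lI)^-1 X' = X' (XX' + lI)^-1 ; avoids the p x p Gram matrix
      G <- tcrossprod(X)
      diag(G) <- diag(G) + lambda
      crossprod(X, solve(G, yy))
    } else {
      A <- crossprod(X)
      diag(A) <- diag(A) + lambda
      solve(A, crossprod(X, yy))
    }
  }, error = function(e) {
    stop("normal equations singular; use lambda > 0 (", conditionMessage(e), ")")
  })
  structure(list(coef = drop(w), levels = levels(f), lambda = lambda),
            class = "ridge_model")
}

#' @rdname ridge_classify
#' @param object A `ridge_model`.
#' @param newdata Matrix of samples to classify.
#' @param type `"class"` or `"score"`.
#' @param ... Unused.
#' @export
predict.ridge_model <- function(object, newdata, type = c("class", "score"),
                                ...) {
  type <- match.arg(type)
  s <- drop(cbind(1, as.matrix(newdata)) %*% object$coef)
  if (type == "score") return(s)
  object$levels[as.integer(s >= 0.5) + 1L]
}

#' Support-vector-machine classifier
#'
#' Soft-margin SVM baseline with the quadratic (degree-2 polynomial)
#' kernel for spectrogram inputs or the linear (dot-product) kernel for
#' feature inputs. Training classes are balanced by downsampling, as for
#' ridge.
#'
#' @param x Numeric matrix (samples x features).
#' @param y Binary labels.
#' @param kernel `"quadratic"` or `"linear"`.
#' @param cost Soft-margin cost.
#' @param balance Downsample the larger class before fitting.
#' @return An object of class `svm_model` wrapping the e1071 fit.
#' @export
svm_classify <- function(x, y, kernel = c("quadratic", "linear"), cost = 1,
                         balance = TRUE) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  f <- as.factor(y)
  if (length(levels(f)) != 2) stop("svm_classify requires exactly 2 classes")
  if (balance) {
    keep <- balance_indices(f)
    x <- x[keep, , drop = FALSE]
    f <- droplevels(f[keep])
  }
  fit <- if (kernel == "quadratic") {
    # plain quadratic kernel (u.v + 1)^2, no feature-count rescaling
    e1071::svm(x, f, kernel = "polynomial", degree = 2, coef0 = 1,
               gamma = 1, cost = cost, scale = FALSE)
  } else {
    e1071::svm(x, f, kernel = "linear", cost = cost, scale = FALSE)
  }
  structure(list(fit = fit, levels = levels(f), kernel = kernel),
            class = "svm_model")
}

#' @rdname svm_classify
#' @param object An `svm_model`.
#' @param newdata Matrix of samples to classify.
#' @param ... Unused.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  as.character(predict(object$fit, as.matrix(newdata)))
}

#' Evaluate predictions
#'
#' Percent correct overall and per class for one test set.
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param scheme Optional tag of the CV scheme
#'   (`"leave-one-subject"`, `"random-10-fold"`, `"shuffled-control"`, ...).
#' @param fold Optional fold identifier.
#' @return An object of class `usv_eval`.
#' @export
evaluate_predictions <- function(truth, predicted, scheme = NA_character_,
                                 fold = NA) {
  if (!length(truth)) stop("empty test set")
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  per_class <- tibble::tibble(class = sort(unique(truth))) |>
    dplyr::mutate(
      n = vapply(.data$class, function(cl) sum(truth == cl),
                 numeric(1), USE.NAMES = FALSE),
      correct = vapply(.data$class, function(cl) {
        sum(truth == cl & predicted == cl)
      }, numeric(1), USE.NAMES = FALSE),
      percent_correct = 100 * .data$correct / .data$n)
  structure(
    list(overall = 100 * mean(truth == predicted),
         per_class = per_class, n_test = length(truth),
         scheme = scheme, fold = fold),
    class = "usv_eval")
}

#' @export
print.usv_eval <- function(x, ...) {
  cat("usv_eval: ", round(x$overall, 1), "% correct (n = ", x$n_test,
      if (!is.na(x$scheme)) paste0(", ", x$scheme), ")\n", sep = "")
  for (i in seq_len(nrow(x$per_class))) {
    cat("  ", x$per_class$class[i], ": ",
        round(x$per_class$percent_correct[i], 1), "% (n = ",
        x$per_class$n[i], ")\n", sep = "")
  }
  invisible(x)
}

#' Binomial comparison of an evaluation against chance
#'
#' @param eval An `usv_eval`.
#' @param chance_p Chance probability of a correct classification.
#' @return One-sided exact binomial p-value.
#' @export
eval_above_chance <- function(eval, chance_p = 0.5) {
  correct <- round(eval$overall / 100 * eval$n_test)
  binomial_above_chance(correct, eval$n_test, chance_p)
}
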