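#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation result
#'
#' @param x An `usv_eval`.
#' @param ... Unused.
#' @return Per-class tibble (`class`, `n`, `correct`, `percent_correct`).
#' @export
tidy.usv_eval <- function(x, ...) {
  dplyr::mutate(x$per_class, scheme = x$scheme, fold = x$fold)
}

#' @rdname tidy.usv_eval
#' @return `glance()`: one-row tibble with the overall percent correct.
#' @export
glance.usv_eval <- function(x, ...) {
  tibble::tibble(percent_correct = x$overall, n_test = x$n_test,
                 scheme = x$scheme, fold = x$fold)
}

#' Tidy a ridge classifier
#'
#' @param x A `ridge_model`.
#' @param ... Unused.
#' @return Tibble of terms and coefficients (intercept first).
#' @export
tidy.ridge_model <- function(x, ...) {
  nm <- names(x$coef)
  if (is.null(nm)) nm <- c("(Intercept)", paste0("x", seq_along(x$coef)[-1] - 1))
  tibble::tibble(term = nm, estimate = unname(x$coef))
}

#' @rdname tidy.ridge_model
#' @export
glance.ridge_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_terms = length(x$coef),
                 l2_norm = sqrt(sum(x$coef^2)))
}

#' Summarize a network fit
#'
#' @param x An `usv_network`.
#' @param ... Unused.
#' @return One-row tibble: kind, parameter count, epochs trained, final
#'   loss.
#' @export
glance.usv_network <- function(x, ...) {
  tibble::tibble(
    kind = x$spec$kind, n_parameters = n_parameters(x),
    trained = x$trained, epochs = length(x$loss_trace),
    final_loss = if (length(x$loss_trace)) utils::tail(x$loss_trace, 1)
      else NA_real_)
}

#' Plot a spectrogram
#'
#' @param object An `usv_spectrogram`.
#' @param trans Intensity transform (`"log1p"` or `"identity"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.usv_spectrogram <- function(object, trans = c("log1p", "identity"),
                                     ...) {
  trans <- match.arg(trans)
  df <- expand.grid(freq_khz = object$freq_khz, time_ms = object$time_ms)
  df$value <- as.numeric(object$values)
  if (trans == "log1p") df$value <- log1p(df$value)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$freq_khz,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = if (trans == "log1p")
      "log(1+|S|)" else "|S|") +
    ggplot2::labs(x = "time (ms)", y = "frequency (kHz)") +
    ggplot2::theme_minimal()
}

#' Plot an embedding
#'
#' @param object An `usv_embedding`.
#' @param labels Optional point labels for colouring.
#' @param dims Two dimensions to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.usv_embedding <- function(object, labels = NULL, dims = c(1, 2),
                                   ...) {
  df <- tibble::tibble(x = object$coords[, dims[1]],
                       y = object$coords[, dims[2]])
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_point(alpha = 0.6, size = 0.8)
  } else {
    df$label <- as.factor(labels)
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                     colour = .data$label)) +
      ggplot2::geom_point(alpha = 0.6, size = 0.8)
  }
  p + ggplot2::labs(x = paste0(object$method, " ", dims[1]),
                    y = paste0(object$method, " ", dims[2])) +
    ggplot2::theme_minimal()
}

#' Plot per-class evaluation results
#'
#' @param object An `usv_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.usv_eval <- function(object, ...) {
  df <- object$per_class
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$percent_correct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$overall, linetype = 2) +
    ggplot2::labs(y = "percent correct", x = NULL,
                  subtitle = paste0("overall ", round(object$overall, 1),
                                    "%")) +
    ggplot2::theme_minimal()
}

#' Plot a training loss trace
#'
#' @param model A trained `usv_network`.
#' @return A ggplot of per-epoch mean loss.
#' @export
plot_loss_trace <- function(model) {
  df <- tibble::tibble(epoch = seq_along(model$loss_trace),
                       loss = model$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "mean training loss") +
    ggplot2::theme_minimal()
}
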