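#' Plot a phantom thermogram
#'
#' Raster plot of the temperature field with a thermographic colour scale.
#'
#' @param object A `"phantom_sample"`.
#' @param which `"temperature"` (degC) or `"gray"` (0-255).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phantom_sample <- function(object,
                                    which = c("temperature", "gray"), ...) {
  which <- match.arg(which)
  m <- object[[which]]
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m))
  lab <- if (which == "temperature") "temp (°C)" else "gray"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("phantom (label %+d)", object$label),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' One point per fold and metric, with the across-fold average marked.
#'
#' @param object An `"egsvm_cv"` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.egsvm_cv <- function(object, ...) {
  metrics <- c("sensitivity", "specificity", "accuracy", "ppv", "npv")
  long <- tidyr::pivot_longer(object$folds[c("fold", metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "percent")
  avg <- tidyr::pivot_longer(object$summary, dplyr::everything(),
                             names_to = "metric", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$percent)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_point(data = avg, colour = "red", shape = 18, size = 4) +
    ggplot2::labs(title = sprintf("%d-fold cross-validation", object$k),
                  x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}

#' Plot an entropy-gradient feature vector
#'
#' Shows the two gradient series (normalized and histogram-equalized
#' branches) against window index.
#'
#' @param features Named numeric vector from [extract_features()].
#' @return A ggplot object.
#' @export
plot_feature_vector <- function(features) {
  half <- length(features) / 2
  df <- tibble::tibble(
    k = rep(seq_len(half), 2),
    branch = rep(c("normalized", "equalized"), each = half),
    gradient = as.numeric(features))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$gradient,
                                   colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window index", y = "entropy gradient (bits)") +
    ggplot2::theme_minimal()
}
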