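#' Tidy a fitted SMLR classifier
#'
#' One row per (feature, class) weight, with an indicator for exact zeros.
#'
#' @param x An `smlr_fit`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `class`, `weight`, `nonzero`.
#' @method tidy smlr_fit
#' @export
tidy.smlr_fit <- function(x, ...) {
  W <- x$weights
  tibble::tibble(
    feature = rep(seq_len(nrow(W)), times = ncol(W)),
    class = rep(x$classes, each = nrow(W)),
    weight = as.numeric(W),
    nonzero = as.numeric(W) != 0
  )
}

#' Glance at a fitted SMLR classifier
#'
#' @param x An `smlr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the penalties, the final objective value,
#'   sparsity, sweep count and convergence flag.
#' @method glance smlr_fit
#' @export
glance.smlr_fit <- function(x, ...) {
  tibble::tibble(
    lambda1 = x$lambda1, lambda2 = x$lambda2,
    objective = x$objective_trace[length(x$objective_trace)],
    n_nonzero = sum(x$weights != 0), n_weights = length(x$weights),
    n_sweeps = x$n_sweeps, converged = x$converged
  )
}

#' Tidy a nested cross-validation result
#'
#' @param x An `asl_cv`.
#' @param ... Unused.
#' @return The per-row prediction tibble (`subject`, `condition`,
#'   `predicted`, `correct`).
#' @method tidy asl_cv
#' @export
tidy.asl_cv <- function(x, ...) {
  x$predictions |>
    dplyr::mutate(correct = .data$condition == .data$predicted)
}

#' Glance at a nested cross-validation result
#'
#' @param x An `asl_cv`.
#' @param ... Unused.
#' @return A one-row tibble with the overall accuracy, prediction counts and
#'   median selected penalties.
#' @method glance asl_cv
#' @export
glance.asl_cv <- function(x, ...) {
  tibble::tibble(
    overall_accuracy = x$overall_accuracy,
    n_predictions = nrow(x$predictions),
    n_correct = sum(x$predictions$condition == x$predictions$predicted),
    n_folds = nrow(x$folds),
    lambda1_median = stats::median(x$folds$lambda1),
    lambda2_median = stats::median(x$folds$lambda2)
  )
}

#' Plot a cross-validated confusion matrix
#'
#' Heatmap of counts with the number of correct predictions per cell
#' overlaid.
#'
#' @param object An `asl_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot asl_cv
#' @export
autoplot.asl_cv <- function(object, ...) {
  df <- as.data.frame(object$confusion, responseName = "count") |>
    tibble::as_tibble()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), color = "white") +
    ggplot2::scale_y_discrete(limits = rev(object$classes)) +
    ggplot2::scale_x_discrete(limits = object$classes) +
    ggplot2::labs(x = "predicted condition", y = "true condition",
                  title = sprintf("Overall accuracy %.1f%%",
                                  100 * object$overall_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a scan-count learning curve
#'
#' Accuracy (per class and overall) against the number of scans averaged
#' before classification.
#'
#' @param object An `asl_learning_curve` tibble from [learning_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot asl_learning_curve
#' @export
autoplot.asl_learning_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$accuracy,
                                       color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(object$k)) +
    ggplot2::labs(x = "scans averaged per condition", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' Plot a discrimination map slice
#'
#' Axial slice of a voxel-coefficient (or t-statistic) volume.
#'
#' @param map 3-D array of coefficients.
#' @param slice Axial slice index (default: middle).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_map_slice <- function(map, slice = NULL, title = NULL) {
  d <- dim(map)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2])) |>
    dplyr::mutate(value = map[cbind(.data$i, .data$j, slice)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey95", high = "red",
                                  na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title %||% sprintf("slice z = %d", slice),
                  fill = "coef") +
    ggplot2::theme_void()
}
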