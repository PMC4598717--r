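#' Plot the permutation null against the observed accuracy
#'
#' Histogram of the null distribution of leave-one-out classification
#' accuracy under label permutation, with the observed accuracy marked.
#'
#' @param object A `classification_result` from [permutation_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classification_result <- function(object, ...) {
  if (is.null(object$null_accuracies)) {
    abort("autoplot: result has no permutation null; run permutation_test()")
  }
  df <- tibble(accuracy = object$null_accuracies)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(binwidth = 1 / nrow(object$folds),
                            fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$accuracy, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = "LOOCV accuracy", y = "permutations",
      title = sprintf("Observed %.1f%% (p = %.3g, %d permutations)",
                      100 * object$accuracy, object$p, object$n_perm)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of BPI against performance gain
#'
#' @param records Tibble from [bpi_records()].
#' @return A ggplot object with a least-squares trend line.
#' @export
plot_bpi_gain <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$bpi,
                                        y = .data$performance_gain)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "grey30") +
    ggplot2::labs(x = "Brain Plasticity Index (1 - r)",
                  y = "performance gain (post - pre accuracy)") +
    ggplot2::theme_minimal()
}

#' Axial montage of a statistical map
#'
#' @param map A [stat_map()] or 3-D array.
#' @param slices Indices of axial (third-axis) slices; default picks four
#'   evenly spaced slices.
#' @return A ggplot object.
#' @export
plot_map_slices <- function(map, slices = NULL) {
  vals <- map_values(map)
  d <- dim(vals)
  slices <- slices %||% round(seq(d[3] * 0.25, d[3] * 0.75, length.out = 4))
  df <- purrr::map_dfr(slices, function(z) {
    tibble(x = rep(seq_len(d[1]), d[2]),
           y = rep(seq_len(d[2]), each = d[1]),
           value = as.vector(vals[, , z]), slice = paste0("z = ", z))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice, nrow = 1) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "grey95",
                                  high = "firebrick", na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
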