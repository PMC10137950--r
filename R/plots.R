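# ggplot2 views of cohort measurement tables and statistics reports.

#' Distribution of the 3D femoral and cup offsets
#'
#' @param data A cohort measurement table with `fo3d` and `cup_offset3d`.
#' @param binwidth Histogram bin width in mm.
#' @return A ggplot object.
#' @export
plot_offset_distribution <- function(data, binwidth = 2) {
  long <- data |>
    dplyr::select("fo3d", "cup_offset3d") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "offset",
                        values_to = "mm") |>
    dplyr::mutate(offset = dplyr::recode(.data$offset,
                                         fo3d = "3D femoral offset",
                                         cup_offset3d = "3D cup offset"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mm, fill = .data$offset)) +
    ggplot2::geom_histogram(binwidth = binwidth, alpha = 0.6,
                            position = "identity", colour = "grey30") +
    ggplot2::labs(x = "offset (mm)", y = "hips", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of two cohort parameters with the least-squares line
#'
#' @param data A cohort measurement table.
#' @param x,y Column names (strings).
#' @return A ggplot object.
#' @export
plot_offset_correlation <- function(data, x = "fo3d", y = "cup_offset3d") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = paste(x, "(mm)"), y = paste(y, "(mm)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort statistics report
#'
#' Scatter of the 3D cup offset against the 3D femoral offset, coloured by
#' group, with the identity line (no medialisation) and the least-squares
#' fit.
#'
#' @param object A [cohort_stats()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hip_cohort_stats
#' @export
autoplot.hip_cohort_stats <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fo3d, y = .data$cup_offset3d,
                                  colour = .data[[object$group]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         ggplot2::aes(group = 1), colour = "firebrick") +
    ggplot2::labs(x = "3D femoral offset (mm)", y = "3D cup offset (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
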