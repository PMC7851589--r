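#' Bar chart of windowed substitution density along the replicon
#'
#' Substitutions per coding site in fixed-width windows of distance from the
#' origin, outlier windows greyed out -- the standard way to eyeball a
#' spatial substitution gradient.
#'
#' @param windows Output of [window_aggregate()], optionally with an
#'   `outlier` column.
#' @return A ggplot.
#' @export
plot_window_density <- function(windows) {
  if (is.null(windows$outlier)) windows$outlier <- FALSE
  ggplot2::ggplot(windows,
                  ggplot2::aes(x = .data$midpoint, y = .data$density,
                               fill = .data$outlier)) +
    ggplot2::geom_col(width = (windows$end - windows$start)[1] * 0.9) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey25",
                                          `TRUE` = "grey80"),
                               guide = "none") +
    ggplot2::labs(x = "distance from origin (bp)",
                  y = "substitutions per coding site") +
    ggplot2::theme_minimal()
}

#' Scatter of dN, dS and omega against distance from the origin
#'
#' @param records Selection records ([omega_outlier_filter()] output).
#' @return A ggplot, faceted by statistic, outliers as open grey circles.
#' @export
plot_selection_distance <- function(records) {
  if (is.null(records$outlier)) records$outlier <- FALSE
  long <- records |>
    tidyr::pivot_longer(cols = c("dN", "dS", "omega"),
                        names_to = "statistic", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$distance, y = .data$value,
                                     colour = .data$outlier,
                                     shape = .data$outlier)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey25",
                                            `TRUE` = "grey70"),
                                 guide = "none") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::facet_wrap(~statistic, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "distance from origin (bp)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot a full run
#'
#' @param object An `ori_run`.
#' @param type `"windows"` (default) or `"selection"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ori_run
#' @export
autoplot.ori_run <- function(object, type = c("windows", "selection"), ...) {
  type <- match.arg(type)
  if (type == "windows") {
    plot_window_density(object$windows)
  } else {
    plot_selection_distance(object$selection)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
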