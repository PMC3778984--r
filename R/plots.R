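#' Scatter plot of two cohort measures with Spearman annotation
#'
#' @param table Cohort tibble.
#' @param x,y Column names (strings).
#' @return A ggplot object.
#' @examples
#' plot_cohort_correlation(load_stroke13(), "fcr_paretic", "walking_speed")
#' @export
plot_cohort_correlation <- function(table, x, y) {
  stopifnot(x %in% names(table), y %in% names(table))
  res <- spearman_test(table[[x]], table[[y]])
  ggplot2::ggplot(table, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = 2, colour = "grey40") +
    ggplot2::labs(
      title = sprintf("Spearman rho = %.2f (n = %d, p = %.3g)",
                      res$value, res$n, res$p_raw),
      x = x, y = y
    )
}

#' @rdname cohort_report
#' @param object An `fcr_report`.
#' @param ... Unused.
#' @method autoplot fcr_report
#' @export
autoplot.fcr_report <- function(object, ...) {
  d <- object$correlations %>%
    filter(!is.na(.data$value)) %>%
    mutate(pair = paste(.data$var1, "~", .data$var2),
           significant = .data$p_corrected < 0.05)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$pair, .data$value),
                                  y = .data$value,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Spearman rho",
                  fill = "corrected p < 0.05") +
    ggplot2::ylim(-1, 1)
}
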