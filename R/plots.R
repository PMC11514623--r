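#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient plot of a MIIV-2SLS fit
#'
#' Dot-and-whisker plot of the free parameters (analysis scale), faceted by
#' parameter kind, with BCa intervals when the fit was bootstrapped.
#'
#' @param object A `miiv_fit`.
#' @param scale `"analysis"` or `"original"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot miiv_fit
#' @export
autoplot.miiv_fit <- function(object, scale = "analysis", ...) {
  td <- tidy(object, scale = scale)
  td$term <- factor(td$term, levels = rev(td$term))
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$kind), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = sprintf("Estimate (%s scale)", scale), y = NULL) +
    ggplot2::theme_minimal()
  if (!all(is.na(td$conf.low))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high), height = 0.2)
  }
  p
}

#' Correlation heat map of the indicator variables
#'
#' @param data Cohort data frame (numeric columns).
#' @return A ggplot tile map of pairwise-complete Pearson correlations.
#' @export
plot_correlations <- function(data) {
  R <- correlation_matrix(data)
  df <- tibble::as_tibble(as.data.frame(as.table(R), stringsAsFactors = FALSE))
  names(df) <- c("x", "y", "r")
  df$x <- factor(df$x, levels = colnames(R))
  df$y <- factor(df$y, levels = rev(colnames(R)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}
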