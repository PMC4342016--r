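#' Plotting helpers
#'
#' Thin ggplot2 layers over the result tibbles; every plot function returns
#' a ggplot object the caller can restyle.
#'
#' @name plots
NULL

#' @export
autoplot.ses_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data$ses,
                               colour = .data$classification)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, height = 0, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "SES",
                  title = paste0("Standardized effect sizes (",
                                 attr(object, "level"), "-PD)")) +
    ggplot2::theme_minimal()
}

#' Scree plot with the broken-stick expectation
#'
#' @param x a `pca_corr`.
#' @param ... unused.
#' @export
autoplot.pca_corr <- function(x, ...) {
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$explained), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$broken_stick), colour = "red") +
    ggplot2::geom_point(ggplot2::aes(y = .data$broken_stick), colour = "red") +
    ggplot2::labs(y = "Proportion of variance",
                  title = "Scree plot vs broken stick") +
    ggplot2::theme_minimal()
}

#' Bar chart of variation-partitioning fractions
#'
#' @param x a `varpart_rao`.
#' @param ... unused.
#' @export
autoplot.varpart_rao <- function(x, ...) {
  df <- dplyr::filter(tidy(x), .data$component != "total_explained")
  df$component <- factor(df$component, levels = rev(df$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$adj_r2, y = .data$component)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Adjusted R²", y = NULL,
                  title = "Variation partitioning of beta-diversity") +
    ggplot2::theme_minimal()
}

#' Averaged coefficients with adjusted-SE error bars
#'
#' @param x an `averaged_model`.
#' @param ... unused.
#' @export
autoplot.averaged_model <- function(x, ...) {
  df <- tidy(x)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$adjusted_se,
                   xmax = .data$estimate + 1.96 * .data$adjusted_se)) +
    ggplot2::labs(x = "Averaged estimate", y = NULL) +
    ggplot2::theme_minimal()
}
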