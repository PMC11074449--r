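#' Plot methods for tumorlr results
#'
#' `autoplot()` renders each result type with ggplot2: per-locus log10(LR)
#' bars for an LR result, a heatmap for a parameter grid, a line for an
#' interval LR, grouped boxplots for a non-contributor test, a Q-Q scatter
#' for the gamma diagnostic, and the log-height-vs-size scatter with the
#' fitted line for a degradation fit.
#'
#' @param object A tumorlr result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name tumorlr-autoplot
NULL

#' @rdname tumorlr-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tlr_lr <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$locus, .data$log10_lr),
                                  y = .data$log10_lr)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "per-locus log10(LR)",
                  title = sprintf("log10(LR) = %.2f", object$log10_lr))
}

#' @rdname tumorlr-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tlr_grid <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$phi, y = .data$mxn, fill = .data$log10_lr)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = expression(phi), y = expression(M[xn]),
                  fill = "log10(LR)")
}

#' @rdname tumorlr-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tlr_interval <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$mxn, y = .data$log10_lr)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(M[xn]), y = "log10(LR)")
}

#' @rdname tumorlr-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tlr_noncontrib <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(signif(.data$mxn, 3)), y = .data$log10_lr)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(M[xn]), y = "log10(LR)",
                  title = "Non-contributor (Hd-true) test")
}

#' @rdname tumorlr-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tlr_qq <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$theoretical, y = .data$empirical)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "theoretical gamma quantile", y = "locus total height (RFU)")
}

#' @rdname tumorlr-autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.tlr_degfit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean_size, y = log(.data$mean_height))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = log(object$per_base_slope),
                         intercept = object$intercept, linetype = 2) +
    ggplot2::labs(x = "mean fragment size (bp)", y = "log mean peak height")
}
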