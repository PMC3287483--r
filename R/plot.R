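#' Plot the tag-density template
#'
#' @param object A [build_profile()] template.
#' @param ... Unused.
#' @return A ggplot: template density against the offset from the site,
#'   with the peak offset marked.
#' @export
autoplot.tag_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$density)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$mode, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = "distance from binding site (bp)",
      y = "tag-start probability",
      title = sprintf("Single-site tag density (L = %.0f, peak at %d bp)",
                      object$L, as.integer(object$mode))) +
    ggplot2::theme_minimal()
}

#' Plot a per-region site fit
#'
#' @param object A [fit_region()] result.
#' @param ... Unused.
#' @return A ggplot of the goodness-of-fit curves for both strands with
#'   detected sites marked.
#' @export
autoplot.site_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$pos, y = .data$r2,
                                    colour = .data$strand)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "genomic position (bp)", y = expression(R^2),
                  colour = "strand",
                  title = sprintf("%s:%d-%d", object$region$chrom,
                                  object$region$start,
                                  object$region$end)) +
    ggplot2::theme_minimal()
  if (nrow(object$sites)) {
    p <- p + ggplot2::geom_vline(data = object$sites,
                                 ggplot2::aes(xintercept = .data$pos),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a resolution report
#'
#' @param object A [resolution_metrics()] result.
#' @param binwidth Histogram bin width (bp).
#' @param ... Unused.
#' @return A ggplot histogram of detected-site-to-reference distances.
#' @export
autoplot.resolution_report <- function(object, binwidth = 5, ...) {
  df <- dplyr::filter(object$distances, is.finite(.data$distance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "distance to nearest reference center (bp)",
                  y = "sites") +
    ggplot2::theme_minimal()
}
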