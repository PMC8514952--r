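#' Plot an RSS position weight matrix
#'
#' Stacked per-position nucleotide frequencies, the tabular equivalent of a
#' sequence logo.
#'
#' @param pwm an [build_pwm()] result.
#' @return a ggplot object.
#' @export
plot_pwm <- function(pwm) {
  stopifnot(inherits(pwm, "rss_pwm"))
  df <- as.data.frame(as.table(unclass(pwm)))
  names(df) <- c("base", "position", "frequency")
  df$position <- as.integer(df$position)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$frequency,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(pwm))) +
    ggplot2::labs(
      title = sprintf("RSS %s position weight matrix (n = %d)",
                      attr(pwm, "element"), attr(pwm, "n")),
      x = "position", y = "relative frequency", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a locus gene map
#'
#' Genes along the locus coordinate, colored by functionality class, with
#' orientation shown by point shape, in the style of a locus organization
#' diagram.
#'
#' @param report a `tr_locus_report` (or an annotation tibble).
#' @return a ggplot object.
#' @export
plot_locus_map <- function(report) {
  genes <- if (inherits(report, "tr_locus_report")) report$annotations else report
  if (nrow(genes) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty locus"))
  }
  genes$mid <- (genes$start + genes$end) / 2
  ggplot2::ggplot(genes, ggplot2::aes(x = .data$mid / 1000, y = .data$type)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$functionality,
                                     shape = .data$strand), size = 2) +
    ggplot2::scale_shape_manual(values = c("+" = 24, "-" = 25)) +
    ggplot2::labs(
      title = if (inherits(report, "tr_locus_report")) {
        sprintf("%s locus map (%s)", report$locus_name, report$organization)
      } else "locus map",
      x = "position (kb)", y = NULL, color = "class", shape = "strand"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @method autoplot tr_locus_report
#' @export
autoplot.tr_locus_report <- function(object, ...) plot_locus_map(object)

#' @method autoplot rss_pwm
#' @export
autoplot.rss_pwm <- function(object, ...) plot_pwm(object)
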