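#' Plot the read length distribution
#'
#' @param ld Tibble from [length_distribution()].
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(ld) {
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "read length (nt)", y = "genome-mapping reads") +
    ggplot2::theme_minimal()
}

#' Plot the category composition of genome-mapping reads
#'
#' @param fractions Tibble from [pie_fractions()].
#' @return A ggplot pie chart.
#' @export
plot_pie <- function(fractions) {
  fr <- dplyr::filter(fractions, .data$count > 0)
  ggplot2::ggplot(fr, ggplot2::aes(x = "", y = .data$percent,
                                   fill = .data$category)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "category") +
    ggplot2::theme_void()
}

#' Plot a strand-specific coverage profile
#'
#' Plus-strand coverage is drawn upward in blue, minus-strand coverage
#' downward in red, along the reference coordinate.
#'
#' @param plus,minus Coverage tracks ([coverage_track()]) for the two
#'   strands of the same reference.
#' @param ylab Y-axis label (defaults to the track normalization).
#' @return A ggplot object.
#' @export
plot_coverage <- function(plus, minus, ylab = attr(plus, "normalization")) {
  df <- dplyr::bind_rows(
    dplyr::mutate(plus, signed = .data$value),
    dplyr::mutate(minus, signed = -.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$signed,
                                   fill = .data$strand)) +
    ggplot2::geom_col(width = attr(plus, "bin_size")) +
    ggplot2::scale_fill_manual(values = c(`+` = "blue", `-` = "red")) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = paste0(plus$ref_name[1], " (nt)"), y = ylab,
                  fill = "strand") +
    ggplot2::theme_minimal()
}

#' Plot an overlap-size histogram
#'
#' @param histogram Tibble from [overlap_histogram()].
#' @return A ggplot object highlighting the 10-nt overlap.
#' @export
plot_overlap_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = .data$overlap, y = .data$percent,
                               fill = .data$overlap == 10)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(x = "5'-overlap (nt)", y = "% of overlaps") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot the overlap histogram of a ping-pong analysis
#'
#' @param object An `srna_pingpong` object.
#' @param feature Feature to plot; defaults to the highest-z feature.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.srna_pingpong <- function(object, feature = NULL, ...) {
  if (is.null(feature)) {
    z <- ifelse(is.na(object$stats$z), -Inf, object$stats$z)
    feature <- object$stats$ID[which.max(z)]
  }
  plot_overlap_histogram(object$histograms[[feature]]) +
    ggplot2::ggtitle(feature)
}

# Save a figure together with the numeric series behind it. The sidecar
# TSV, not the image, is the test surface.
save_figure <- function(plot, data, out_dir, name) {
  sidecar <- file.path(out_dir, paste0(name, ".tsv"))
  write_table(data, sidecar)
  img <- file.path(out_dir, paste0(name, ".png"))
  suppressMessages(ggplot2::ggsave(img, plot, width = 7, height = 4, dpi = 96))
  invisible(c(figure = img, sidecar = sidecar))
}
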