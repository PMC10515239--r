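# ggplot2 visualisations for the package's result objects

#' Plot PAV segment positions along each genome
#'
#' @param x A `pav_result` from [pav_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_pav_segments <- function(x, ...) {
  stopifnot(inherits(x, "pav_result"))
  ggplot2::ggplot(x$segments,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$genome)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$length / 1e3),
                        alpha = 0.6, shape = 108) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = NULL, size = "length (kb)",
                  title = "Genome-specific (PAV) segments") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pav_result <- function(object, ...) plot_pav_segments(object, ...)

#' Plot segment length distribution
#'
#' @param x A `pav_result`.
#' @param binwidth Histogram bin width in bp.
#' @return A ggplot.
#' @export
plot_segment_lengths <- function(x, binwidth = 250) {
  stopifnot(inherits(x, "pav_result"))
  ggplot2::ggplot(x$segments, ggplot2::aes(.data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::facet_wrap(~genome) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "segment length (bp)", y = "segments") +
    ggplot2::theme_minimal()
}

#' Plot a Ks density with its detected modes
#'
#' @param x A `ks_peaks` object from [ks_distribution_peaks()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_ks_distribution <- function(x, ...) {
  stopifnot(inherits(x, "ks_peaks"))
  ggplot2::ggplot(x$density, ggplot2::aes(.data$ks, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = x$peaks,
                        ggplot2::aes(xintercept = .data$mode),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Ks", y = "density",
                  title = "Synonymous divergence of paralog pairs") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ks_peaks <- function(object, ...) plot_ks_distribution(object, ...)

#' Plot a k-mer depth histogram
#'
#' @param hist A [kmer_histogram()].
#' @param max_depth Truncate the x axis (default 3x the histogram peak).
#' @return A ggplot.
#' @export
plot_kmer_histogram <- function(hist, max_depth = NULL) {
  stopifnot(inherits(hist, "kmer_histogram"))
  if (is.null(max_depth)) {
    max_depth <- 3 * hist$depth[which.max(hist$species)]
  }
  df <- dplyr::filter(as_tibble(hist), .data$depth <= max_depth)
  ggplot2::ggplot(df, ggplot2::aes(.data$depth, .data$species)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "k-mer depth", y = "distinct k-mer species",
                  title = sprintf("%d-mer depth histogram", attr(hist, "k"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.kmer_histogram <- function(object, ...) plot_kmer_histogram(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
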