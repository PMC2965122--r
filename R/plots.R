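# ggplot2 figures for the evaluation results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Barcoding-gap scatter plot
#'
#' Plots, per species, the minimum interspecific against the maximum
#' intraspecific K2P distance. Points above the 1:1 line are discriminated
#' under the strict criterion; points on or below it are not.
#'
#' @param gap_stats Output of [species_gap_stats()] (may cover several
#'   loci if a `locus` column is present).
#' @return A ggplot.
#' @export
plot_barcode_gap <- function(gap_stats) {
  df <- gap_stats[gap_stats$evaluable, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$max_intra,
                                        y = .data$min_inter,
                                        colour = .data$discriminated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Maximum intraspecific K2P distance",
                  y = "Minimum interspecific K2P distance",
                  colour = "Discriminated") +
    ggplot2::theme_minimal()
  if ("locus" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~locus, scales = "free")
  }
  p
}

#' Inter/intraspecific divergence ratio bars
#'
#' Per-species ratio of mean interspecific to mean intraspecific K2P
#' distance; large ratios indicate a usable barcoding gap.
#'
#' @inheritParams plot_barcode_gap
#' @return A ggplot.
#' @export
plot_divergence_ratios <- function(gap_stats) {
  df <- gap_stats[!is.na(gap_stats$ratio), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$ratio)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Mean inter / mean intra K2P distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if ("locus" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~locus, scales = "free_y")
  }
  p
}

#' Ordination plot of a PCoA result
#'
#' @param object A `pcoa_result` from [pcoa_bands()].
#' @param species_map Optional species map; when given, points are
#'   coloured by `colour_by`.
#' @param axes Which two axes to show.
#' @param colour_by `"region"` or `"species"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, species_map = NULL,
                                 axes = c(1, 2), colour_by = "region", ...) {
  df <- object$coordinates
  ax <- paste0("axis_", axes)
  if (!all(ax %in% names(df))) stop("requested axes not available", call. = FALSE)
  if (!is.null(species_map)) {
    df <- dplyr::left_join(df, species_map, by = c(accession = "accession_id"))
  }
  lab <- function(i) sprintf("Axis %d (%.1f%%)", axes[i],
                             object$pct_variance[axes[i]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]],
                                        y = .data[[ax[2]]])) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
  if (!is.null(species_map) && colour_by %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]),
                            size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
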