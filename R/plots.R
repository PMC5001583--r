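#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   geom_abline scale_x_continuous scale_y_continuous labs theme_minimal
#'   scale_fill_viridis_c scale_colour_manual geom_histogram facet_wrap
NULL

#' Plot a coverage track
#'
#' Per-base coverage is averaged into fixed-width windows before plotting so
#' megabase tracks stay light.
#'
#' @param object A [coverage_track()].
#' @param window Averaging window in bp.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_track
#' @export
autoplot.coverage_track <- function(object, window = 1000L, ...) {
  L <- length(object$values)
  n <- L %/% window
  cc <- c(0, cumsum(object$values))
  idx <- seq_len(n)
  df <- tibble(pos = (idx - 0.5) * window,
               coverage = (cc[idx * window + 1] - cc[(idx - 1) * window + 1]) /
                 window)
  ggplot(df, aes(x = .data$pos, y = .data$coverage)) +
    geom_line(linewidth = 0.3) +
    labs(x = sprintf("%s position (bp)", object$contig),
         y = "mean coverage") +
    theme_minimal()
}

#' Scatter plot of per-HMR read counts in the two host contexts
#'
#' The classification scatter: depth-normalised counts per union HMR,
#' coloured by shared / species-specific label, on log10 axes with the
#' identity line.
#'
#' @param object An [classify_hmrs()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hmr_classification
#' @export
autoplot.hmr_classification <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$n_a + 1, y = .data$n_b_normalized + 1,
                 colour = .data$label)) +
    geom_point(alpha = 0.7, size = 1.4) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    scale_x_continuous(trans = "log10") +
    scale_y_continuous(trans = "log10") +
    scale_colour_manual(values = c(shared = "grey40", A_specific = "#c0392b",
                                   B_specific = "#2980b9")) +
    labs(x = "BioCAP reads, context A (+1)",
         y = "BioCAP reads, context B, depth-normalised (+1)",
         colour = NULL) +
    theme_minimal()
}

#' Heatmap of a centred, length-ranked signal matrix
#'
#' @param object An [aggregate_matrix()] result.
#' @param trans Fill transform (default `"sqrt"` to tame peak summits).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signal_matrix
#' @export
autoplot.signal_matrix <- function(object, trans = "sqrt", ...) {
  m <- unclass(object)
  flank <- attr(object, "flank")
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), bin = seq_len(ncol(m)))
  df$signal <- as.vector(t(m))
  df$pos <- (df$bin - 0.5) / ncol(m) * 2 * flank - flank
  ggplot(df, aes(x = .data$pos, y = -.data$row, fill = .data$signal)) +
    geom_raster() +
    scale_fill_viridis_c(trans = trans, na.value = "grey90") +
    labs(x = "distance from HMR centre (bp)",
         y = "HMRs (ranked by length)", fill = "coverage") +
    theme_minimal()
}

#' Metaplot of mean signal around interval centres
#'
#' @param mat An [aggregate_matrix()] result.
#' @return A ggplot object of the per-bin column means.
#' @export
plot_metaplot <- function(mat) {
  stopifnot(inherits(mat, "signal_matrix"))
  flank <- attr(mat, "flank")
  mp <- metaplot(mat)
  df <- tibble(pos = (seq_along(mp) - 0.5) / length(mp) * 2 * flank - flank,
               signal = mp)
  ggplot(df, aes(x = .data$pos, y = .data$signal)) +
    geom_line() +
    labs(x = "distance from HMR centre (bp)", y = "mean coverage") +
    theme_minimal()
}

#' Frequency distributions of HMR sequence features by class
#'
#' @param features A [hmr_feature_table()] result (optionally with the
#'   shifted-background rows appended).
#' @param feature Which column to plot.
#' @param bins Histogram bins.
#' @return A ggplot object faceted by feature class label.
#' @export
plot_feature_distribution <- function(features,
                                      feature = c("cpg_per_100bp",
                                                  "gc_fraction"),
                                      bins = 30L) {
  feature <- match.arg(feature)
  ggplot(features, aes(x = .data[[feature]])) +
    geom_histogram(bins = bins, fill = "grey30") +
    facet_wrap(~label, scales = "free_y") +
    labs(x = feature, y = "HMRs") +
    theme_minimal()
}
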