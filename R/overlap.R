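#' Annotation parameters
#'
#' @param tss_window Half-width in bp of the promoter window around a TSS;
#'   the window is inclusive of both endpoints, so the default 500 gives a
#'   1001-position footprint (TSS +/- 500 bp).
#' @return A list of class `annotation_params`.
#' @export
annotation_params <- function(tss_window = 500L) {
  stopifnot_scalar_number(tss_window, "tss_window", min = 0)
  structure(list(tss_window = as.integer(tss_window)),
            class = "annotation_params")
}

#' Partition HMRs by TSS proximity
#'
#' An HMR is TSS-associated when it overlaps `[tss - w, tss + w + 1)` for any
#' TSS (any-overlap; strand does not alter the window); otherwise it is
#' distal. Every HMR lands in exactly one group.
#'
#' @param hmrs HMR interval tibble.
#' @param tss Tibble of TSS positions with columns `contig`, `pos` (and
#'   optionally `strand`, unused for the window).
#' @param params An [annotation_params()].
#' @return `hmrs` with an added logical column `tss_associated`.
#' @export
classify_tss_proximity <- function(hmrs, tss, params = annotation_params()) {
  w <- params$tss_window
  windows <- tibble(contig = tss$contig,
                    start = pmax(0, tss$pos - w),
                    end = tss$pos + w + 1)
  out <- hmrs
  out$tss_associated <- interval_overlaps_any(hmrs, windows)
  out
}

#' Species-specific vs shared transcription factor binding
#'
#' Peaks are compared across the two host contexts factor by factor: a peak
#' is context-specific when it overlaps (>= 1 bp) no peak of the same factor
#' in the other context, and shared otherwise. Within each context and
#' factor, the shared and specific subsets partition the input.
#'
#' @param peaks_a,peaks_b TF peak tibbles with columns `contig`, `start`,
#'   `end`, `factor` for contexts A and B.
#' @return A tibble of all peaks with added columns `context` (`"A"`/`"B"`)
#'   and `status` (`"specific"`/`"shared"`).
#' @export
species_specific_peaks <- function(peaks_a, peaks_b) {
  classify_one <- function(own, other, ctx) {
    if (nrow(own) == 0L) {
      own$context <- character(0)
      own$status <- character(0)
      return(own)
    }
    spec <- rep(TRUE, nrow(own))
    for (fac in unique(own$factor)) {
      oi <- which(own$factor == fac)
      spec[oi] <- !interval_overlaps_any(own[oi, ],
                                         other[other$factor == fac, ])
    }
    own$context <- ctx
    own$status <- ifelse(spec, "specific", "shared")
    own
  }
  bind_rows(classify_one(peaks_a, peaks_b, "A"),
            classify_one(peaks_b, peaks_a, "B"))
}

#' Multi-way overlap (Venn) summary of HMRs against feature sets
#'
#' For each target interval, a membership vector records which of the (up to
#' four) named feature sets it overlaps by >= 1 bp. Pattern counts sum to the
#' number of targets; the headline percentage of targets overlapping at least
#' one feature set is rounded half-up to an integer, the convention used for
#' reported overlap figures.
#'
#' @param targets Non-empty interval tibble (e.g. the context-specific HMRs).
#' @param feature_sets Named list of 1 to 4 interval tibbles (e.g. the
#'   context-specific peaks of each TF).
#' @return A list of class `overlap_summary`: `patterns` (one row per
#'   membership pattern with its count), `n_targets`, `n_any`, `percent_any`.
#' @export
multiway_overlap_summary <- function(targets, feature_sets) {
  if (nrow(targets) == 0L) abort("`targets` must be non-empty")
  if (length(feature_sets) < 1L || length(feature_sets) > 4L ||
      is.null(names(feature_sets))) {
    abort("`feature_sets` must be a named list of 1 to 4 interval sets")
  }
  member <- purrr::map_dfc(feature_sets,
                           ~ interval_overlaps_any(targets, .x))
  any_hit <- rowSums(as.matrix(member)) > 0
  patterns <- member |>
    dplyr::count(dplyr::across(dplyr::everything()), name = "count") |>
    arrange(dplyr::desc(.data$count))
  structure(list(patterns = patterns,
                 n_targets = nrow(targets),
                 n_any = sum(any_hit),
                 percent_any = round_half_up(100 * mean(any_hit))),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> %d/%d targets (%d%%) overlap >= 1 feature set\n",
              x$n_any, x$n_targets, x$percent_any))
  print(x$patterns)
  invisible(x)
}

#' Centred, length-ranked signal matrix for heatmaps and metaplots
#'
#' Each interval contributes one row of mean coverage in `bins` equal windows
#' spanning `[midpoint - flank, midpoint + flank)`; rows are ordered by
#' interval length (descending, ties by start), the layout used for
#' centre-aligned, length-ranked heatmaps. Bins extending past a contig edge
#' are set to `NA`. Column means (NA-removed) give the metaplot vector.
#'
#' @param intervals Interval tibble.
#' @param coverage A [coverage_track()].
#' @param flank Half-width of the plotted span in bp (>= 0).
#' @param bins Number of equal-width columns (>= 1).
#' @return A numeric matrix of class `signal_matrix` (rows named by interval)
#'   with attributes `flank`, `bins` and `intervals` (the row-ordered interval
#'   tibble).
#' @export
aggregate_matrix <- function(intervals, coverage, flank = 5000L, bins = 100L) {
  stopifnot(inherits(coverage, "coverage_track"))
  stopifnot_scalar_number(bins, "bins", min = 1)
  stopifnot_scalar_number(flank, "flank", min = 0)
  ord <- order(-(intervals$end - intervals$start), intervals$start)
  intervals <- intervals[ord, ]
  L <- length(coverage$values)
  cc <- c(0, cumsum(coverage$values))
  edges <- round(seq(0, 2 * flank, length.out = bins + 1))
  mat <- matrix(NA_real_, nrow = nrow(intervals), ncol = bins)
  for (i in seq_len(nrow(intervals))) {
    mid <- floor((intervals$start[i] + intervals$end[i]) / 2)
    lo <- mid - flank + edges[-length(edges)]
    hi <- mid - flank + edges[-1]
    ok <- lo >= 0 & hi <= L & hi > lo
    mat[i, ok] <- (cc[hi[ok] + 1] - cc[lo[ok] + 1]) / (hi[ok] - lo[ok])
  }
  rownames(mat) <- if ("name" %in% names(intervals)) intervals$name else NULL
  structure(mat, flank = flank, bins = bins, intervals = intervals,
            class = c("signal_matrix", "matrix", "array"))
}

#' Metaplot vector of a signal matrix
#' @param mat A [aggregate_matrix()] result.
#' @return Numeric vector of per-bin column means (NA-removed).
#' @export
metaplot <- function(mat) {
  stopifnot(inherits(mat, "signal_matrix"))
  colMeans(unclass(mat), na.rm = TRUE)
}

#' Fold-change distributions at vs away from TSSs, with Welch's t test
#'
#' Splits per-HMR fold changes (from differential classification) into
#' TSS-associated and distal groups and compares them with a two-sided
#' Welch's t test (unequal variances, Welch-Satterthwaite degrees of
#' freedom).
#'
#' @param hmrs Tibble with `fold` and logical `tss_associated` columns (from
#'   [classify_hmrs()] piped through [classify_tss_proximity()]), optionally
#'   pre-filtered to one label.
#' @param log2_fold Compare log2 folds (default) rather than raw ratios.
#' @return A list of class `welch_comparison`: `groups` (per-group n, mean,
#'   sd, median of the compared values), `statistic`, `df`, `p_value`, and
#'   the underlying `data`.
#' @export
fold_change_by_location <- function(hmrs, log2_fold = TRUE) {
  if (!all(c("fold", "tss_associated") %in% names(hmrs))) {
    abort("`hmrs` needs `fold` and `tss_associated` columns")
  }
  val <- if (log2_fold) log2(hmrs$fold) else hmrs$fold
  x <- val[hmrs$tss_associated]
  y <- val[!hmrs$tss_associated]
  if (length(x) < 2L || length(y) < 2L) {
    abort("both groups need at least 2 HMRs")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    abort("both groups are constant; Welch's t is undefined")
  }
  ht <- stats::t.test(x, y)
  groups <- tibble(
    group = c("tss", "distal"), n = c(length(x), length(y)),
    mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)),
    median = c(stats::median(x), stats::median(y))
  )
  structure(list(groups = groups,
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 data = tibble(group = rep(c("tss", "distal"),
                                           c(length(x), length(y))),
                               value = c(x, y))),
            class = "welch_comparison")
}

#' @export
print.welch_comparison <- function(x, ...) {
  cat(sprintf("<welch_comparison> t = %.4g, df = %.4g, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$groups)
  invisible(x)
}
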