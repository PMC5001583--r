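#' Per-CpG methylation percentage
#'
#' Adds `percent` = 100 * meth / (meth + unmeth) to a call table. CpGs with
#' zero total depth are undefined and are dropped with a warning.
#'
#' @param calls Tibble with `meth_count` and `unmeth_count` columns.
#' @return The input tibble (minus zero-depth rows) with a `percent` column
#'   in `[0, 100]`.
#' @export
methylation_percent <- function(calls) {
  depth <- calls$meth_count + calls$unmeth_count
  if (any(depth == 0)) {
    warn(sprintf("%d CpG(s) with zero depth excluded", sum(depth == 0)))
    calls <- calls[depth > 0, ]
    depth <- depth[depth > 0]
  }
  calls$percent <- 100 * calls$meth_count / depth
  calls
}

#' Summarise bisulfite calls over amplicons
#'
#' @param calls Call tibble (`contig`, `position`, `meth_count`,
#'   `unmeth_count`).
#' @param amplicons Interval tibble of amplicons.
#' @return A list of class `amplicon_summary`: `per_cpg` (per-CpG
#'   percentages tagged by amplicon) and `summary` (per-amplicon `n_cpgs`,
#'   `total_depth`, `mean_percent` -- the unweighted mean of per-CpG
#'   percentages).
#' @export
summarize_amplicons <- function(calls, amplicons) {
  validate_intervals(amplicons, "amplicons")
  nm <- if ("name" %in% names(amplicons) && !anyNA(amplicons$name)) {
    amplicons$name
  } else sprintf("amp_%02d", seq_len(nrow(amplicons)))
  per_cpg <- purrr::map_dfr(seq_len(nrow(amplicons)), function(i) {
    sub <- calls[calls$contig == amplicons$contig[i] &
                   calls$position >= amplicons$start[i] &
                   calls$position < amplicons$end[i], ]
    if (nrow(sub) == 0L) return(NULL)
    sub <- methylation_percent(sub)
    sub$amplicon <- nm[i]
    sub
  })
  if (is.null(per_cpg) || nrow(per_cpg) == 0L) {
    per_cpg <- tibble(contig = character(), position = numeric(),
                      meth_count = integer(), unmeth_count = integer(),
                      percent = numeric(), amplicon = character())
  }
  summary <- purrr::map_dfr(seq_len(nrow(amplicons)), function(i) {
    sub <- per_cpg[per_cpg$amplicon == nm[i], ]
    tibble(amplicon = nm[i], contig = amplicons$contig[i],
           start = amplicons$start[i], end = amplicons$end[i],
           n_cpgs = nrow(sub),
           total_depth = sum(sub$meth_count + sub$unmeth_count),
           mean_percent = if (nrow(sub) > 0) mean(sub$percent) else NA_real_)
  })
  structure(list(per_cpg = per_cpg, summary = summary),
            class = "amplicon_summary")
}

#' Bisulfite conversion-efficiency QC from spike-in controls
#'
#' Pooled over the fully unmethylated spike-in, the conversion rate is the
#' fraction of reads correctly read as unmethylated; pooled over the fully
#' methylated spike-in, the unmethylated fraction proxies over-conversion
#' (inappropriate deamination of methylated cytosines). A QC flag is raised
#' when conversion falls below `threshold`.
#'
#' @param unmeth_spikein,meth_spikein Call tibbles for the unmethylated and
#'   methylated spike-in controls (non-empty, positive total depth).
#' @param threshold Minimum acceptable conversion rate (default 0.98, a
#'   conventional QC bound).
#' @return A one-row tibble: `conversion`, `overconversion_proxy`,
#'   `n_cpgs_unmeth`, `n_cpgs_meth`, `qc_pass`.
#' @export
conversion_efficiency <- function(unmeth_spikein, meth_spikein,
                                  threshold = 0.98) {
  for (nm in c("unmeth_spikein", "meth_spikein")) {
    x <- get(nm)
    if (nrow(x) == 0L || sum(x$meth_count + x$unmeth_count) == 0) {
      abort(sprintf("`%s` must be non-empty with positive depth", nm))
    }
  }
  conv <- sum(unmeth_spikein$unmeth_count) /
    sum(unmeth_spikein$meth_count + unmeth_spikein$unmeth_count)
  over <- sum(meth_spikein$unmeth_count) /
    sum(meth_spikein$meth_count + meth_spikein$unmeth_count)
  if (conv < threshold) {
    warn(sprintf("bisulfite conversion %.4f below QC threshold %.2f",
                 conv, threshold))
  }
  tibble(conversion = conv, overconversion_proxy = over,
         n_cpgs_unmeth = nrow(unmeth_spikein),
         n_cpgs_meth = nrow(meth_spikein),
         qc_pass = conv >= threshold)
}

#' Average amplicon summaries across biological replicates
#'
#' Per-CpG percentages are averaged unweighted across replicates; replicates
#' must cover identical amplicons and CpG positions.
#'
#' @param rep_summaries List of [summarize_amplicons()] results.
#' @return An `amplicon_summary` with averaged per-CpG percentages.
#' @export
average_replicates <- function(rep_summaries) {
  stopifnot(length(rep_summaries) >= 1L,
            all(vapply(rep_summaries, inherits, logical(1),
                       "amplicon_summary")))
  key <- function(s) paste(s$per_cpg$amplicon, s$per_cpg$contig,
                           s$per_cpg$position)
  k1 <- key(rep_summaries[[1]])
  for (s in rep_summaries[-1]) {
    if (!identical(key(s), k1)) {
      abort("replicates must cover identical amplicons and CpG positions")
    }
  }
  per_cpg <- rep_summaries[[1]]$per_cpg
  per_cpg$percent <- rowMeans(
    vapply(rep_summaries, function(s) s$per_cpg$percent,
           numeric(nrow(per_cpg))))
  per_cpg$meth_count <- per_cpg$unmeth_count <- NA_integer_
  summary <- per_cpg |>
    group_by(.data$amplicon) |>
    summarise(n_cpgs = n(), mean_percent = mean(.data$percent),
              .groups = "drop") |>
    left_join(rep_summaries[[1]]$summary[, c("amplicon", "contig", "start", "end")],
              by = "amplicon")
  structure(list(per_cpg = per_cpg, summary = summary),
            class = "amplicon_summary")
}
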