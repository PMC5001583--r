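#' Parameters for shared vs species-specific HMR classification
#'
#' @param fold_threshold Fold-change rule: an HMR is called context-specific
#'   when its depth-normalised BioCAP read counts differ by more than this
#'   factor (> 1; default 2, the greater-than-2-fold rule).
#' @param pseudocount Reads added to both normalised counts before the ratio,
#'   preventing infinite folds at zero-count HMRs while perturbing large
#'   counts negligibly.
#' @return A list of class `differential_params`.
#' @export
differential_params <- function(fold_threshold = 2.0, pseudocount = 1.0) {
  if (fold_threshold <= 1) abort("`fold_threshold` must be > 1")
  stopifnot_scalar_number(pseudocount, "pseudocount", min = 0)
  structure(list(fold_threshold = fold_threshold, pseudocount = pseudocount),
            class = "differential_params")
}

#' Union of two HMR sets
#'
#' Overlapping intervals from the two sets are merged into maximal unions;
#' non-overlapping intervals pass through. The union intervals -- not the
#' per-context peak coordinates -- are the unit of differential
#' classification, avoiding double counting of partially overlapping peaks.
#'
#' @param hmrs_a,hmrs_b Interval tibbles.
#' @return A sorted interval tibble with columns `contig`, `start`, `end`,
#'   `name`.
#' @export
merge_union <- function(hmrs_a, hmrs_b) {
  both <- bind_rows(hmrs_a[, c("contig", "start", "end")],
                    hmrs_b[, c("contig", "start", "end")])
  out <- reduce_intervals(both, min_gapwidth = 0L)
  out$name <- sprintf("hmr_%04d", seq_len(nrow(out)))
  out
}

#' Scale one sample's read count onto another's sequencing depth
#'
#' Returns `count_a` unchanged and `count_b` rescaled by
#' `total_a / total_b`, i.e. both counts expressed at sample A's depth.
#'
#' @param count_a,count_b Read counts over a region in samples A and B.
#' @param total_a,total_b Sample-wide mapped-read totals (> 0).
#' @return Numeric vector `c(count_a, count_b_normalised)` (or a two-column
#'   tibble when the counts are vectors).
#' @examples
#' normalize_to_common_depth(50, 1e6, 200, 4e6)  # c(50, 50)
#' @export
normalize_to_common_depth <- function(count_a, total_a, count_b, total_b) {
  stopifnot_scalar_number(total_a, "total_a", min = 0, strict = TRUE)
  stopifnot_scalar_number(total_b, "total_b", min = 0, strict = TRUE)
  b <- count_b * total_a / total_b
  if (length(count_a) == 1L && length(count_b) == 1L) {
    c(count_a, b)
  } else {
    tibble(count_a = count_a, count_b_normalized = b)
  }
}

#' Classify union HMRs as shared or species-specific
#'
#' Fragment counts over each union interval are estimated from the two
#' coverage tracks, placed on a common depth, and compared by the fold rule:
#' fold > threshold labels the HMR specific to the context where it is
#' hypomethylated (higher BioCAP signal), and symmetrically; everything else
#' is shared. The fold itself is computed on counts scaled to the geometric
#' mean of the two depths so that swapping the contexts mirrors the labels
#' exactly even with a pseudocount; the reported `n_a`/`n_b_normalized`
#' columns use the conventional scaling of B onto A's depth.
#'
#' @param union Interval tibble from [merge_union()] (non-empty, no
#'   zero-length intervals).
#' @param cov_a,cov_b [coverage_track()] objects for contexts A and B.
#' @param params A [differential_params()].
#' @param fragment_length Mean fragment length for count estimation; defaults
#'   to the tracks' recorded value.
#' @return A tibble of class `hmr_classification`: the union intervals plus
#'   `summit` (leftmost maximum of pooled depth-scaled coverage), `n_a`,
#'   `n_b_normalized`, `fold` (A over B on symmetric scaling) and `label`
#'   (`shared`, `A_specific`, `B_specific`).
#' @export
classify_hmrs <- function(union, cov_a, cov_b,
                          params = differential_params(),
                          fragment_length = NULL) {
  stopifnot(inherits(params, "differential_params"),
            inherits(cov_a, "coverage_track"),
            inherits(cov_b, "coverage_track"))
  if (nrow(union) == 0L) abort("`union` must be non-empty")
  if (any(union$end <= union$start)) abort("zero-length interval in `union`")
  if (cov_a$total_reads <= 0 || cov_b$total_reads <= 0) {
    abort("both tracks need positive total reads")
  }
  fragment_length <- fragment_length %||% attr(cov_a, "fragment_length")
  n_a <- count_reads(cov_a, union, fragment_length)
  n_b <- count_reads(cov_b, union, fragment_length)
  ta <- as.numeric(cov_a$total_reads)
  tb <- as.numeric(cov_b$total_reads)
  tg <- sqrt(ta * tb)
  pc <- params$pseudocount
  fold <- (n_a * tg / ta + pc) / (n_b * tg / tb + pc)
  label <- dplyr::case_when(
    fold > params$fold_threshold ~ "A_specific",
    1 / fold > params$fold_threshold ~ "B_specific",
    TRUE ~ "shared"
  )
  # summit from pooled, depth-matched coverage
  pooled_summit <- vapply(seq_len(nrow(union)), function(i) {
    idx <- (union$start[i] + 1L):union$end[i]
    v <- cov_a$values[idx] + cov_b$values[idx] * ta / tb
    union$start[i] + which.max(v) - 1
  }, numeric(1))
  out <- union
  out$summit <- pooled_summit
  out$n_a <- n_a
  out$n_b_normalized <- n_b * ta / tb
  out$fold <- fold
  out$label <- label
  class(out) <- c("hmr_classification", class(out))
  out
}

#' Fraction of species-specific HMRs unique to one tissue
#'
#' An ssHMR is unique when it overlaps (>= 1 bp) no ssHMR of the same label
#' in any other tissue.
#'
#' @param ss_by_tissue Named list (>= 2 tissues) of labelled HMR tibbles (as
#'   from [classify_hmrs()]).
#' @param labels Which labels to evaluate (default the two specific classes).
#' @return A tibble with one row per (label, tissue): `n`, `n_unique`,
#'   `fraction_unique`.
#' @export
tissue_specificity <- function(ss_by_tissue,
                               labels = c("A_specific", "B_specific")) {
  if (length(ss_by_tissue) < 2L || is.null(names(ss_by_tissue))) {
    abort("`ss_by_tissue` must be a named list of >= 2 tissues")
  }
  purrr::map_dfr(labels, function(lab) {
    sets <- purrr::map(ss_by_tissue, ~ filter(.x, .data$label == lab))
    purrr::map_dfr(names(sets), function(tis) {
      own <- sets[[tis]]
      others <- bind_rows(sets[setdiff(names(sets), tis)])
      uniq <- if (nrow(own) == 0L) logical(0) else
        !interval_overlaps_any(own, others)
      tibble(label = lab, tissue = tis, n = nrow(own),
             n_unique = sum(uniq),
             fraction_unique = ifelse(nrow(own) > 0, sum(uniq) / nrow(own),
                                      NA_real_))
    })
  })
}

#' Squared Pearson correlation between replicate read counts
#'
#' @param counts_rep1,counts_rep2 Equal-length (>= 3) non-constant numeric
#'   vectors of per-HMR read counts.
#' @return The square of the Pearson product-moment correlation.
#' @examples
#' replicate_r2(1:5, 3 * (1:5) + 7)  # 1
#' @export
replicate_r2 <- function(counts_rep1, counts_rep2) {
  if (length(counts_rep1) != length(counts_rep2)) {
    abort("replicate count vectors must have equal length")
  }
  if (length(counts_rep1) < 3L) abort("need at least 3 HMRs")
  if (stats::sd(counts_rep1) == 0 || stats::sd(counts_rep2) == 0) {
    abort("correlation undefined for a constant count vector")
  }
  stats::cor(counts_rep1, counts_rep2)^2
}
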