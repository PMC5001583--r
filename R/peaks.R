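#' Peak-calling parameters for the Poisson local-background HMR caller
#'
#' Defaults mirror the MACS-style settings used for BioCAP HMR detection:
#' 300 bp scan bandwidth, 10/30 enrichment fold bounds for candidate
#' selection, Poisson tail p-value cutoff 1e-5, effective genome size 4.8e8
#' bp, local-lambda windows of 1, 5 and 10 kb, and 100 bp gap merging.
#'
#' @param bandwidth Scan window width in bp.
#' @param mfold_low,mfold_high Enrichment bounds over the genome-background
#'   rate used to seed candidate windows; only the lower bound gates calls
#'   (the upper bound exists for shift-model building in tag-based callers,
#'   which fragment-level BioCAP coverage does not need).
#' @param pvalue_threshold Poisson tail cutoff; compared in log space.
#' @param effective_genome_size Mappable genome size in bp used for the
#'   genome-background rate. The default is the composite-genome value used
#'   with genome-wide read totals; when a track's `total_reads` covers only
#'   the analysed contig, set this to the analysed genome length instead.
#' @param local_lambda_windows Ascending window sizes (bp) over which the
#'   control-derived local lambda is estimated.
#' @param merge_gap Significant windows closer than this many bp are merged
#'   into one peak.
#' @param fragment_length Mean fragment length (bp) used to convert coverage
#'   sums into fragment-count units for the Poisson model.
#' @return A list of class `peak_call_params`.
#' @export
peak_call_params <- function(bandwidth = 300L,
                             mfold_low = 10,
                             mfold_high = 30,
                             pvalue_threshold = 1e-5,
                             effective_genome_size = 4.8e8,
                             local_lambda_windows = c(1000L, 5000L, 10000L),
                             merge_gap = 100L,
                             fragment_length = 200) {
  if (pvalue_threshold <= 0 || pvalue_threshold >= 1) {
    abort("`pvalue_threshold` must lie in (0, 1)")
  }
  if (mfold_low >= mfold_high) abort("need mfold_low < mfold_high")
  if (is.unsorted(local_lambda_windows, strictly = TRUE)) {
    abort("`local_lambda_windows` must be strictly ascending")
  }
  stopifnot_scalar_number(bandwidth, "bandwidth", min = 1)
  stopifnot_scalar_number(fragment_length, "fragment_length", min = 0,
                          strict = TRUE)
  structure(list(bandwidth = as.integer(bandwidth),
                 mfold_low = mfold_low, mfold_high = mfold_high,
                 pvalue_threshold = pvalue_threshold,
                 effective_genome_size = effective_genome_size,
                 local_lambda_windows = as.integer(local_lambda_windows),
                 merge_gap = as.integer(merge_gap),
                 fragment_length = fragment_length),
            class = "peak_call_params")
}

#' Upper-tail Poisson probability
#'
#' Returns P(X >= observed) for X ~ Poisson(lambda), computed in log space so
#' that extreme tails remain accurate.
#'
#' @param observed Non-negative integer count(s).
#' @param lam Poisson mean(s) (> 0).
#' @param log_p Return the natural log of the tail probability.
#' @return Tail probabilities (or their logs), vectorised over inputs.
#' @examples
#' poisson_tail(1, 2)    # 1 - exp(-2)
#' poisson_tail(0, 5)    # 1
#' @export
poisson_tail <- function(observed, lam, log_p = FALSE) {
  if (any(lam <= 0)) abort("`lam` must be > 0")
  if (any(observed < 0) || any(observed != round(observed))) {
    abort("`observed` must be a non-negative integer count")
  }
  stats::ppois(observed - 1, lam, lower.tail = FALSE, log.p = log_p)
}

#' Call hypomethylated regions from BioCAP treatment vs input coverage
#'
#' Every `bandwidth`-wide window of the contig is converted into a fragment
#' count (coverage sum / fragment length) and tested against a local Poisson
#' rate: the maximum of the genome-background rate
#' `total_reads * bandwidth / effective_genome_size` and the depth-scaled
#' control rate over each of the `local_lambda_windows` centred on the
#' window. Windows whose count reaches `mfold_low` times the genome
#' background and whose tail probability is at most `pvalue_threshold`
#' (compared in log space) are merged when closer than `merge_gap`, and each
#' resulting peak is reported with its summit (leftmost maximum of treatment
#' coverage), its smallest window p-value, and its estimated fragment count.
#'
#' @param treatment,control [coverage_track()] objects on the same contig,
#'   both with positive `total_reads` (a zero-signal treatment yields an
#'   empty result with a warning).
#' @param params A [peak_call_params()].
#' @return A tibble with columns `contig`, `start`, `end`, `name`, `score`
#'   (-log10 p), `strand`, `summit` (absolute 0-based position), `p_value`,
#'   `n_reads`.
#' @export
call_peaks <- function(treatment, control, params = peak_call_params()) {
  stopifnot(inherits(treatment, "coverage_track"),
            inherits(control, "coverage_track"),
            inherits(params, "peak_call_params"))
  if (treatment$contig != control$contig) {
    abort("treatment and control tracks are on different contigs")
  }
  if (control$total_reads <= 0) abort("control track has zero total reads")
  empty <- tibble(contig = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric(), strand = character(),
                  summit = numeric(), p_value = numeric(), n_reads = numeric())
  if (treatment$total_reads <= 0 || sum(treatment$values) == 0) {
    warn("treatment track has no signal; no peaks called")
    return(empty)
  }
  bw <- params$bandwidth
  L <- length(treatment$values)
  if (L < bw) return(empty)
  n_win <- L - bw + 1L                     # 1-based window starts

  tc <- c(0, cumsum(treatment$values))
  obs <- round((tc[(bw + 1):(L + 1)] - tc[1:n_win]) / params$fragment_length)

  lambda_bg <- treatment$total_reads * bw / params$effective_genome_size
  lam <- .local_lambda(control, n_win, bw, params,
                       scale = treatment$total_reads / control$total_reads,
                       floor_lambda = lambda_bg)

  candidate <- obs >= params$mfold_low * lambda_bg & obs > 0
  logp <- rep(0, n_win)
  logp[candidate] <- poisson_tail(obs[candidate], lam[candidate], log_p = TRUE)
  significant <- candidate & logp <= log(params$pvalue_threshold)
  if (!any(significant)) return(empty)

  # significant window starts -> covered intervals -> gap merge
  s <- which(significant)
  runs <- IRanges::reduce(IRanges::IRanges(s, s + bw - 1L),
                          min.gapwidth = params$merge_gap + 1L)
  peak_start <- IRanges::start(runs)       # 1-based
  peak_end <- IRanges::end(runs)
  out <- purrr::map_dfr(seq_along(peak_start), function(i) {
    idx <- peak_start[i]:peak_end[i]
    summit <- idx[which.max(treatment$values[idx])]   # leftmost max
    win_in <- s[s >= peak_start[i] & s <= peak_end[i] - bw + 1L]
    if (length(win_in) == 0L) win_in <- s[s >= peak_start[i] & s <= peak_end[i]]
    p_log <- min(logp[win_in])
    tibble(contig = treatment$contig,
           start = peak_start[i] - 1, end = as.numeric(peak_end[i]),
           score = -p_log / log(10),
           summit = summit - 1,
           p_value = exp(p_log),
           n_reads = (tc[peak_end[i] + 1] - tc[peak_start[i]]) /
             params$fragment_length)
  })
  out$name <- sprintf("peak_%04d", seq_len(nrow(out)))
  out$strand <- "."
  out[, c("contig", "start", "end", "name", "score", "strand",
          "summit", "p_value", "n_reads")]
}

# lambda per scoring window: max over control rates measured in windows of
# each size centred on the scoring window, scaled to the treatment depth and
# normalised to the bandwidth, floored at the genome-background rate.
.local_lambda <- function(control, n_win, bw, params, scale, floor_lambda) {
  L <- length(control$values)
  cc <- c(0, cumsum(control$values))
  mid <- seq_len(n_win) + (bw %/% 2L)
  lam <- rep(floor_lambda, n_win)
  for (w in params$local_lambda_windows) {
    lo <- pmax(mid - w %/% 2L, 1L)
    hi <- pmin(mid + w %/% 2L, L)
    rate <- (cc[hi + 1] - cc[lo]) / (hi - lo + 1) * bw /
      params$fragment_length * scale
    lam <- pmax(lam, rate)
  }
  lam
}

#' Keep peaks reproduced in a second biological replicate
#'
#' Retains replicate-1 peaks (with their coordinates) that overlap any
#' replicate-2 peak by at least 1 bp; input order is preserved.
#'
#' @param peaks_rep1,peaks_rep2 Peak tibbles as from [call_peaks()].
#' @return The retained subset of `peaks_rep1`.
#' @export
intersect_replicates <- function(peaks_rep1, peaks_rep2) {
  if (nrow(peaks_rep1) == 0L || nrow(peaks_rep2) == 0L) {
    return(peaks_rep1[0, ])
  }
  peaks_rep1[interval_overlaps_any(peaks_rep1, peaks_rep2), ]
}

#' Describe rearrangements of the transplanted contig
#'
#' Host-genome rearrangement of the transplanted sequence is provided as a
#' map of breakpoint positions, deleted intervals, and duplicated intervals
#' with integer copy number >= 2.
#'
#' @param breakpoints Numeric vector of 0-based breakpoint positions.
#' @param deleted Interval tibble of deleted regions (or `NULL`).
#' @param duplicated Interval tibble of duplicated regions with a
#'   `copy_number` column (or `NULL`).
#' @return A list of class `rearrangement_map`.
#' @export
rearrangement_map <- function(breakpoints = numeric(0), deleted = NULL,
                              duplicated = NULL) {
  deleted <- deleted %||% interval_tbl(character(), numeric(), numeric())[0, ]
  if (is.null(duplicated)) {
    duplicated <- interval_tbl(character(), numeric(), numeric())[0, ]
    duplicated$copy_number <- integer(0)
  }
  validate_intervals(deleted, "deleted")
  validate_intervals(duplicated, "duplicated")
  if (nrow(duplicated) > 0L) {
    if (!"copy_number" %in% names(duplicated) ||
        any(duplicated$copy_number < 2L) ||
        any(duplicated$copy_number != round(duplicated$copy_number))) {
      abort("duplicated intervals need an integer `copy_number` >= 2")
    }
  }
  structure(list(breakpoints = as.numeric(breakpoints),
                 deleted = deleted, duplicated = duplicated),
            class = "rearrangement_map")
}

#' Remove or rescale HMRs affected by rearrangements
#'
#' HMRs overlapping any breakpoint position or deleted interval are dropped;
#' HMRs overlapping a duplicated interval have their read-count columns
#' divided by the copy number (fractional counts allowed); all other HMRs
#' pass through unchanged.
#'
#' @param hmrs Peak tibble (as from [call_peaks()] or [classify_hmrs()]).
#' @param map A [rearrangement_map()].
#' @param read_cols Names of count columns to rescale in duplicated regions;
#'   defaults to whichever of `n_reads`, `n_a`, `n_b`, `n_b_normalized` are
#'   present.
#' @return The corrected HMR tibble.
#' @export
apply_rearrangement_map <- function(hmrs, map,
                                    read_cols = intersect(
                                      c("n_reads", "n_a", "n_b", "n_b_normalized"),
                                      names(hmrs))) {
  stopifnot(inherits(map, "rearrangement_map"))
  if (nrow(hmrs) == 0L) return(hmrs)
  drop <- interval_overlaps_any(hmrs, map$deleted)
  if (length(map$breakpoints) > 0L) {
    for (bp in map$breakpoints) {
      drop <- drop | (hmrs$start <= bp & bp < hmrs$end)
    }
  }
  out <- hmrs[!drop, ]
  if (nrow(map$duplicated) > 0L && nrow(out) > 0L) {
    for (i in seq_len(nrow(out))) {
      hit <- map$duplicated$contig == out$contig[i] &
        map$duplicated$start < out$end[i] & out$start[i] < map$duplicated$end
      if (any(hit)) {
        cn <- max(map$duplicated$copy_number[hit])
        for (cc in read_cols) out[[cc]][i] <- out[[cc]][i] / cn
      }
    }
  }
  out
}
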