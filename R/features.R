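#' CpG density of a DNA sequence
#'
#' Counts CG dinucleotides (the C of each CpG on the forward strand; the
#' reverse-strand G is the same symmetric dyad) and reports them per 100 bp
#' of sequence. Case-insensitive; dinucleotides containing a letter outside
#' A/C/G/T are skipped.
#'
#' @param seq Character vector of DNA sequences, each of length >= 2.
#' @return CpGs per 100 bp, one value per sequence.
#' @examples
#' cpg_density("CGCGCGCGCG")  # 50
#' @export
cpg_density <- function(seq) {
  vapply(seq, function(s) {
    if (nchar(s) < 2L) abort("sequence must be at least 2 bp")
    b <- strsplit(toupper(s), "")[[1]]
    100 * length(.cg_starts(b)) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC content of a DNA sequence
#'
#' Fraction (G + C) / (A + C + G + T); letters outside A/C/G/T are excluded
#' from numerator and denominator. Case-insensitive.
#'
#' @param seq Character vector of DNA sequences, each of length >= 1.
#' @return GC fraction in `[0, 1]`, one value per sequence.
#' @examples
#' gc_content(c("GGCC", "ACGT"))  # 1, 0.5
#' @export
gc_content <- function(seq) {
  vapply(seq, function(s) {
    if (nchar(s) < 1L) abort("sequence must be at least 1 bp")
    b <- strsplit(toupper(s), "")[[1]]
    acgt <- b %in% .BASES
    if (!any(acgt)) return(NA_real_)
    sum(b %in% c("G", "C")) / sum(acgt)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Length-matched randomly shifted background intervals
#'
#' Each input interval is moved to a uniformly random start on the same
#' contig (keeping its length) such that it stays within the contig and
#' overlaps no excluded interval, by rejection sampling with at most
#' `max_tries` attempts per interval. The matched control preserves the
#' interval-length multiset exactly.
#'
#' @param intervals Interval tibble; every interval must be shorter than
#'   `contig_length`.
#' @param contig_length Length of the contig the intervals are shifted on.
#' @param excluded Interval tibble the shifted copies must not overlap
#'   (typically the HMRs themselves), or `NULL`.
#' @param seed Integer seed; output is seed-deterministic.
#' @param max_tries Rejection-sampling budget per interval.
#' @return An interval tibble of the same height as `intervals`.
#' @export
shifted_background <- function(intervals, contig_length, excluded = NULL,
                               seed = 1L, max_tries = 10000L) {
  if (nrow(intervals) == 0L) return(intervals[0, ])
  validate_intervals(intervals)
  lens <- intervals$end - intervals$start
  if (any(lens >= contig_length)) {
    abort("every interval must be shorter than `contig_length`")
  }
  with_seed(seed, {
    out <- intervals
    for (i in seq_len(nrow(intervals))) {
      len <- lens[i]
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        s <- sample.int(contig_length - len + 1L, 1L) - 1L
        cand <- tibble(contig = intervals$contig[i], start = s, end = s + len)
        if (!any(interval_overlaps_any(cand, excluded))) {
          out$start[i] <- s
          out$end[i] <- s + len
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "could not place shifted copy of interval %d (%s:%g-%g) after %d tries",
          i, intervals$contig[i], intervals$start[i], intervals$end[i],
          max_tries))
      }
    }
    out
  })
}

#' Repeat-age parameters
#'
#' @param mutation_rate Substitutions per site per year used to convert
#'   consensus divergence into age; default 2.2e-9, the estimated mammalian
#'   mutation rate.
#' @return A list of class `repeat_age_params`.
#' @export
repeat_age_params <- function(mutation_rate = 2.2e-9) {
  stopifnot_scalar_number(mutation_rate, "mutation_rate", min = 0,
                          strict = TRUE)
  structure(list(mutation_rate = mutation_rate), class = "repeat_age_params")
}

#' Estimate repeat age from RepeatMasker milliDiv
#'
#' Age in years = (milliDiv / 1000) / mutation_rate: the per-site divergence
#' from the repeat consensus divided by the per-site per-year mutation rate.
#'
#' @param millidiv Non-negative substitutions per 1000 bases vs consensus.
#' @param params A [repeat_age_params()].
#' @return Age(s) in years.
#' @examples
#' repeat_age(220)  # 1e8 years
#' @export
repeat_age <- function(millidiv, params = repeat_age_params()) {
  if (any(millidiv < 0)) abort("`millidiv` must be >= 0")
  (millidiv / 1000) / params$mutation_rate
}

#' Repeat ages at HMR summits, by HMR class
#'
#' For every HMR whose summit base falls inside an annotated repeat, the
#' repeat's estimated age is emitted tagged with the HMR's label; when two
#' label groups are requested, they are compared with a two-sided
#' Mann-Whitney U test (exact for group sizes up to 20 without ties, normal
#' approximation otherwise).
#'
#' @param hmrs Labelled HMR tibble with `summit` and `label` columns.
#' @param repeats Repeat tibble with `millidiv` (and optionally `family`).
#' @param params A [repeat_age_params()].
#' @param compare Length-2 character vector of labels to test against each
#'   other, or `NULL` to skip the test.
#' @param mode `"summit"` (point query, the default) or `"overlap"` (any
#'   >= 1 bp HMR/repeat overlap).
#' @return A list of class `repeat_age_profile`: `samples` (tibble `name`,
#'   `label`, `family`, `millidiv`, `age_years`) and `test` (tibble with the
#'   U statistic and p-value, or `NULL`).
#' @export
summit_repeat_ages <- function(hmrs, repeats, params = repeat_age_params(),
                               compare = NULL, mode = c("summit", "overlap")) {
  mode <- match.arg(mode)
  if (!"summit" %in% names(hmrs) && mode == "summit") {
    abort("`hmrs` needs a `summit` column for summit mode")
  }
  samples <- purrr::map_dfr(seq_len(nrow(hmrs)), function(i) {
    hit <- if (mode == "summit") {
      repeats$contig == hmrs$contig[i] &
        repeats$start <= hmrs$summit[i] & hmrs$summit[i] < repeats$end
    } else {
      repeats$contig == hmrs$contig[i] &
        repeats$start < hmrs$end[i] & hmrs$start[i] < repeats$end
    }
    if (!any(hit)) return(NULL)
    rep_hit <- repeats[which(hit)[1], ]
    tibble(name = hmrs$name[i] %||% NA_character_,
           label = hmrs$label[i],
           family = rep_hit$family %||% NA_character_,
           millidiv = rep_hit$millidiv,
           age_years = repeat_age(rep_hit$millidiv, params))
  })
  if (is.null(samples) || nrow(samples) == 0L) {
    samples <- tibble(name = character(), label = character(),
                      family = character(), millidiv = integer(),
                      age_years = numeric())
  }
  test <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2L)
    x <- samples$age_years[samples$label == compare[1]]
    y <- samples$age_years[samples$label == compare[2]]
    if (length(x) > 0L && length(y) > 0L) {
      exact <- length(x) <= 20L && length(y) <= 20L &&
        !anyDuplicated(c(x, y))
      ht <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = !exact))
      test <- tibble(group1 = compare[1], group2 = compare[2],
                     n1 = length(x), n2 = length(y),
                     statistic = unname(ht$statistic), p_value = ht$p.value,
                     method = if (exact) "exact" else "normal approximation")
    }
  }
  structure(list(samples = samples, test = test),
            class = "repeat_age_profile")
}

#' Per-HMR sequence feature table
#'
#' Extracts the underlying DNA of each HMR and computes its CpG density (per
#' 100 bp) and GC fraction.
#'
#' @param hmrs Interval tibble (optionally with `label`).
#' @param sequences Named character vector of contig sequences.
#' @return A tibble `name`, `label`, `contig`, `start`, `end`, `length`,
#'   `cpg_per_100bp`, `gc_fraction`.
#' @export
hmr_feature_table <- function(hmrs, sequences) {
  if (nrow(hmrs) == 0L) {
    return(tibble(name = character(), label = character(), contig = character(),
                  start = numeric(), end = numeric(), length = numeric(),
                  cpg_per_100bp = numeric(), gc_fraction = numeric()))
  }
  seqs <- vapply(seq_len(nrow(hmrs)), function(i) {
    substr(sequences[[hmrs$contig[i]]], hmrs$start[i] + 1, hmrs$end[i])
  }, character(1))
  tibble(
    name = if ("name" %in% names(hmrs)) hmrs$name else
      sprintf("hmr_%04d", seq_len(nrow(hmrs))),
    label = if ("label" %in% names(hmrs)) hmrs$label else NA_character_,
    contig = hmrs$contig, start = hmrs$start, end = hmrs$end,
    length = hmrs$end - hmrs$start,
    cpg_per_100bp = cpg_density(seqs),
    gc_fraction = gc_content(seqs)
  )
}
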