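#' Per-base fragment coverage for one contig
#'
#' A `coverage_track` stores the per-base BioCAP (or input) fragment coverage
#' of one contig, together with the sample-wide number of mapped fragments and
#' the mean fragment length used to convert coverage sums back into
#' fragment-count units.
#'
#' @param contig Contig name.
#' @param values Numeric vector of non-negative per-base coverage, one entry
#'   per base of the contig.
#' @param total_reads Sample-wide mapped-fragment count (>= 0).
#' @param fragment_length Mean fragment length in bp; used by [count_reads()].
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(contig, values, total_reads,
                           fragment_length = 200) {
  if (!is.character(contig) || length(contig) != 1L || contig == "") {
    abort("`contig` must be a single non-empty name")
  }
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE)) abort("coverage values must be >= 0")
  stopifnot_scalar_number(total_reads, "total_reads", min = 0)
  stopifnot_scalar_number(fragment_length, "fragment_length", min = 0,
                          strict = TRUE)
  structure(
    list(contig = contig, values = values,
         total_reads = as.numeric(total_reads)),
    fragment_length = fragment_length,
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %s: %s bp, mean %.2fx, %s fragments (sample-wide)\n",
    x$contig, format(length(x$values), big.mark = ","),
    mean(x$values), format(x$total_reads, big.mark = ",")
  ))
  invisible(x)
}

#' Estimate fragment counts over intervals from a coverage track
#'
#' The number of fragments overlapping an interval is estimated as the
#' coverage sum over the interval divided by the mean fragment length -- the
#' read-count semantics used for differential classification when only
#' coverage is available.
#'
#' @param track A [coverage_track()].
#' @param intervals Interval tibble (`contig`, `start`, `end`) on the track's
#'   contig.
#' @param fragment_length Mean fragment length in bp; defaults to the value
#'   recorded on the track.
#' @return Numeric vector of estimated fragment counts, one per interval.
#' @export
count_reads <- function(track, intervals, fragment_length = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  fragment_length <- fragment_length %||% attr(track, "fragment_length")
  if (nrow(intervals) == 0L) return(numeric(0))
  validate_intervals(intervals)
  if (any(intervals$contig != track$contig)) {
    abort("`intervals` must lie on the track's contig")
  }
  L <- length(track$values)
  if (any(intervals$end > L)) abort("interval beyond contig end")
  cc <- c(0, cumsum(track$values))
  (cc[intervals$end + 1] - cc[intervals$start + 1]) / fragment_length
}

coverage_sum <- function(track, start, end) {
  cc <- c(0, cumsum(track$values))
  cc[end + 1] - cc[start + 1]
}
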