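#' Build an interval tibble
#'
#' Genomic intervals are plain tibbles throughout the package, using the BED
#' convention: 0-based, half-open `[start, end)` coordinates on a named contig.
#' This constructor validates coordinates and fills the optional BED6 columns.
#'
#' @param contig Contig name(s).
#' @param start,end 0-based half-open coordinates; `0 <= start < end`.
#' @param name Optional feature labels.
#' @param score Optional numeric scores.
#' @param strand One of `"+"`, `"-"`, `"."` per interval.
#' @return A tibble with columns `contig`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @examples
#' interval_tbl("chrT", c(0, 500), c(100, 900), name = c("a", "b"))
#' @export
interval_tbl <- function(contig, start, end, name = NA_character_,
                         score = NA_real_, strand = ".") {
  out <- tibble(
    contig = as.character(contig),
    start = as.numeric(start),
    end = as.numeric(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand)
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x, where = "intervals") {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$contig) | x$contig == "")) {
    abort(sprintf("%s: contig names must be non-empty", where))
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0L) {
    abort(sprintf("%s: need 0 <= start < end (first offending record %d)",
                  where, bad[1]))
  }
  invisible(x)
}

# tibble (0-based half-open) -> IRanges (1-based closed)
as_iranges <- function(x) {
  IRanges::IRanges(start = as.integer(x$start) + 1L, end = as.integer(x$end))
}

# For each row of `x`, does it overlap (>= 1 bp) any row of `y` on the same
# contig?
interval_overlaps_any <- function(x, y) {
  if (nrow(x) == 0L) return(logical(0))
  if (is.null(y) || nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  out <- rep(FALSE, nrow(x))
  for (ctg in unique(x$contig)) {
    xi <- which(x$contig == ctg)
    yi <- which(y$contig == ctg)
    if (length(yi) == 0L) next
    out[xi] <- IRanges::overlapsAny(as_iranges(x[xi, ]), as_iranges(y[yi, ]))
  }
  out
}

# Union of overlapping intervals, per contig; adjacency alone does not merge.
reduce_intervals <- function(x, min_gapwidth = 0L) {
  if (nrow(x) == 0L) {
    return(tibble(contig = character(), start = numeric(), end = numeric()))
  }
  purrr::map_dfr(split(x, x$contig), function(d) {
    r <- IRanges::reduce(as_iranges(d), min.gapwidth = as.integer(min_gapwidth))
    tibble(contig = d$contig[1],
           start = IRanges::start(r) - 1,
           end = as.numeric(IRanges::end(r)))
  }) |>
    arrange(.data$contig, .data$start)
}
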