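#' Read genomic intervals from a BED file
#'
#' Accepts BED3 or BED6; all coordinates are kept 0-based half-open. Parse
#' errors report the offending file and line.
#'
#' @param path Path to a tab-delimited BED file (no header).
#' @return An interval tibble as from [interval_tbl()].
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[lines != ""]
  if (length(lines) == 0L) return(interval_tbl(character(), numeric(), numeric())[0, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("%s:%d: expected at least 3 tab-separated fields",
                  path, which(nf < 3L)[1]))
  }
  get <- function(i) purrr::map_chr(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  })
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(sprintf("%s:%d: malformed coordinate", path, bad[1]))
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad) > 0L) {
    abort(sprintf("%s:%d: need 0 <= start < end", path, bad[1]))
  }
  score <- suppressWarnings(as.numeric(get(5)))
  interval_tbl(get(1), start, end,
               name = get(4),
               score = score,
               strand = dplyr::coalesce(get(6), "."))
}

#' Write intervals as BED
#'
#' Writes BED6 when any of `name`/`score`/`strand` is informative, BED3
#' otherwise. Extra columns can be appended via `extra_cols`.
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @param extra_cols Character vector of additional columns of `x` to append
#'   after the BED6 fields.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra_cols = character()) {
  validate_intervals(x)
  name <- if ("name" %in% names(x)) dplyr::coalesce(x$name, ".") else rep(".", nrow(x))
  score <- if ("score" %in% names(x)) dplyr::coalesce(x$score, 0) else rep(0, nrow(x))
  strand <- if ("strand" %in% names(x)) dplyr::coalesce(x$strand, ".") else rep(".", nrow(x))
  bed6 <- any(name != ".") || any(score != 0) || any(strand != ".") ||
    length(extra_cols) > 0L
  out <- tibble(contig = x$contig, start = format_coord(x$start),
                end = format_coord(x$end))
  if (bed6) {
    out$name <- name
    out$score <- score
    out$strand <- strand
    for (cc in extra_cols) out[[cc]] <- x[[cc]]
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read RepeatMasker-style repeat annotations
#'
#' BED6 plus a seventh column holding milliDiv (substitutions per 1000 bases
#' relative to the repeat consensus); the `name` field carries the repeat
#' family.
#'
#' @param path Path to the tab-delimited repeat file (no header).
#' @return Interval tibble with additional columns `family` and `millidiv`.
#' @export
read_repeats <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[lines != ""]
  empty <- interval_tbl(character(), numeric(), numeric())[0, ]
  empty$family <- character(0)
  empty$millidiv <- integer(0)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 7L)) {
    abort(sprintf("%s:%d: repeat records need 7 fields (BED6 + milliDiv)",
                  path, which(nf < 7L)[1]))
  }
  md <- suppressWarnings(as.integer(purrr::map_chr(fields, 7)))
  bad <- which(is.na(md) | md < 0L)
  if (length(bad) > 0L) {
    abort(sprintf("%s:%d: milliDiv must be a non-negative integer", path, bad[1]))
  }
  x <- read_bed_fields(fields, path)
  x$family <- x$name
  x$millidiv <- md
  x
}

# shared BED6 field parsing for pre-split lines
read_bed_fields <- function(fields, path) {
  get <- function(i) purrr::map_chr(fields, function(f) {
    if (length(f) >= i) f[i] else NA_character_
  })
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end) | !(start >= 0 & start < end))
  if (length(bad) > 0L) {
    abort(sprintf("%s:%d: malformed coordinates", path, bad[1]))
  }
  interval_tbl(get(1), start, end, name = get(4),
               score = suppressWarnings(as.numeric(get(5))),
               strand = dplyr::coalesce(get(6), "."))
}

#' Write repeat annotations (BED6 + milliDiv)
#' @param x Repeat tibble as from [read_repeats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeats <- function(x, path) {
  out <- tibble(contig = x$contig, start = format_coord(x$start),
                end = format_coord(x$end),
                name = dplyr::coalesce(x$family, x$name, "."),
                score = 0, strand = ".", millidiv = x$millidiv)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a per-base coverage track
#'
#' Records must be sorted and non-overlapping; gaps are zero-filled so the
#' round trip with [write_bedgraph()] preserves per-base values exactly.
#'
#' @param path Path to a bedGraph file (contig, start, end, value).
#' @param contig_length Contig length in bp; defaults to the largest end
#'   coordinate in the file.
#' @param total_reads Sample-wide mapped-fragment count to record on the
#'   track; defaults to coverage-sum / `fragment_length`.
#' @param fragment_length Mean fragment length recorded on the track.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, contig_length = NULL, total_reads = NULL,
                          fragment_length = 200) {
  df <- readr::read_tsv(path, col_names = c("contig", "start", "end", "value"),
                        col_types = "cddd", progress = FALSE)
  if (nrow(df) == 0L) {
    if (is.null(contig_length)) {
      abort(sprintf("%s: empty bedGraph needs an explicit `contig_length`", path))
    }
    return(coverage_track("track", numeric(contig_length),
                          total_reads %||% 0, fragment_length))
  }
  if (length(unique(df$contig)) > 1L) {
    abort(sprintf("%s: a coverage track holds a single contig", path))
  }
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad) > 0L) abort(sprintf("%s:%d: malformed record", path, bad[1]))
  if (is.unsorted(df$start, strictly = TRUE)) {
    abort(sprintf("%s:%d: records must be sorted by start", path,
                  which(diff(df$start) <= 0)[1] + 1L))
  }
  ovl <- which(df$start[-1] < df$end[-nrow(df)])
  if (length(ovl) > 0L) {
    abort(sprintf("%s:%d: overlapping records", path, ovl[1] + 1L))
  }
  contig_length <- contig_length %||% max(df$end)
  if (any(df$end > contig_length)) {
    abort(sprintf("%s:%d: record beyond contig end", path,
                  which(df$end > contig_length)[1]))
  }
  values <- numeric(contig_length)
  for (i in seq_len(nrow(df))) {
    values[(df$start[i] + 1):df$end[i]] <- df$value[i]
  }
  coverage_track(df$contig[1], values,
                 total_reads %||% (sum(values) / fragment_length),
                 fragment_length)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal coverage are collapsed into single records; zero runs are
#' omitted (and restored by zero-filling on read).
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  out <- tibble(contig = track$contig,
                start = format_coord(starts[keep]),
                end = format_coord(ends[keep]),
                value = r$values[keep])
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a FASTA file
#'
#' Sequences are uppercased; letters outside A/C/G/T are preserved verbatim
#' and simply never counted as part of a CpG or of GC content downstream.
#'
#' @param path Path to a FASTA file with unique headers.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) abort(sprintf("%s: duplicate FASTA headers", path))
  setNames(toupper(as.character(ss)), nm)
}

#' Write sequences as FASTA
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read or write per-CpG methylation calls
#'
#' Tab-delimited with header `contig`, `position` (0-based C of the CpG on
#' the forward strand), `meth_count`, `unmeth_count`.
#'
#' @param path Path to the TSV file.
#' @return A tibble of calls.
#' @export
read_methcalls <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(), position = readr::col_double(),
    meth_count = readr::col_integer(), unmeth_count = readr::col_integer()
  ), progress = FALSE)
  bad <- which(df$meth_count < 0L | df$unmeth_count < 0L | df$position < 0)
  if (length(bad) > 0L) {
    abort(sprintf("%s:%d: negative count or position", path, bad[1] + 1L))
  }
  df
}

#' @rdname read_methcalls
#' @param calls Tibble with columns `contig`, `position`, `meth_count`,
#'   `unmeth_count`.
#' @export
write_methcalls <- function(calls, path) {
  readr::write_tsv(calls[, c("contig", "position", "meth_count", "unmeth_count")],
                   path)
  invisible(path)
}
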