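#' Simulate targeted bisulfite counts with conversion spike-ins
#'
#' For every CpG inside an amplicon, the methylated read count is drawn
#' Binomial(depth, p_obs) with p_obs = m + (1 - m) * (1 - conversion_rate):
#' a truly methylated cytosine is always read as methylated, while an
#' unmethylated cytosine escapes conversion (and so reads as methylated) with
#' probability 1 - conversion_rate. Two spike-in call sets are emitted from
#' the bundle's synthetic control contigs, generated with m = 0 (fully
#' unmethylated) and m = 1 (fully methylated) at every CpG, mirroring the
#' unmethylated/methylated control DNA spiked into conversion reactions.
#'
#' @inheritParams simulate_biocap_coverage
#' @param amplicons Interval tibble of amplicons on the bundle's contigs.
#' @param depth Reads per CpG (> 0 integer).
#' @param conversion_rate Conversion rate in (0, 1]; defaults to the config.
#' @param seed Integer seed.
#' @return A list with tibbles `calls`, `spike_unmeth`, `spike_meth`, each
#'   with columns `contig`, `position` (0-based C of the CpG), `meth_count`,
#'   `unmeth_count`; `calls` also carries `amplicon` and the true `m`.
#' @export
simulate_bisulfite_counts <- function(bundle, context, amplicons,
                                      depth = NULL, conversion_rate = NULL,
                                      seed = 1L) {
  stopifnot(inherits(bundle, "genome_bundle"))
  if (!context %in% names(bundle$methylome_by_context)) {
    abort(sprintf("unknown context '%s'", context))
  }
  cfg <- bundle$config
  depth <- depth %||% cfg$bisulfite_depth
  conversion_rate <- conversion_rate %||% cfg$conversion_rate
  stopifnot_scalar_number(depth, "depth", min = 0, strict = TRUE)
  if (conversion_rate <= 0 || conversion_rate > 1) {
    abort("`conversion_rate` must lie in (0, 1]")
  }
  validate_intervals(amplicons, "amplicons")
  lens <- nchar(bundle$sequences)
  bad <- which(!(amplicons$contig %in% names(lens)) |
                 amplicons$end > lens[amplicons$contig])
  if (length(bad) > 0L) {
    abort(sprintf("amplicon %d is not contained in a bundle contig", bad[1]))
  }

  meth <- bundle$methylome_by_context[[context]]
  with_seed(seed, {
    calls <- purrr::map_dfr(seq_len(nrow(amplicons)), function(i) {
      amp <- amplicons[i, ]
      cpg <- meth[meth$contig == amp$contig &
                    meth$pos >= amp$start & meth$pos < amp$end, ]
      if (nrow(cpg) == 0L) {
        warn(sprintf("amplicon %s:%d-%d contains no CpG; emitting no calls",
                     amp$contig, amp$start, amp$end))
        return(tibble(amplicon = character(), contig = character(),
                      position = numeric(), m = numeric(),
                      meth_count = integer(), unmeth_count = integer()))
      }
      p_obs <- cpg$m + (1 - cpg$m) * (1 - conversion_rate)
      mc <- rbinom(nrow(cpg), depth, p_obs)
      nm <- if (!is.null(amp$name) && !is.na(amp$name)) amp$name
            else sprintf("amp_%02d", i)
      tibble(amplicon = nm,
             contig = cpg$contig, position = cpg$pos, m = cpg$m,
             meth_count = mc, unmeth_count = depth - mc)
    })
    spike <- function(contig, m) {
      seq <- strsplit(bundle$sequences[[contig]], "")[[1]]
      pos <- .cg_starts(seq) - 1L
      p_obs <- m + (1 - m) * (1 - conversion_rate)
      mc <- rbinom(length(pos), depth, p_obs)
      tibble(contig = contig, position = as.numeric(pos),
             meth_count = mc, unmeth_count = depth - mc)
    }
    list(calls = calls,
         spike_unmeth = spike(.SPIKE_UNMETH, 0),
         spike_meth = spike(.SPIKE_METH, 1))
  })
}
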