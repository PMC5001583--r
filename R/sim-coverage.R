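#' Simulate BioCAP fragment coverage for one host context
#'
#' BioCAP capture is modelled at the fragment level: fragment lengths are
#' Normal(`fragment_len_mean`, `fragment_len_sd`), truncated at 50 bp and
#' discretised to 10 bp; a fragment starting at position s with length l is
#' sampled with weight proportional to the sum of (1 - m_i) over the CpGs it
#' covers (its expected count of unmethylated CpGs under the context's
#' methylome) plus a uniform non-specific background. Coverage is the per-base
#' pile-up of the sampled fragments. Duplicated intervals of the bundle's
#' rearrangement map multiply the capture weight by their copy number.
#'
#' @param bundle A [simulate_composite_genome()] result.
#' @param context Host context id, `"A"` or `"B"`.
#' @param replicate_seed Integer seed for this replicate; distinct seeds give
#'   independent noise around the same expectation.
#' @param depth Target mean fragment coverage (> 0); defaults to the bundle
#'   config's `biocap_depth`.
#' @param contig Contig to simulate (default the transplanted contig).
#' @param background_rate Non-specific capture weight per fragment; defaults
#'   to the config's `biocap_background_rate`.
#' @return A [coverage_track()].
#' @examples
#' bundle <- simulate_composite_genome(sim_config(
#'   transplant_length = 1e5, n_shared_cgis = 4, n_a_specific = 0,
#'   n_b_specific = 0, n_young_repeats = 0, n_old_repeats = 0
#' ))
#' trk <- simulate_biocap_coverage(bundle, "A", replicate_seed = 1, depth = 5)
#' mean(trk$values)
#' @export
simulate_biocap_coverage <- function(bundle, context, replicate_seed,
                                     depth = NULL, contig = .TRANSPLANT,
                                     background_rate = NULL) {
  stopifnot(inherits(bundle, "genome_bundle"))
  if (!context %in% names(bundle$methylome_by_context)) {
    abort(sprintf("unknown context '%s'", context))
  }
  cfg <- bundle$config
  depth <- depth %||% cfg$biocap_depth
  stopifnot_scalar_number(depth, "depth", min = 0, strict = TRUE)
  background_rate <- background_rate %||% cfg$biocap_background_rate

  meth <- bundle$methylome_by_context[[context]]
  meth <- meth[meth$contig == contig, ]
  L <- nchar(bundle$sequences[[contig]])
  wpb <- numeric(L)
  if (nrow(meth) > 0L) wpb[meth$pos + 1L] <- 1 - meth$m
  wpb <- wpb + background_rate / cfg$fragment_len_mean
  wpb <- .apply_duplication_weight(wpb, bundle$rearrangement_map, contig)

  with_seed(replicate_seed,
            .sample_fragment_track(wpb, contig, depth, cfg))
}

#' Simulate an input (no-capture) control track
#'
#' Fragments are sampled uniformly along the contig with no methylation
#' weighting; only copy-number duplications of the rearrangement map bias the
#' sampling.
#'
#' @inheritParams simulate_biocap_coverage
#' @param seed Integer seed.
#' @param depth Target mean fragment coverage (>= 0); 0 gives an empty track.
#' @return A [coverage_track()].
#' @export
simulate_input_control <- function(bundle, seed, depth = NULL,
                                   contig = .TRANSPLANT) {
  stopifnot(inherits(bundle, "genome_bundle"))
  cfg <- bundle$config
  depth <- depth %||% cfg$biocap_depth
  stopifnot_scalar_number(depth, "depth", min = 0)
  L <- nchar(bundle$sequences[[contig]])
  wpb <- rep(1, L)
  wpb <- .apply_duplication_weight(wpb, bundle$rearrangement_map, contig)
  with_seed(seed, .sample_fragment_track(wpb, contig, depth, cfg))
}

.apply_duplication_weight <- function(wpb, map, contig) {
  dup <- map$duplicated
  if (is.null(dup) || nrow(dup) == 0L) return(wpb)
  dup <- dup[dup$contig == contig, ]
  for (i in seq_len(nrow(dup))) {
    idx <- (dup$start[i] + 1L):min(dup$end[i], length(wpb))
    wpb[idx] <- wpb[idx] * dup$copy_number[i]
  }
  wpb
}

# Core fragment sampler: per-base weight wpb; a fragment (s, l) has weight
# sum(wpb[s:(s+l-1)]). Lengths are handled in discrete groups so each group's
# start distribution is exact for its own length.
.sample_fragment_track <- function(wpb, contig, depth, cfg) {
  L <- length(wpb)
  n_frag <- round(depth * L / cfg$fragment_len_mean)
  if (n_frag == 0L) {
    return(coverage_track(contig, numeric(L), 0,
                          fragment_length = cfg$fragment_len_mean))
  }
  lens <- round(rnorm(n_frag, cfg$fragment_len_mean, cfg$fragment_len_sd) / 10) * 10
  lens <- pmin(pmax(lens, 50), L)
  cw <- c(0, cumsum(wpb))
  starts_all <- integer(0)
  lens_all <- integer(0)
  for (l in sort(unique(lens))) {
    k <- sum(lens == l)
    ns <- L - l + 1L                       # valid 1-based starts
    w <- cw[(l + 1):(L + 1)] - cw[1:ns]
    tot <- sum(w)
    if (tot <= 0) {
      warn(sprintf("zero total capture weight for fragment length %d; %d fragments dropped",
                   l, k))
      next
    }
    s <- sample.int(ns, k, replace = TRUE, prob = w)
    starts_all <- c(starts_all, s)
    lens_all <- c(lens_all, rep.int(as.integer(l), k))
  }
  values <- if (length(starts_all) > 0L) {
    d_plus <- tabulate(starts_all, nbins = L)
    d_minus <- tabulate(starts_all + lens_all, nbins = L + 1L)
    cumsum(d_plus - d_minus[1:L])
  } else numeric(L)
  coverage_track(contig, values, length(starts_all),
                 fragment_length = cfg$fragment_len_mean)
}
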