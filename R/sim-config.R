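#' Simulation configuration for the synthetic composite genome
#'
#' Defines the study conditions the generator emulates: one transplanted
#' contig carrying shared CpG islands (CGIs), young CpG-rich repeats that are
#' hypomethylated only in the host environment lacking a co-evolved repeat
#' defence, and TF-protected low-CpG distal elements bound in only one host
#' context -- plus two host-context methylomes, BioCAP fragment capture and
#' bisulfite counts with conversion spike-ins.
#'
#' @param seed Integer seed; a fixed config (including seed) yields
#'   byte-identical output.
#' @param transplant_length Length of the transplanted contig (bp).
#' @param n_shared_cgis Number of CGIs hypomethylated in both host contexts.
#' @param n_a_specific,n_b_specific Context-specific hypomethylated elements
#'   per context, each split between young CpG-rich repeats and TF-protected
#'   low-CpG elements (see `n_young_repeats`).
#' @param n_young_repeats Total young CpG-rich repeats planted as drivers of
#'   context-specific elements (half per context; the remainder of each
#'   specific set is TF-protected).
#' @param n_old_repeats Old, diverged repeats annotated at the centres of a
#'   random subset of shared CGIs, giving the shared class summit-in-repeat
#'   age samples.
#' @param n_tf_sites_per_context TF ChIP peaks per context: one at each of
#'   that context's TF-protected elements, the rest shared between contexts.
#' @param cgi_length_range CGI length range in bp (CGIs are 1-2 kb CpG-rich
#'   regions).
#' @param repeat_length,tf_element_length Lengths (bp) of the young-repeat and
#'   TF-protected elements.
#' @param background_cpg_rate,cgi_cpg_rate,repeat_cpg_rate,tf_element_cpg_rate
#'   CpG dinucleotides per bp for background sequence, shared CGIs, young
#'   repeats (above CGI level, as in CpG-rich young repeat elements) and
#'   TF-protected elements (intermediate).
#' @param background_meth,hmr_meth `c(shape1, shape2)` of the Beta
#'   distributions for per-CpG methylation probabilities outside (mean 0.85,
#'   concentrated) and inside (mean 0.05, strongly bimodal: most CpGs of a
#'   hypomethylated element are essentially unmethylated while a small
#'   fraction retain methylation) hypomethylated elements.
#' @param biocap_depth Mean BioCAP fragment coverage of the transplanted
#'   contig.
#' @param biocap_background_rate Non-specific capture weight per fragment
#'   (added to the per-fragment sum of 1 - m over covered CpGs).
#' @param fragment_len_mean,fragment_len_sd Fragment length distribution
#'   (Normal, truncated at 50 bp, discretised to 10 bp).
#' @param bisulfite_depth Reads per CpG for simulated bisulfite counts.
#' @param conversion_rate Bisulfite conversion rate in (0, 1].
#' @param host_length Length of the background host contig (bp).
#' @param spike_length Length of each synthetic conversion-control spike-in
#'   contig (bp).
#' @param tss_fraction Fraction of shared CGIs that carry a TSS at their 5'
#'   edge (context-specific elements stay distal).
#' @param n_breakpoints,n_deletions,n_duplications Optional rearrangement-map
#'   features planted in background sequence to exercise
#'   [apply_rearrangement_map()]; all default to 0.
#' @return A list of class `sim_config`.
#' @seealso [simulate_composite_genome()]
#' @export
sim_config <- function(seed = 1L,
                       transplant_length = 2e6,
                       n_shared_cgis = 60L,
                       n_a_specific = 20L,
                       n_b_specific = 20L,
                       n_young_repeats = 20L,
                       n_old_repeats = 20L,
                       n_tf_sites_per_context = 25L,
                       cgi_length_range = c(1000L, 2000L),
                       repeat_length = 800L,
                       tf_element_length = 600L,
                       background_cpg_rate = 0.01,
                       cgi_cpg_rate = 0.10,
                       repeat_cpg_rate = 0.12,
                       tf_element_cpg_rate = 0.04,
                       background_meth = c(17, 3),
                       hmr_meth = c(0.025, 0.475),
                       biocap_depth = 30,
                       biocap_background_rate = 0.05,
                       fragment_len_mean = 200,
                       fragment_len_sd = 50,
                       bisulfite_depth = 100L,
                       conversion_rate = 0.99,
                       host_length = 1e5,
                       spike_length = 1e4,
                       tss_fraction = 0.7,
                       n_breakpoints = 0L,
                       n_deletions = 0L,
                       n_duplications = 0L) {
  cfg <- list(
    seed = as.integer(seed),
    transplant_length = transplant_length,
    n_shared_cgis = as.integer(n_shared_cgis),
    n_a_specific = as.integer(n_a_specific),
    n_b_specific = as.integer(n_b_specific),
    n_young_repeats = as.integer(n_young_repeats),
    n_old_repeats = as.integer(n_old_repeats),
    n_tf_sites_per_context = as.integer(n_tf_sites_per_context),
    cgi_length_range = as.integer(cgi_length_range),
    repeat_length = as.integer(repeat_length),
    tf_element_length = as.integer(tf_element_length),
    background_cpg_rate = background_cpg_rate,
    cgi_cpg_rate = cgi_cpg_rate,
    repeat_cpg_rate = repeat_cpg_rate,
    tf_element_cpg_rate = tf_element_cpg_rate,
    background_meth = background_meth,
    hmr_meth = hmr_meth,
    biocap_depth = biocap_depth,
    biocap_background_rate = biocap_background_rate,
    fragment_len_mean = fragment_len_mean,
    fragment_len_sd = fragment_len_sd,
    bisulfite_depth = as.integer(bisulfite_depth),
    conversion_rate = conversion_rate,
    host_length = host_length,
    spike_length = spike_length,
    tss_fraction = tss_fraction,
    n_breakpoints = as.integer(n_breakpoints),
    n_deletions = as.integer(n_deletions),
    n_duplications = as.integer(n_duplications)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_shared_cgis", "n_a_specific", "n_b_specific",
              "n_young_repeats", "n_old_repeats", "n_tf_sites_per_context",
              "n_breakpoints", "n_deletions", "n_duplications")
  for (nm in counts) {
    if (cfg[[nm]] < 0L) abort(sprintf("`%s` must be >= 0", nm))
  }
  rates <- c("background_cpg_rate", "cgi_cpg_rate", "repeat_cpg_rate",
             "tf_element_cpg_rate", "conversion_rate", "tss_fraction")
  for (nm in rates) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1]", nm))
    }
  }
  if (cfg$cgi_length_range[1] > cfg$cgi_length_range[2]) {
    abort("`cgi_length_range` must be increasing")
  }
  stopifnot_scalar_number(cfg$transplant_length, "transplant_length",
                          min = 0, strict = TRUE)
  stopifnot_scalar_number(cfg$fragment_len_mean, "fragment_len_mean",
                          min = 0, strict = TRUE)
  for (nm in c("background_meth", "hmr_meth")) {
    if (length(cfg[[nm]]) != 2L || any(cfg[[nm]] <= 0)) {
      abort(sprintf("`%s` must be two positive Beta shape parameters", nm))
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  transplant contig: %s bp, seed %d\n",
              format(x$transplant_length, big.mark = ","), x$seed))
  cat(sprintf("  planted: %d shared CGIs, %d A-specific, %d B-specific\n",
              x$n_shared_cgis, x$n_a_specific, x$n_b_specific))
  cat(sprintf("  BioCAP depth %gx, fragments %g +/- %g bp\n",
              x$biocap_depth, x$fragment_len_mean, x$fragment_len_sd))
  invisible(x)
}
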