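# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small composite genome for module-level tests.
small_config <- function(...) {
  sim_config(transplant_length = 2e5, n_shared_cgis = 6, n_a_specific = 2,
             n_b_specific = 2, n_young_repeats = 2, n_old_repeats = 2,
             n_tf_sites_per_context = 4, ...)
}

small_bundle <- function() cached("small_bundle", {
  simulate_composite_genome(small_config())
})

# Full default-scale simulation shared by the acceptance suite.
default_bundle <- function() cached("default_bundle", {
  simulate_composite_genome(sim_config(seed = 1))
})

default_tracks <- function() cached("default_tracks", {
  b <- default_bundle()
  out <- list()
  for (k in 1:2) {
    ctx <- c("A", "B")[k]
    reps <- lapply(1:2, function(r) {
      simulate_biocap_coverage(b, ctx, replicate_seed = 10L * k + r,
                               depth = 30)
    })
    input <- simulate_input_control(b, seed = 100L + k, depth = 30)
    pooled <- coverage_track(reps[[1]]$contig,
                             reps[[1]]$values + reps[[2]]$values,
                             reps[[1]]$total_reads + reps[[2]]$total_reads,
                             attr(reps[[1]], "fragment_length"))
    out[[ctx]] <- list(reps = reps, input = input, pooled = pooled)
  }
  out
})

# HMR call + classification on the default simulation.
default_classification <- function() cached("default_classification", {
  b <- default_bundle()
  trks <- default_tracks()
  hmrs <- lapply(trks, function(t) {
    intersect_replicates(call_peaks(t$reps[[1]], t$input),
                         call_peaks(t$reps[[2]], t$input))
  })
  union <- merge_union(hmrs$A, hmrs$B)
  cls <- classify_hmrs(union, trks$A$pooled, trks$B$pooled)
  list(hmrs = hmrs, classified = cls)
})

# Constant-coverage track helper.
flat_track <- function(L, value, total = NULL, contig = "chrT",
                       fragment_length = 200) {
  coverage_track(contig, rep(value, L),
                 total %||% (value * L / fragment_length),
                 fragment_length)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a track from constant background plus rectangular blocks.
block_track <- function(L, background = 0, blocks = list(), total = NULL,
                        contig = "chrT", fragment_length = 200) {
  v <- rep(background, L)
  for (blk in blocks) v[(blk$start + 1):blk$end] <- blk$value
  coverage_track(contig, v, total %||% (sum(v) / fragment_length),
                 fragment_length)
}
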