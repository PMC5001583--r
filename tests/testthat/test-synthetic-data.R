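test_that("a config with nothing planted yields background-only methylomes", {
  cfg <- sim_config(transplant_length = 5e4, n_shared_cgis = 0,
                    n_a_specific = 0, n_b_specific = 0, n_young_repeats = 0,
                    n_old_repeats = 0, n_tf_sites_per_context = 0)
  b <- simulate_composite_genome(cfg)
  expect_equal(nrow(b$cgi_truth), 0)
  expect_equal(nrow(b$element_truth), 0)
  m <- b$methylome_by_context$A
  m <- m$m[m$contig == "chrT"]
  # Beta(17, 3) background: mean 0.85
  expect_gt(mean(m), 0.8)
  expect_lt(mean(m), 0.9)
})

test_that("the same seed reproduces sequences, truth and methylomes exactly", {
  b1 <- simulate_composite_genome(small_config())
  b2 <- simulate_composite_genome(small_config())
  expect_identical(b1$sequences, b2$sequences)
  expect_identical(b1$element_truth, b2$element_truth)
  expect_identical(b1$methylome_by_context, b2$methylome_by_context)
  t1 <- simulate_biocap_coverage(b1, "A", replicate_seed = 7, depth = 5)
  t2 <- simulate_biocap_coverage(b2, "A", replicate_seed = 7, depth = 5)
  expect_identical(t1$values, t2$values)
})

test_that("planted CGIs are CpG-denser than length-matched background windows", {
  b <- simulate_composite_genome(sim_config(
    transplant_length = 1e6, n_shared_cgis = 60, n_a_specific = 20,
    n_b_specific = 20, seed = 1))
  count_cg <- function(iv) {
    # independent oracle: direct dinucleotide count on the extracted string
    sum(vapply(seq_len(nrow(iv)), function(i) {
      s <- substr(b$sequences[["chrT"]], iv$start[i] + 1, iv$end[i])
      lengths(regmatches(s, gregexpr("(?=CG)", s, perl = TRUE)))
    }, numeric(1)))
  }
  cgi <- b$cgi_truth
  bg <- shifted_background(cgi, nchar(b$sequences[["chrT"]]),
                           excluded = b$element_truth, seed = 5)
  dens_cgi <- count_cg(cgi) / sum(cgi$end - cgi$start)
  dens_bg <- count_cg(bg) / sum(bg$end - bg$start)
  expect_gt(dens_cgi, dens_bg)
  expect_gt(dens_cgi, 0.08)   # ~ the configured 0.10 CpG/bp
  expect_lt(dens_bg, 0.03)
})

test_that("overcrowded configs fail with a sizing error naming the counts", {
  expect_error(
    simulate_composite_genome(sim_config(transplant_length = 5e4,
                                         n_shared_cgis = 60)),
    "exceed transplant_length")
})

test_that("a fully methylated methylome gives background-only capture", {
  b <- simulate_composite_genome(small_config())
  b$methylome_by_context$A$m <- 1
  trk <- simulate_biocap_coverage(b, "A", replicate_seed = 1, depth = 10)
  # no CpG-weighted fragments: coverage at planted CGIs matches background
  cgi_cov <- mean(count_reads(trk, b$cgi_truth) /
                    (b$cgi_truth$end - b$cgi_truth$start))
  expect_equal(mean(trk$values), 10, tolerance = 0.05)
  # per-bp fragment rate at CGIs close to the genome-wide rate (no enrichment)
  genome_rate <- trk$total_reads / length(trk$values)
  expect_lt(cgi_cov / genome_rate, 2)
})

test_that("with zero background every fragment overlaps the only CGI", {
  cfg <- sim_config(transplant_length = 5e4, n_shared_cgis = 1,
                    n_a_specific = 0, n_b_specific = 0, n_young_repeats = 0,
                    n_old_repeats = 0, n_tf_sites_per_context = 0,
                    biocap_background_rate = 0)
  b <- simulate_composite_genome(cfg)
  # make everything outside the CGI fully methylated so only the CGI carries
  # capture weight
  m <- b$methylome_by_context$A
  inside <- m$contig == "chrT" &
    m$pos >= b$cgi_truth$start & m$pos < b$cgi_truth$end
  b$methylome_by_context$A$m <- ifelse(inside, 0, 1)
  trk <- simulate_biocap_coverage(b, "A", replicate_seed = 3, depth = 2)
  v <- trk$values
  # no coverage farther than the longest possible fragment from the CGI
  far <- c(seq_len(max(0, b$cgi_truth$start - 600)),
           seq(b$cgi_truth$end + 600, length(v)))
  expect_true(all(v[far] == 0))
  expect_gt(sum(v[(b$cgi_truth$start + 1):b$cgi_truth$end]), 0)
})

test_that("input control is uniform at the requested depth and deterministic", {
  b <- small_bundle()
  trk <- simulate_input_control(b, seed = 11, depth = 20)
  expect_equal(mean(trk$values), 20, tolerance = 0.05)
  trk2 <- simulate_input_control(b, seed = 11, depth = 20)
  expect_identical(trk$values, trk2$values)
  empty <- simulate_input_control(b, seed = 1, depth = 0)
  expect_equal(sum(empty$values), 0)
  expect_equal(empty$total_reads, 0)
  expect_error(simulate_biocap_coverage(b, "A", 1, depth = 0), "depth")
})

test_that("fragment accounting is conserved between totals and coverage", {
  b <- small_bundle()
  trk <- simulate_biocap_coverage(b, "A", replicate_seed = 5, depth = 8)
  # sum of coverage = sum of fragment lengths ~= n_fragments * mean length
  implied <- sum(trk$values) / b$config$fragment_len_mean
  expect_equal(implied, trk$total_reads, tolerance = 0.02)
})

test_that("expected capture increases with the unmethylated CpG count", {
  # two elements identical except CpG count; zero background so all weight
  # is CpG-driven
  cfg <- sim_config(transplant_length = 1e5, n_shared_cgis = 2,
                    n_a_specific = 0, n_b_specific = 0, n_young_repeats = 0,
                    n_old_repeats = 0, n_tf_sites_per_context = 0,
                    cgi_length_range = c(1500L, 1500L),
                    biocap_background_rate = 0.01)
  b <- simulate_composite_genome(cfg)
  m <- b$methylome_by_context$A
  e1 <- b$cgi_truth[1, ]; e2 <- b$cgi_truth[2, ]
  in1 <- m$contig == "chrT" & m$pos >= e1$start & m$pos < e1$end
  in2 <- m$contig == "chrT" & m$pos >= e2$start & m$pos < e2$end
  # element 1: all CpGs unmethylated; element 2: half unmethylated
  b$methylome_by_context$A$m[in1] <- 0
  idx2 <- which(in2)
  b$methylome_by_context$A$m[idx2] <- rep(c(0, 1), length.out = length(idx2))
  counts <- rowMeans(vapply(1:6, function(s) {
    trk <- simulate_biocap_coverage(b, "A", replicate_seed = s, depth = 10)
    count_reads(trk, b$cgi_truth)
  }, numeric(2)))
  expect_gt(counts[1], counts[2])
  expect_equal(counts[1] / counts[2], 2, tolerance = 0.25)
})

test_that("bisulfite counts follow the conversion arithmetic", {
  b <- small_bundle()
  amp <- b$cgi_truth[1, ]
  # m = 0 everywhere, perfect conversion: zero methylated reads
  b0 <- b
  b0$methylome_by_context$A$m <- 0
  bs <- simulate_bisulfite_counts(b0, "A", amp, depth = 50,
                                  conversion_rate = 1, seed = 2)
  expect_true(all(bs$calls$meth_count == 0))
  # m = 1: full methylated counts regardless of conversion
  b1 <- b
  b1$methylome_by_context$A$m <- 1
  bs1 <- simulate_bisulfite_counts(b1, "A", amp, depth = 50,
                                   conversion_rate = 0.9, seed = 2)
  expect_true(all(bs1$calls$meth_count == 50))
  # m = 0, conversion 0.99, depth 1000: observed methylation ~1%
  bs2 <- simulate_bisulfite_counts(b0, "A", amp, depth = 1000,
                                   conversion_rate = 0.99, seed = 2)
  frac <- sum(bs2$calls$meth_count) /
    sum(bs2$calls$meth_count + bs2$calls$unmeth_count)
  n <- nrow(bs2$calls) * 1000
  expect_equal(frac, 0.01, tolerance = 4 * sqrt(0.01 * 0.99 / n) / 0.01)
  # amplicon without CpGs warns and emits nothing
  expect_warning(
    empty <- simulate_bisulfite_counts(
      b, "A", interval_tbl("chrT", 0, 2), depth = 10, seed = 1),
    "no CpG")
  expect_equal(nrow(empty$calls), 0)
})
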