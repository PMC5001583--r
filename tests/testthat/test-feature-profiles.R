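test_that("CpG density and GC content follow direct counting, any case", {
  expect_equal(cpg_density("CGCGCGCGCG"), 50)
  expect_equal(cpg_density("ATATATATAT"), 0)
  expect_equal(cpg_density("cgcgcgcgcg"), 50)
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("AATT"), 0)
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("acgt"), 0.5)

  # random 1 kb at uniform composition ~ 6.25 CpG / 100 bp in expectation;
  # oracle = an independent regex dinucleotide scan
  seqs <- withr::with_seed(42, vapply(1:40, function(i) {
    paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  }, character(1)))
  scan <- vapply(seqs, function(s) {
    100 * length(regmatches(s, gregexpr("(?=CG)", s, perl = TRUE))[[1]]) / 1000
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(cpg_density(seqs), scan)
  expect_equal(mean(scan), 6.25, tolerance = 0.08)
})

test_that("shifted background preserves lengths and avoids exclusions", {
  iv <- interval_tbl("chrT", c(0, 100, 5000), c(50, 1100, 5600))
  bg <- shifted_background(iv, 2e4, excluded = iv, seed = 3)
  expect_equal(sort(bg$end - bg$start), sort(iv$end - iv$start))
  expect_false(any(interval_overlaps_any(bg, iv)))
  # deterministic under the seed
  expect_identical(bg, shifted_background(iv, 2e4, excluded = iv, seed = 3))
  expect_equal(nrow(shifted_background(iv[0, ], 1e4)), 0)
  # impossible placement errors out, naming the interval
  blocked <- interval_tbl("chrT", 0, 990)
  expect_error(shifted_background(blocked, 1000,
                                  excluded = interval_tbl("chrT", 0, 1000),
                                  max_tries = 50),
               "interval 1")
})

test_that("shifted background reproduces contig-wide CpG density", {
  # law of large numbers on a uniform-composition contig
  contig <- withr::with_seed(7, paste(sample(c("A", "C", "G", "T"), 5e4, TRUE),
                                      collapse = ""))
  iv <- interval_tbl("chrT", seq(0, by = 60, length.out = 200),
                     seq(0, by = 60, length.out = 200) + 50)
  bg <- shifted_background(iv, 5e4, seed = 11)
  seqs <- vapply(seq_len(nrow(bg)), function(i) {
    substr(contig, bg$start[i] + 1, bg$end[i])
  }, character(1))
  expect_equal(mean(cpg_density(seqs)), cpg_density(contig),
               tolerance = 0.12)
})

test_that("repeat age is milliDiv/1000 divided by the mutation rate", {
  expect_equal(repeat_age(0), 0)
  expect_identical(repeat_age(220, repeat_age_params(2.2e-9)), 1.0e8)
  expect_equal(repeat_age(22), 1.0e7)
  expect_error(repeat_age(-1), "millidiv")
})

test_that("summit-in-repeat ages compose the point query with the age formula", {
  reps <- tibble::tibble(contig = "chrT", start = c(100, 900),
                         end = c(300, 1200),
                         family = c("AluY_like", "L2_like"),
                         millidiv = c(22L, 220L))
  hmrs <- tibble::tibble(contig = "chrT", start = c(80, 2000),
                         end = c(350, 2400), summit = c(150, 2100),
                         name = c("h1", "h2"),
                         label = c("B_specific", "shared"))
  prof <- summit_repeat_ages(hmrs, reps)
  expect_equal(nrow(prof$samples), 1)
  expect_equal(prof$samples$label, "B_specific")
  expect_equal(prof$samples$age_years, 1e7)
  # no summit in any repeat -> empty samples
  none <- summit_repeat_ages(dplyr::mutate(hmrs, summit = c(500, 2100)), reps)
  expect_equal(nrow(none$samples), 0)
})

test_that("Mann-Whitney output matches exhaustive rank enumeration", {
  reps <- tibble::tibble(contig = "chrT",
                         start = seq(0, by = 100, length.out = 6),
                         end = seq(0, by = 100, length.out = 6) + 50,
                         family = "x",
                         millidiv = as.integer(c(1, 2, 3, 4, 5, 6)))
  hmrs <- tibble::tibble(contig = "chrT", start = reps$start,
                         end = reps$end, summit = reps$start + 10,
                         name = letters[1:6],
                         label = rep(c("B_specific", "shared"), each = 3))
  prof <- summit_repeat_ages(hmrs, reps, compare = c("B_specific", "shared"))
  # brute-force oracle over all C(6,3) rank assignments
  vals <- repeat_age(1:6)
  combos <- utils::combn(6, 3)
  u_of <- function(idx) {
    x <- vals[idx]; y <- vals[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(1:3)
  u_all <- apply(combos, 2, u_of)
  p_exact <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  expect_equal(unname(prof$test$statistic), u_obs)   # U = 0 here
  expect_equal(prof$test$p_value, min(1, p_exact), tolerance = 1e-12)
  expect_equal(prof$test$method, "exact")
})

test_that("feature tables report per-HMR density from the genome sequence", {
  b <- small_bundle()
  ft <- hmr_feature_table(b$element_truth, b$sequences)
  expect_equal(nrow(ft), nrow(b$element_truth))
  med <- tapply(ft$cpg_per_100bp, b$element_truth$mechanism, stats::median)
  expect_gt(med[["young_repeat"]], med[["cgi"]])
  expect_gt(med[["cgi"]], med[["tf_protected"]])
})
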