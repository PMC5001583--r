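test_that("TSS windows are inclusive of both endpoints and partition HMRs", {
  tss <- tibble::tibble(contig = "chrT", pos = 1500)
  hmrs <- interval_tbl("chrT", c(900, 0), c(1100, 400))
  out <- classify_tss_proximity(hmrs, tss, annotation_params(500))
  expect_equal(out$tss_associated, c(TRUE, FALSE))
  # degenerate window 0: only direct overlap of the TSS base
  out0 <- classify_tss_proximity(interval_tbl("chrT", 999, 1001),
                                 tibble::tibble(contig = "chrT", pos = 1000),
                                 annotation_params(0))
  expect_true(out0$tss_associated)
  # exact boundary: HMR ending at tss - w does not reach the window...
  edge <- classify_tss_proximity(interval_tbl("chrT", c(0, 0), c(1000, 1001)),
                                 tss, annotation_params(500))
  expect_equal(edge$tss_associated, c(FALSE, TRUE))
  # partition: exactly one group per HMR
  b <- small_bundle()
  all_out <- classify_tss_proximity(b$element_truth, b$tss_truth)
  expect_equal(sum(all_out$tss_associated) + sum(!all_out$tss_associated),
               nrow(b$element_truth))
})

test_that("species-specific TF calls are factor-stratified partitions", {
  mk <- function(starts, factors) {
    x <- interval_tbl("chrT", starts, starts + 200)
    x$factor <- factors
    x
  }
  a <- mk(c(0, 1000, 5000), c("CEBPA", "HNF4A", "CTCF"))
  # identical sets: all shared
  same <- species_specific_peaks(a, a)
  expect_true(all(same$status == "shared"))
  # disjoint sets: all specific
  b <- mk(c(9000, 12000, 15000), c("CEBPA", "HNF4A", "CTCF"))
  disj <- species_specific_peaks(a, b)
  expect_true(all(disj$status == "specific"))
  # same position, different factor: still specific
  cross <- species_specific_peaks(mk(0, "CEBPA"), mk(0, "HNF4A"))
  expect_true(all(cross$status == "specific"))
  # partition per context
  mixed <- species_specific_peaks(a, mk(c(0, 9000), c("CEBPA", "CTCF")))
  expect_equal(sum(mixed$context == "A"), nrow(a))
  expect_equal(sort(unique(mixed$status)), c("shared", "specific"))
})

test_that("multi-way overlap summaries count patterns and round half-up", {
  targets <- interval_tbl("chrT", seq(0, by = 1000, length.out = 10),
                          seq(0, by = 1000, length.out = 10) + 500)
  none <- list(f1 = interval_tbl("chrT", 5e5, 5e5 + 10))
  s0 <- multiway_overlap_summary(targets, none)
  expect_equal(s0$percent_any, 0)
  all_sets <- list(f1 = targets, f2 = targets)
  s1 <- multiway_overlap_summary(targets, all_sets)
  expect_equal(s1$percent_any, 100)
  expect_equal(nrow(s1$patterns), 1)
  # pattern counts always sum to the number of targets
  partial <- list(f1 = targets[1:3, ], f2 = targets[3:5, ])
  s2 <- multiway_overlap_summary(targets, partial)
  expect_equal(sum(s2$patterns$count), 10)
  expect_equal(s2$n_any, 5)
  expect_equal(s2$percent_any, 50)
  expect_error(multiway_overlap_summary(targets[0, ], none), "non-empty")
})

test_that("signal matrices are centred, length-ranked and edge-padded", {
  L <- 20000
  iv <- interval_tbl("chrT", c(1000, 5000, 9000), c(1400, 5200, 10000),
                     name = c("mid", "small", "big"))
  flat <- flat_track(L, 5)
  m <- aggregate_matrix(iv, flat, flank = 500, bins = 10)
  expect_equal(dim(m), c(3, 10))
  expect_true(all(unclass(m) == 5))
  # rows ordered by length descending
  expect_equal(rownames(m), c("big", "mid", "small"))
  zero <- flat_track(L, 0)
  expect_true(all(unclass(aggregate_matrix(iv, zero, 500, 10)) == 0))
  # triangular peak at one midpoint: metaplot maximal at the centre bins
  tri <- numeric(L)
  mid <- 5100
  tri[(mid - 400):(mid + 400)] <- 400 - abs(seq(-400, 400))
  trk <- coverage_track("chrT", tri, sum(tri) / 200, 200)
  m2 <- aggregate_matrix(iv[2, ], trk, flank = 500, bins = 10)
  mp <- metaplot(m2)
  expect_true(which.max(mp) %in% c(5, 6))
  # oracle: direct per-bin mean on the constructed track
  direct <- vapply(1:10, function(j) {
    lo <- mid - 500 + (j - 1) * 100
    mean(tri[(lo + 1):(lo + 100)])
  }, numeric(1))
  expect_equal(unname(mp), direct)
  # midpoint closer than flank to the contig edge -> NA padding
  near_edge <- interval_tbl("chrT", 0, 200)
  m3 <- aggregate_matrix(near_edge, flat, flank = 500, bins = 10)
  expect_true(anyNA(m3))
  expect_true(all(unclass(m3)[1, 5:10] == 5))
})

test_that("Welch comparison of folds matches the hand formula", {
  mk <- function(tss_vals, distal_vals) {
    tibble::tibble(fold = c(tss_vals, distal_vals),
                   tss_associated = rep(c(TRUE, FALSE),
                                        c(length(tss_vals),
                                          length(distal_vals))))
  }
  # identical groups: t = 0, p = 1
  same <- fold_change_by_location(mk(c(1, 2, 3), c(1, 2, 3)),
                                  log2_fold = FALSE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # (1,2,3) vs (2,3,4): hand-computed Welch t and Welch-Satterthwaite df
  w <- fold_change_by_location(mk(c(1, 2, 3), c(2, 3, 4)), log2_fold = FALSE)
  se2 <- 1 / 3 + 1 / 3          # s1^2/n1 + s2^2/n2, both variances 1
  t_hand <- (2 - 3) / sqrt(se2)
  df_hand <- se2^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(w$statistic, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-12)
  expect_equal(w$p_value, 2 * stats::pt(t_hand, df_hand), tolerance = 1e-12)
  # both groups constant: degenerate variance is an error
  expect_error(fold_change_by_location(mk(c(2, 2), c(2, 2))), "constant")
  tidy_w <- generics::tidy(w)
  expect_equal(tidy_w$statistic, t_hand)
})
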