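test_that("poisson_tail matches closed forms and brute-force summation", {
  expect_equal(poisson_tail(0, 5), 1.0)
  expect_equal(poisson_tail(1, 2), 1 - exp(-2), tolerance = 1e-12)
  # independent oracle: direct pmf summation via exp(k log l - l - lgamma)
  brute <- function(obs, lam) {
    k <- obs:200
    sum(exp(k * log(lam) - lam - lgamma(k + 1)))
  }
  expect_equal(poisson_tail(12, 2), brute(12, 2), tolerance = 1e-12)
  expect_error(poisson_tail(3, 0), "lam")
  expect_error(poisson_tail(-1, 2), "observed")
})

test_that("no peaks are called when treatment equals control", {
  trt <- flat_track(5000, 10)
  ctl <- flat_track(5000, 10)
  expect_equal(nrow(call_peaks(trt, ctl)), 0)
})

test_that("a single enriched block yields one peak matching hand computation", {
  # 1 kb block at 20x over a 1x background, flat control
  L <- 10000
  trt <- block_track(L, background = 1,
                     blocks = list(list(start = 4000, end = 5000, value = 20)))
  ctl <- flat_track(L, 1)
  params <- peak_call_params()
  peaks <- call_peaks(trt, ctl, params)
  expect_equal(nrow(peaks), 1)
  expect_lte(peaks$start, 4000)
  expect_gte(peaks$end, 5000)
  # hand-computed scoring at the block centre: observed = 20 * 300 / 200 = 30;
  # lambda_local = control rate scaled to treatment depth
  scale <- trt$total_reads / ctl$total_reads
  lam_hand <- max(trt$total_reads * 300 / params$effective_genome_size,
                  1 * 300 / 200 * scale)
  expect_equal(peaks$p_value,
               stats::ppois(29, lam_hand, lower.tail = FALSE),
               tolerance = 1e-8)
  # leftmost-maximum summit inside the block
  expect_gte(peaks$summit, 4000)
  expect_lt(peaks$summit, 5000)
  expect_equal(peaks$summit, 4000)  # constant block: leftmost maximum
})

test_that("blocks closer than merge_gap merge into one peak", {
  L <- 10000
  blocks <- list(list(start = 3000, end = 3500, value = 30),
                 list(start = 3550, end = 4100, value = 30))
  trt <- block_track(L, background = 1, blocks = blocks)
  ctl <- flat_track(L, 1)
  peaks <- call_peaks(trt, ctl, peak_call_params(merge_gap = 100))
  expect_equal(nrow(peaks), 1)
  far <- list(list(start = 2000, end = 2500, value = 30),
              list(start = 4500, end = 5000, value = 30))
  trt2 <- block_track(L, background = 1, blocks = far)
  peaks2 <- call_peaks(trt2, ctl, peak_call_params(merge_gap = 100))
  expect_equal(nrow(peaks2), 2)
})

test_that("production caller equals an exhaustive per-window oracle", {
  # independent implementation: every window tested, no candidate pre-filter,
  # direct sums instead of cumulative tricks
  oracle_caller <- function(trt, ctl, params) {
    bw <- params$bandwidth
    L <- length(trt$values)
    scale <- trt$total_reads / ctl$total_reads
    lam_bg <- trt$total_reads * bw / params$effective_genome_size
    sig <- logical(L - bw + 1)
    for (s in seq_len(L - bw + 1)) {
      obs <- round(sum(trt$values[s:(s + bw - 1)]) / params$fragment_length)
      if (obs == 0) next
      mid <- s + bw %/% 2
      lam <- lam_bg
      for (w in params$local_lambda_windows) {
        lo <- max(mid - w %/% 2, 1)
        hi <- min(mid + w %/% 2, L)
        lam <- max(lam, sum(ctl$values[lo:hi]) / (hi - lo + 1) * bw /
                     params$fragment_length * scale)
      }
      p <- stats::ppois(obs - 1, lam, lower.tail = FALSE)
      sig[s] <- p <= params$pvalue_threshold
    }
    s <- which(sig)
    if (length(s) == 0) return(data.frame(start = numeric(), end = numeric()))
    iv <- IRanges::reduce(IRanges::IRanges(s, s + bw - 1),
                          min.gapwidth = params$merge_gap + 1)
    data.frame(start = IRanges::start(iv) - 1,
               end = as.numeric(IRanges::end(iv)))
  }
  params <- peak_call_params()
  cases <- list(
    block_track(10000, background = 1,
                blocks = list(list(start = 1000, end = 1800, value = 15),
                              list(start = 5000, end = 5400, value = 40),
                              list(start = 5500, end = 5900, value = 40),
                              list(start = 9500, end = 9950, value = 25))),
    block_track(8000, background = 2,
                blocks = list(list(start = 0, end = 600, value = 30),
                              list(start = 7500, end = 8000, value = 30))),
    block_track(6000, background = 0,
                blocks = list(list(start = 2000, end = 2100, value = 12)))
  )
  for (trt in cases) {
    ctl <- flat_track(length(trt$values), 1,
                      total = length(trt$values) / 200)
    got <- call_peaks(trt, ctl, params)
    want <- oracle_caller(trt, ctl, params)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("scaling treatment coverage up never removes a peak", {
  b <- small_bundle()
  trt <- simulate_biocap_coverage(b, "A", replicate_seed = 4, depth = 8)
  ctl <- simulate_input_control(b, seed = 40, depth = 8)
  base <- call_peaks(trt, ctl)
  for (c_scale in c(2, 5)) {
    scaled <- coverage_track(trt$contig, trt$values * c_scale,
                             trt$total_reads * c_scale,
                             attr(trt, "fragment_length"))
    up <- call_peaks(scaled, ctl)
    # every base peak is still covered by a scaled peak
    expect_true(all(interval_overlaps_any(base, up)))
  }
})

test_that("replicate intersection keeps rep1 peaks overlapping rep2", {
  p1 <- interval_tbl("chrT", c(100, 400, 900), c(200, 600, 1000))
  expect_equal(intersect_replicates(p1, p1), p1)
  disjoint <- interval_tbl("chrT", 2000, 2100)
  expect_equal(nrow(intersect_replicates(p1, disjoint)), 0)
  # 1 bp overlap retains the rep1 coordinates
  p2 <- interval_tbl("chrT", 199, 300)
  kept <- intersect_replicates(p1, p2)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$start, 100)
  expect_equal(kept$end, 200)
})

test_that("rearrangement correction drops and rescales as specified", {
  hmrs <- interval_tbl("chrT", c(100, 1000, 5000), c(300, 1400, 5600),
                       name = c("a", "b", "c"))
  hmrs$n_reads <- c(50, 300, 120)
  expect_equal(apply_rearrangement_map(hmrs, rearrangement_map()), hmrs)
  # breakpoint inside "a" drops it
  m1 <- rearrangement_map(breakpoints = 150)
  expect_equal(apply_rearrangement_map(hmrs, m1)$name, c("b", "c"))
  # deleted region removes "c"
  m2 <- rearrangement_map(deleted = interval_tbl("chrT", 5500, 7000))
  expect_equal(apply_rearrangement_map(hmrs, m2)$name, c("a", "b"))
  # duplication halves the reads of "b"
  dup <- interval_tbl("chrT", 900, 2000)
  dup$copy_number <- 2L
  m3 <- rearrangement_map(duplicated = dup)
  out <- apply_rearrangement_map(hmrs, m3)
  expect_equal(out$n_reads, c(50, 150, 120))
})
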