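make_bins <- function(counts, chrom = "chr1", bin_size = 1e6) {
  n <- length(counts)
  tibble::tibble(chrom = chrom,
                 start = (seq_len(n) - 1) * bin_size + 1,
                 end = seq_len(n) * bin_size,
                 count = counts)
}

test_that("median normalization yields copy ratios and estimates", {
  b <- normalize_bins(make_bins(rep(100, 50)))
  expect_equal(b$ratio, rep(1, 50))
  expect_equal(b$cn_estimate, rep(2, 50))
  b2 <- normalize_bins(dplyr::bind_rows(
    make_bins(rep(100, 100), "chr1"),
    make_bins(rep(150, 20), "chr21"),
    make_bins(rep(50, 20), "chr22")
  ))
  expect_equal(unique(b2$cn_estimate[b2$chrom == "chr21"]), 3)
  expect_equal(unique(b2$cn_estimate[b2$chrom == "chr22"]), 1)
  expect_error(normalize_bins(make_bins(rep(0, 30))), "zero")
  expect_error(normalize_bins(make_bins(rep(5, 10), chrom = "chrX")),
               "autosomal")
})

test_that("a constant series stays one segment", {
  set.seed(1)
  s <- cbs_segment(rep(1, 50), n_perm = 200)
  expect_equal(nrow(s), 1)
  expect_equal(s$first_bin, 1)
  expect_equal(s$last_bin, 50)
  s2 <- cbs_segment(rnorm(1, 1, 0), n_perm = 200)  # single bin
  expect_equal(nrow(s2), 1)
})

test_that("an embedded gain is segmented at the exact change-points", {
  set.seed(12)
  x <- c(rnorm(20, 1, 0.05), rnorm(5, 1.5, 0.05), rnorm(20, 1, 0.05))
  s <- cbs_segment(x, alpha = 0.01, n_perm = 1000)
  expect_equal(nrow(s), 3)
  expect_equal(s$last_bin, c(20, 25, 45))
  expect_equal(s$mean_ratio[2], 1.5, tolerance = 0.05)
  # the first accepted arc is the one the exhaustive search finds
  scan <- pgtdup:::cbs_max_arc(x, 2L)
  ref <- oracle_max_arc(x, 2)
  expect_equal(scan$i, ref$i)
  expect_equal(scan$j, ref$j)
  expect_equal(scan$stat, ref$stat, tolerance = 1e-10)
})

test_that("the arc scan matches the exhaustive reference on random input", {
  set.seed(33)
  for (trial in 1:40) {
    n <- sample(10:50, 1)
    x <- rnorm(n)
    if (runif(1) < 0.5) {
      a <- sample.int(n - 3, 1)
      b <- min(n, a + sample.int(10, 1))
      x[a:b] <- x[a:b] + runif(1, 0.5, 2)
    }
    scan <- pgtdup:::cbs_max_arc(x, 2L)
    ref <- oracle_max_arc(x, 2)
    expect_equal(scan$stat, ref$stat, tolerance = 1e-10)
    ok <- (scan$i == ref$i && scan$j == ref$j)
    if (!ok) {
      # a numerically tied alternative arc is acceptable
      arc <- x[(scan$i + 1):scan$j]
      rest <- x[-((scan$i + 1):scan$j)]
      k <- length(arc)
      st <- abs(mean(arc) - mean(rest)) /
        (sd(x) * sqrt(1 / k + 1 / (n - k)))
      expect_equal(st, ref$stat, tolerance = 1e-10)
    }
  }
})

test_that("segments always partition the input bins", {
  set.seed(44)
  for (trial in 1:10) {
    n <- sample(20:80, 1)
    x <- rnorm(n, 1, 0.1)
    if (runif(1) < 0.7) x[seq_len(sample.int(n - 1, 1))] <- 1.8
    s <- cbs_segment(x, n_perm = 200)
    expect_equal(s$first_bin[1], 1)
    expect_equal(s$last_bin[nrow(s)], n)
    if (nrow(s) > 1) {
      expect_equal(s$first_bin[-1], head(s$last_bin, -1) + 1)
    }
    expect_equal(sum(s$n_bins), n)
  }
})

test_that("dual-resolution calling applies size thresholds and labels", {
  # genome mode: a 3 Mb gain is below the 4 Mb reporting floor
  set.seed(55)
  counts <- rep(100, 120)
  counts[50:52] <- 150
  b <- normalize_bins(make_bins(counts))
  s <- segment_bins(b, n_perm = 500)
  expect_equal(nrow(call_cnvs(s, mode = "genome")), 0)
  # a 10 Mb loss is reported
  counts2 <- rpois(120, 100)
  counts2[30:39] <- rpois(10, 50)
  b2 <- normalize_bins(make_bins(counts2))
  s2 <- segment_bins(b2, n_perm = 500)
  calls2 <- call_cnvs(s2, mode = "genome")
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$type, "loss")
  expect_equal(calls2$cn, 1)
  expect_match(calls2$label, "^del")
  # whole-chromosome events report as signed chromosome labels
  b3 <- normalize_bins(dplyr::bind_rows(
    make_bins(rpois(100, 100), "chr1"),
    make_bins(rpois(48, 150), "chr21")
  ))
  s3 <- segment_bins(b3, n_perm = 500)
  calls3 <- call_cnvs(s3, mode = "genome")
  expect_equal(calls3$label, "+21")
  expect_true(calls3$whole_chromosome)
  # target mode requires a region
  expect_error(call_cnvs(s3, mode = "target"), "region")
})

test_that("flat genomes produce no calls", {
  set.seed(66)
  b <- normalize_bins(make_bins(rpois(200, 500)))
  s <- segment_bins(b, n_perm = 500)
  expect_equal(nrow(call_cnvs(s, mode = "genome")), 0)
  expect_equal(nrow(call_cnvs(s, mode = "target",
                              region = region("chr1", 1, 2e7))), 0)
})

test_that("target-region copy number rounds dosage away from diploid", {
  reg <- dup_region()
  cfg <- sim_config(seed = 77)
  sim_cn <- function(cn) {
    prof <- flat_profile()
    prof <- dplyr::bind_rows(
      tibble::tibble(chrom = "chr1", start = 1, end = reg$start - 1, cn = 2),
      tibble::tibble(chrom = "chr1", start = reg$start, end = reg$end,
                     cn = cn),
      tibble::tibble(chrom = "chr1", start = reg$end + 1, end = 249250621,
                     cn = 2))
    simulate_bin_counts(prof, cfg, bin_size = 4e5, reads_per_bin = 800) |>
      normalize_bins()
  }
  expect_equal(estimate_target_cn(sim_cn(3), reg)$cn, 3)
  expect_equal(estimate_target_cn(sim_cn(2), reg)$cn, 2)
  expect_equal(estimate_target_cn(sim_cn(4), reg)$cn, 4)  # homozygous dup
  expect_equal(estimate_target_cn(sim_cn(3), reg)$n_bins, 3)
  # ties round away from 2 copies
  expect_equal(pgtdup:::round_cn(2.5), 3)
  expect_equal(pgtdup:::round_cn(1.5), 1)
  # no fully contained bin -> instructive error
  coarse <- normalize_bins(make_bins(rep(100, 100), bin_size = 2.5e6))
  expect_error(estimate_target_cn(coarse, reg), "smaller bin size")
})
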