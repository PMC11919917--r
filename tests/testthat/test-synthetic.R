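test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 5, n_snps_flank = 6, n_snps_inside = 3)
  f1 <- simulate_family(cfg, n_embryos = 2)
  f2 <- simulate_family(cfg, n_embryos = 2)
  expect_identical(f1$pedigree$panel, f2$pedigree$panel)
  expect_identical(f1$observations, f2$observations)
  expect_identical(f1$embryos$E2$cn_profile, f2$embryos$E2$cn_profile)
})

test_that("pedigree SNPs land in the duplication and its 2 Mb flanks", {
  cfg <- sim_config(seed = 8, n_snps_flank = 50, n_snps_inside = 20)
  ped <- simulate_pedigree(cfg)
  reg <- ped$dup_region
  p <- ped$panel
  expect_true(all(p$pos[p$side == "upstream"] >= reg$start - 2e6 &
                    p$pos[p$side == "upstream"] < reg$start))
  expect_true(all(p$pos[p$side == "downstream"] > reg$end &
                    p$pos[p$side == "downstream"] <= reg$end + 2e6))
  expect_true(all(p$pos[p$side == "inside"] >= reg$start &
                    p$pos[p$side == "inside"] <= reg$end))
  # informativeness guarantee: at least one usable site per flank
  informative <- p$f_hap1 != p$f_hap2 & p$m_hap1 == p$m_hap2
  expect_true(any(informative[p$side == "upstream"]))
  expect_true(any(informative[p$side == "downstream"]))
})

test_that("parental heterozygosity matches the allele-frequency model", {
  cfg <- sim_config(seed = 13, n_snps_flank = 1000, n_snps_inside = 0,
                    maf_range = c(0.5, 0.5))
  ped <- simulate_pedigree(cfg)
  p <- ped$panel
  n <- nrow(p)
  # two independent Bernoulli(0.5) draws differ with probability 1/2
  tol <- 3 * sqrt(0.25 / n)
  expect_equal(mean(p$f_hap1 != p$f_hap2), 0.5, tolerance = 3 * tol)
  expect_equal(mean(p$m_hap1 != p$m_hap2), 0.5, tolerance = 3 * tol)
})

test_that("transmission is fair and recombination-free when disabled", {
  cfg <- sim_config(seed = 17, n_snps_flank = 5, n_snps_inside = 2,
                    recomb_prob = 0, chroms = "chr1")
  ped <- simulate_pedigree(cfg)
  haps <- vapply(seq_len(10000), function(k) {
    e <- simulate_embryo(ped, cfg)
    stopifnot(length(unique(e$transmission$pat_hap)) == 1)
    e$transmission$pat_hap[1]
  }, numeric(1))
  expect_lt(abs(mean(haps == 1) - 0.5), 0.015)
})

test_that("whole-chromosome aneuploidies shift the copy-number profile", {
  cfg <- sim_config(seed = 2, n_snps_flank = 5, n_snps_inside = 2)
  ped <- simulate_pedigree(cfg)
  emb <- simulate_embryo(ped, cfg, paternal_hap = 2,
                         aneuploidies = tibble::tibble(
                           chrom = c("chr20", "chr21", "chr22"),
                           type = c("loss", "gain", "loss")))
  prof <- emb$cn_profile
  cn_of <- function(ch) unique(prof$cn[prof$chrom == ch])
  expect_equal(cn_of("chr20"), 1)
  expect_equal(cn_of("chr21"), 3)
  expect_equal(cn_of("chr22"), 1)
  expect_equal(cn_of("chr19"), 2)
  # non-carrier embryo: diploid across the duplication chromosome
  expect_equal(cn_of("chr1"), 2)
  # carrier embryo gains one copy over the region only
  emb2 <- simulate_embryo(ped, cfg, paternal_hap = 1)
  p1 <- emb2$cn_profile |> dplyr::filter(chrom == "chr1")
  expect_equal(p1$cn[p1$start == ped$dup_region$start], 3)
  expect_equal(sort(unique(p1$cn)), c(2, 3))
  expect_true(emb2$dup_transmitted)
})

test_that("read dosage at CN-3 heterozygous sites averages 1/3 or 2/3", {
  cfg <- sim_config(seed = 23, ado_rate = 0, false_allele_rate = 0,
                    mean_site_depth = 60)
  n <- 5000
  two_alt <- tibble::tibble(rsid = paste0("s", 1:n), chrom = "chr1",
                            pos = 1:n, ref = "C", alt = "T",
                            n_ref = 1L, n_alt = 2L)
  obs <- simulate_allele_depths(two_alt, cfg)
  expect_equal(mean(obs$af, na.rm = TRUE), 2 / 3, tolerance = 0.01)
  one_alt <- dplyr::mutate(two_alt, n_ref = 2L, n_alt = 1L)
  obs2 <- simulate_allele_depths(one_alt, cfg)
  expect_equal(mean(obs2$af, na.rm = TRUE), 1 / 3, tolerance = 0.01)
})

test_that("noise-free high-depth observations recover truth everywhere", {
  cfg <- sim_config(seed = 29, n_snps_flank = 40, n_snps_inside = 10,
                    ado_rate = 0, false_allele_rate = 0,
                    mean_site_depth = 300)
  fam <- simulate_family(cfg, n_embryos = 1)
  geno <- tidy(apply_qc(fam$observations))
  truth <- fam$pedigree$panel
  mother <- dplyr::filter(geno, sample == "Female") |> dplyr::arrange(pos)
  expect_equal(nrow(mother), nrow(truth))
  expect_equal(mother$a1, pmin(truth$m_hap1, truth$m_hap2))
})

test_that("binned counts follow overlap-weighted copy-number dosage", {
  cfg <- sim_config(seed = 31)
  reg <- cfg$dup_region
  prof <- flat_profile()
  prof <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = 1, end = reg$start - 1, cn = 2),
    tibble::tibble(chrom = "chr1", start = reg$start, end = reg$end, cn = 3),
    tibble::tibble(chrom = "chr1", start = reg$end + 1, end = 249250621,
                   cn = 2)
  )
  rpb <- 2000
  reps <- 40
  sums <- replicate(reps, {
    b <- simulate_bin_counts(prof, cfg, bin_size = 4e5, reads_per_bin = rpb)
    list(flat = mean(b$count[b$end < reg$start - 4e5]),
         dup = mean(b$count[b$start >= reg$start & b$end <= reg$end]),
         straddle = b$count[b$start <= reg$start & b$end >= reg$start])
  }, simplify = FALSE)
  flat <- mean(vapply(sums, `[[`, 0, "flat"))
  dup <- mean(vapply(sums, `[[`, 0, "dup"))
  straddle <- mean(vapply(sums, `[[`, 0, "straddle"))
  expect_equal(flat, rpb, tolerance = 0.01)
  expect_equal(dup, 1.5 * rpb, tolerance = 0.01)
  # start-straddling bin: 23.5% of it is duplicated
  ov <- (ceiling(reg$start / 4e5) * 4e5 - reg$start + 1) / 4e5
  expect_equal(straddle, (2 + ov) / 2 * rpb, tolerance = 0.02)
})

test_that("realized totals conserve the configured read budget", {
  cfg <- sim_config(seed = 37, reads_total = 2e6, chroms = "chr1")
  b <- simulate_bin_counts(flat_profile(), cfg, bin_size = 1e6,
                           chroms = "chr1")
  expect_equal(sum(b$count), 2e6, tolerance = 0.01)
})
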