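test_that("distances to the duplication match every printed value", {
  reg <- dup_region()
  raw <- table1_raw()
  flank <- raw[!is.na(raw$Distance), ]
  d <- compute_distance(as.numeric(flank$POS), reg)
  expect_equal(nrow(flank), 12)
  expect_equal(d$distance_bp, as.numeric(flank$Distance))
  expect_equal(unique(d$side[d$distance_bp < 0]), "upstream")
  expect_equal(unique(d$side[d$distance_bp > 0]), "downstream")
  # boundary positions classify as inside with no distance
  b <- compute_distance(c(reg$start, reg$end), reg)
  expect_equal(b$side, c("inside", "inside"))
  expect_true(all(is.na(b$distance_bp)))
  expect_error(compute_distance(0, reg))
})

test_that("informative-SNP selection applies the carrier-trio rules", {
  g <- table1_geno()
  inf <- select_informative_snps(g, dup_region())
  expect_equal(nrow(inf), 22)
  expect_equal(sum(inf$snp_class == "flanking"), 12)
  expect_equal(sum(inf$snp_class == "within_dup"), 10)

  # father homozygous, mother heterozygous, or out-of-window sites drop
  sites <- make_geno(list(
    hom_father = list(145000000, Male = "C/C", Female = "A/A",
                      Proband = "A/C"),
    het_mother = list(145000001, Male = "C/G", Female = "C/G",
                      Proband = "C/C"),
    too_far = list(140000000, Male = "C/G", Female = "C/C",
                   Proband = "C/C"),
    good = list(145000002, Male = "C/G", Female = "C/C", Proband = "C/C")
  ))
  inf2 <- select_informative_snps(sites, dup_region())
  expect_equal(inf2$rsid, "good")
  # inside the duplication the proband must be homozygous like the mother
  inside <- make_geno(list(
    ok = list(146800000, Male = "T/C", Female = "T/T", Proband = "T/T"),
    proband_het = list(146800001, Male = "T/C", Female = "T/T",
                       Proband = "T/C")
  ))
  inf3 <- select_informative_snps(inside, dup_region())
  expect_equal(inf3$rsid, "ok")
  expect_equal(inf3$snp_class, "within_dup")
})

test_that("proband-anchored phasing reproduces the printed haplotypes", {
  g <- table1_geno()
  phased <- phase_paternal(select_informative_snps(g, dup_region()))
  raw <- table1_raw()
  flank <- raw[!is.na(raw$Paternal_hap1), ]
  m <- dplyr::inner_join(tidy(phased),
                         dplyr::select(flank, rsid = RSID,
                                       hap1 = Paternal_hap1,
                                       hap2 = Paternal_hap2),
                         by = "rsid")
  expect_equal(nrow(m), 12)
  expect_equal(m$hap1_allele, m$hap1)
  expect_equal(m$hap2_allele, m$hap2)
  # within the duplication, hap 1 is the shared mother/proband allele
  inside <- dplyr::filter(tidy(phased), snp_class == "within_dup")
  expect_equal(nrow(inside), 10)
  expect_equal(inside$hap1_allele, inside$mother_allele)
  expect_true(all(inside$hap2_allele != inside$hap1_allele))
})

test_that("Mendelian-inconsistent sites are dropped from phasing", {
  sites <- make_geno(list(
    good = list(145000002, Male = "C/G", Female = "C/C", Proband = "C/C"),
    impossible = list(145000003, Male = "C/G", Female = "C/C",
                      Proband = "T/T")
  ))
  inf <- select_informative_snps(sites, dup_region())
  expect_equal(nrow(inf), 2)
  expect_message(phased <- phase_paternal(inf), "impossible")
  expect_equal(tidy(phased)$rsid, "good")
  # a lone unphaseable panel fails loudly
  expect_error(
    suppressMessages(phase_paternal(inf[inf$rsid == "impossible", ])),
    "no informative site")
})

test_that("embryo classification reproduces the published five verdicts", {
  g <- table1_geno()
  phased <- phase_paternal(select_informative_snps(g, dup_region()))
  v <- classify_embryos(g, phased, paste0("E", 1:5))
  status <- setNames(v$status, v$embryo)
  expect_equal(status[["E1"]], "high_risk")
  expect_equal(status[["E2"]], "low_risk")
  expect_equal(status[["E3"]], "high_risk")
  expect_equal(status[["E4"]], "high_risk")
  expect_equal(status[["E5"]], "low_risk")
  # E2: every usable vote is low-risk, the two no-calls are skipped
  e2 <- dplyr::filter(tidy(v), embryo == "E2")
  expect_equal(sum(e2$vote == "hap2"), 20)
  expect_equal(sum(e2$vote == "no_call"), 2)
  expect_equal(v$consistency, rep(1, 5))
  expect_false(any(v$recombination_flag))
  # an embryo with no genotypes at all is inconclusive
  blank <- dplyr::mutate(dplyr::filter(g, sample == "E1"), sample = "E9",
                         a1 = NA_character_, a2 = NA_character_)
  v9 <- classify_embryos(dplyr::bind_rows(g, blank), phased, "E9")
  expect_equal(v9$status, "inconclusive")
  expect_equal(v9$n_informative_used, 0)
})

test_that("swapping the haplotype labels flips every verdict", {
  # the flanking vote rule is label-symmetric; within-duplication votes
  # are anchored on hap 1 being the mother-shared allele, so symmetry is
  # checked on the flanking panel
  g <- table1_geno()
  phased <- phase_paternal(select_informative_snps(g, dup_region()))
  phased <- phased[phased$snp_class == "flanking", ]
  swapped <- phased
  swapped$hap1_allele <- phased$hap2_allele
  swapped$hap2_allele <- phased$hap1_allele
  v <- classify_embryos(g, phased, paste0("E", 1:5))
  vs <- classify_embryos(g, swapped, paste0("E", 1:5))
  flip <- c(high_risk = "low_risk", low_risk = "high_risk",
            inconclusive = "inconclusive")
  expect_equal(vs$status, unname(flip[v$status]))
})

test_that("flank disagreement is flagged as recombination, not risk", {
  g <- table1_geno()
  phased <- phase_paternal(select_informative_snps(g, dup_region()))
  # build a synthetic embryo carrying hap1 upstream and hap2 downstream
  key <- tidy(phased)
  mk <- function(rs, allele_col) {
    row <- key[key$rsid == rs, ]
    pat <- row[[allele_col]]
    tibble::tibble(rsid = rs, chrom = "chr1", pos = row$pos, sample = "EX",
                   a1 = pmin(pat, row$mother_allele),
                   a2 = pmax(pat, row$mother_allele))
  }
  up <- dplyr::filter(key, side == "upstream")$rsid
  down <- dplyr::filter(key, side == "downstream")$rsid
  embryo <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(up, mk, allele_col = "hap1_allele")),
    dplyr::bind_rows(lapply(down, mk, allele_col = "hap2_allele"))
  )
  v <- classify_embryos(dplyr::bind_rows(table1_geno(), embryo), phased, "EX")
  expect_true(v$recombination_flag)
  expect_equal(v$status, "inconclusive")
})

test_that("phasing recovers the simulated duplication haplotype exactly", {
  cfg <- sim_config(seed = 41, n_snps_flank = 30, n_snps_inside = 10,
                    ado_rate = 0, false_allele_rate = 0,
                    mean_site_depth = 300)
  fam <- simulate_family(cfg, n_embryos = 0)
  geno <- tidy(apply_qc(fam$observations))
  phased <- phase_paternal(select_informative_snps(geno, cfg$dup_region))
  truth <- fam$pedigree$panel
  m <- dplyr::inner_join(tidy(phased),
                         dplyr::select(truth, rsid, f_hap1, f_hap2),
                         by = "rsid")
  expect_gt(nrow(m), 0)
  expect_equal(m$hap1_allele, m$f_hap1)
  expect_equal(m$hap2_allele, m$f_hap2)
})

test_that("the linkage report flattens verdicts one row per embryo", {
  g <- table1_geno()
  phased <- phase_paternal(select_informative_snps(g, dup_region()))
  v <- classify_embryos(g, phased, paste0("E", 1:5))
  rep <- linkage_report(v)
  expect_equal(nrow(rep), 5)
  expect_false("votes" %in% names(rep))
  cfg <- sim_config(seed = 43, n_snps_flank = 10, n_snps_inside = 5,
                    ado_rate = 0, false_allele_rate = 0,
                    mean_site_depth = 100, recomb_prob = 0)
  fam <- simulate_family(cfg, n_embryos = 20)
  geno <- tidy(apply_qc(fam$observations))
  ph <- phase_paternal(select_informative_snps(geno, cfg$dup_region))
  v20 <- classify_embryos(geno, ph, names(fam$embryos))
  expect_equal(nrow(linkage_report(v20)), 20)
})
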