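#' Signed distance from a SNP to a duplication boundary
#'
#' Positions upstream of the region get the (negative) distance to the
#' region start, positions downstream the (positive) distance to the
#' region end; positions inside the region (boundaries included) are
#' class `"inside"` with distance `NA`.
#'
#' @param pos SNP position(s), 1-based bp.
#' @param region A `pgt_region`.
#' @return Tibble with `side` (`upstream`/`inside`/`downstream`) and
#'   `distance_bp` (signed, `NA` inside).
#' @examples
#' reg <- parse_region("chr1:146305863-147992406")
#' compute_distance(c(144939820, 149860372, 146305863), reg)
#' @export
compute_distance <- function(pos, region) {
  stopifnot(inherits(region, "pgt_region"), all(pos >= 1))
  side <- case_when(pos < region$start ~ "upstream",
                    pos > region$end ~ "downstream",
                    .default = "inside")
  distance_bp <- case_when(side == "upstream" ~ pos - region$start,
                           side == "downstream" ~ pos - region$end,
                           .default = NA_real_)
  tibble(side = side, distance_bp = distance_bp)
}

geno_wide <- function(geno, samples) {
  stopifnot(all(c("rsid", "chrom", "pos", "sample", "a1", "a2") %in%
                  names(geno)))
  missing <- setdiff(samples, unique(geno$sample))
  if (length(missing) > 0) {
    abort(paste0("genotype table lacks sample(s): ",
                 paste(missing, collapse = ", ")))
  }
  geno |>
    filter(.data$sample %in% samples) |>
    select("rsid", "chrom", "pos", "sample", "a1", "a2") |>
    pivot_wider(names_from = "sample", values_from = c("a1", "a2"),
                names_glue = "{sample}_{.value}")
}

#' Select informative SNPs for duplication linkage analysis
#'
#' Informative markers are heterozygous in the carrier father and
#' homozygous in the mother.  Two classes are kept:
#'
#' * `flanking` — sites within `flank_bp` of a region boundary (either
#'   side); the transmitted paternal allele is read off offspring
#'   genotypes directly.
#' * `within_dup` — sites inside the duplication where the affected
#'   proband is additionally homozygous for the mother's allele; there
#'   an affected offspring is homozygous like the proband while an
#'   unaffected one is heterozygous.
#'
#' @param geno Long genotype tibble (`rsid`, `chrom`, `pos`, `sample`,
#'   `a1`, `a2`), QC-passed.
#' @param region The duplication `pgt_region`.
#' @param father,mother,proband Sample names (defaults follow the
#'   pedigree-table convention `Male`/`Female`/`Proband`).
#' @param flank_bp Flank window in bp (default 2e6).
#' @return Tibble of informative sites: `rsid`, `chrom`, `pos`,
#'   `snp_class`, `side`, `distance_bp`, `father_a1`, `father_a2`,
#'   `mother_allele`, `proband_a1`, `proband_a2`.
#' @export
select_informative_snps <- function(geno, region, father = "Male",
                                    mother = "Female", proband = "Proband",
                                    flank_bp = 2e6) {
  wide <- geno_wide(geno, c(father, mother, proband)) |>
    rename(father_a1 = paste0(father, "_a1"),
           father_a2 = paste0(father, "_a2"),
           mother_a1 = paste0(mother, "_a1"),
           mother_a2 = paste0(mother, "_a2"),
           proband_a1 = paste0(proband, "_a1"),
           proband_a2 = paste0(proband, "_a2")) |>
    filter(.data$chrom == region$chrom)
  wide |>
    bind_cols(compute_distance(wide$pos, region)) |>
    mutate(
      father_het = !is.na(.data$father_a1) &
        .data$father_a1 != .data$father_a2,
      mother_hom = !is.na(.data$mother_a1) &
        .data$mother_a1 == .data$mother_a2,
      snp_class = case_when(
        .data$father_het & .data$mother_hom & .data$side != "inside" &
          abs(.data$distance_bp) <= flank_bp ~ "flanking",
        .data$father_het & .data$mother_hom & .data$side == "inside" &
          !is.na(.data$proband_a1) &
          .data$proband_a1 == .data$proband_a2 &
          .data$proband_a1 == .data$mother_a1 ~ "within_dup",
        .default = NA_character_
      )
    ) |>
    filter(!is.na(.data$snp_class)) |>
    transmute(.data$rsid, .data$chrom, .data$pos, .data$snp_class,
              .data$side, .data$distance_bp,
              .data$father_a1, .data$father_a2,
              mother_allele = .data$mother_a1,
              .data$proband_a1, .data$proband_a2)
}

## transmitted paternal allele of an offspring given a homozygous
## mother: remove one maternal allele from the offspring genotype.
## Returns NA when transmission is Mendelian-impossible.
paternal_allele_of <- function(o1, o2, m) {
  case_when(
    is.na(o1) | is.na(m) ~ NA_character_,
    o1 == m & o2 == m ~ m,
    o1 == m ~ o2,
    o2 == m ~ o1,
    .default = NA_character_
  )
}

#' Phase the carrier father's high- and low-risk haplotypes
#'
#' Anchors phasing on the affected proband, who inherited the
#' duplication-bearing paternal haplotype (hap 1).  At flanking sites
#' the paternal allele transmitted to the proband (proband genotype
#' minus one maternal allele) becomes the hap-1 allele and the father's
#' other allele hap 2.  At within-duplication sites the proband is
#' homozygous for the mother's allele, so that allele is hap 1 and the
#' father's other allele hap 2.  Sites whose proband genotype is
#' incompatible with the parents are dropped with a
#' Mendelian-inconsistency message; a proband no-call likewise drops
#' the site.
#'
#' @param informative A [select_informative_snps()] tibble.
#' @return A `pgt_phase` tibble: the informative sites that could be
#'   phased, plus `hap1_allele` (high risk) and `hap2_allele`
#'   (low risk).  Attributes record the dropped sites.
#' @export
phase_paternal <- function(informative) {
  inf <- informative |>
    mutate(
      transmitted = case_when(
        .data$snp_class == "flanking" ~ paternal_allele_of(
          .data$proband_a1, .data$proband_a2, .data$mother_allele),
        .default = .data$mother_allele
      ),
      hap1_allele = .data$transmitted,
      hap2_allele = case_when(
        .data$transmitted == .data$father_a1 ~ .data$father_a2,
        .data$transmitted == .data$father_a2 ~ .data$father_a1,
        .default = NA_character_
      )
    )
  dropped <- inf |> filter(is.na(.data$hap1_allele) | is.na(.data$hap2_allele))
  phased <- inf |>
    filter(!is.na(.data$hap1_allele), !is.na(.data$hap2_allele)) |>
    select(-"transmitted")
  if (nrow(dropped) > 0) {
    inform(paste0(nrow(dropped), " informative site(s) dropped during ",
                  "phasing (proband no-call or Mendelian inconsistency): ",
                  paste(dropped$rsid, collapse = ", ")))
  }
  if (nrow(phased) == 0) {
    abort("no informative site could be phased through the proband")
  }
  structure(phased, class = c("pgt_phase", class(phased)),
            dropped = select(dropped, -"transmitted"))
}

#' @rdname phase_paternal
#' @param x A `pgt_phase` object.
#' @param ... Unused.
#' @method tidy pgt_phase
#' @export
tidy.pgt_phase <- function(x, ...) as_tibble(x)

#' @rdname phase_paternal
#' @method glance pgt_phase
#' @export
glance.pgt_phase <- function(x, ...) {
  tibble(
    n_sites = nrow(x),
    n_flanking = sum(x$snp_class == "flanking"),
    n_within_dup = sum(x$snp_class == "within_dup"),
    n_upstream = sum(x$side == "upstream"),
    n_downstream = sum(x$side == "downstream"),
    n_dropped = nrow(attr(x, "dropped"))
  )
}

vote_site <- function(e1, e2, snp_class, mother_allele, hap1, hap2) {
  pat <- paternal_allele_of(e1, e2, mother_allele)
  case_when(
    is.na(e1) ~ "no_call",
    snp_class == "flanking" & !is.na(pat) & pat == hap1 &
      pat != hap2 ~ "hap1",
    snp_class == "flanking" & !is.na(pat) & pat == hap2 &
      pat != hap1 ~ "hap2",
    snp_class == "within_dup" & e1 == e2 & e1 == hap1 ~ "hap1",
    snp_class == "within_dup" & e1 != e2 &
      pmin(hap1, hap2) == pmin(e1, e2) &
      pmax(hap1, hap2) == pmax(e1, e2) ~ "hap2",
    .default = "no_call"
  )
}

#' Classify embryos against the phased paternal haplotypes
#'
#' Each informative SNP casts one vote.  At flanking sites the
#' embryo's paternal allele (embryo genotype minus one maternal
#' allele) is matched to hap 1 / hap 2; ambiguous or
#' Mendelian-inconsistent deductions vote `no_call`.  At
#' within-duplication sites an embryo homozygous like the proband
#' votes hap 1 (affected) and a heterozygous embryo votes hap 2.
#'
#' The verdict is `high_risk`/`low_risk` by majority vote, subject to
#' conservative clinical-style thresholds: at least `min_votes`
#' informative votes, at least `min_per_flank` on each flank,
#' majority consistency at least `min_consistency`, and agreement
#' between the upstream and downstream flank majorities (disagreement
#' flags a putative recombination and forces `inconclusive` — a
#' crossover between flank and duplication breaks linkage, so no risk
#' call is made).
#'
#' @param geno Long genotype tibble containing the embryo samples.
#' @param phased A [phase_paternal()] result.
#' @param embryos Character vector of embryo sample names.
#' @param min_votes Minimum informative votes for a call (default 3).
#' @param min_per_flank Minimum votes on each flank (default 1).
#' @param min_consistency Minimum majority fraction (default 0.9).
#' @return A `pgt_verdicts` tibble, one row per embryo: `embryo`,
#'   `status` (`high_risk`/`low_risk`/`inconclusive`), vote counts,
#'   per-side consistencies, `recombination_flag`, and a `votes`
#'   list-column of per-SNP assignments.
#' @export
classify_embryos <- function(geno, phased, embryos,
                             min_votes = 3, min_per_flank = 1,
                             min_consistency = 0.9) {
  stopifnot(inherits(phased, "pgt_phase"), length(embryos) > 0)
  key <- as_tibble(phased) |>
    select("rsid", "pos", "snp_class", "side", "mother_allele",
           "hap1_allele", "hap2_allele")
  rows <- map(embryos, function(e) {
    eg <- geno |>
      filter(.data$sample == e) |>
      select("rsid", e_a1 = "a1", e_a2 = "a2")
    votes <- key |>
      left_join(eg, by = "rsid") |>
      mutate(vote = vote_site(.data$e_a1, .data$e_a2, .data$snp_class,
                              .data$mother_allele, .data$hap1_allele,
                              .data$hap2_allele))
    summarise_votes(e, votes, min_votes, min_per_flank, min_consistency)
  })
  structure(list_rbind(rows), class = c("pgt_verdicts", "tbl_df", "tbl",
                                        "data.frame"))
}

summarise_votes <- function(embryo, votes, min_votes, min_per_flank,
                            min_consistency) {
  counted <- votes |> filter(.data$vote %in% c("hap1", "hap2"))
  n1 <- sum(counted$vote == "hap1")
  n2 <- sum(counted$vote == "hap2")
  total <- n1 + n2
  majority <- if (total == 0 || n1 == n2) NA_character_
    else if (n1 > n2) "hap1" else "hap2"
  side_majority <- function(s) {
    v <- counted$vote[counted$side == s]
    if (length(v) == 0) return(NA_character_)
    k1 <- sum(v == "hap1")
    if (k1 * 2 == length(v)) NA_character_
    else if (k1 * 2 > length(v)) "hap1" else "hap2"
  }
  side_consistency <- function(s) {
    v <- counted$vote[counted$side == s]
    if (length(v) == 0 || is.na(majority)) return(NA_real_)
    mean(v == majority)
  }
  up <- side_majority("upstream")
  down <- side_majority("downstream")
  recomb <- !is.na(up) && !is.na(down) && up != down
  consistency <- if (total > 0 && !is.na(majority))
    max(n1, n2) / total else NA_real_
  flank_ok <- sum(counted$side == "upstream") >= min_per_flank &&
    sum(counted$side == "downstream") >= min_per_flank
  status <- if (is.na(majority) || total < min_votes || !flank_ok ||
                recomb || consistency < min_consistency) {
    "inconclusive"
  } else if (majority == "hap1") "high_risk" else "low_risk"
  tibble(
    embryo = embryo, status = status,
    n_informative_used = total, n_hap1 = n1, n_hap2 = n2,
    consistency = consistency,
    upstream_consistency = side_consistency("upstream"),
    downstream_consistency = side_consistency("downstream"),
    inside_consistency = side_consistency("inside"),
    recombination_flag = recomb,
    votes = list(select(votes, "rsid", "pos", "snp_class", "side",
                        "e_a1", "e_a2", "vote"))
  )
}

#' @rdname classify_embryos
#' @param embryo A single embryo sample name.
#' @export
classify_embryo <- function(geno, phased, embryo, min_votes = 3,
                            min_per_flank = 1, min_consistency = 0.9) {
  classify_embryos(geno, phased, embryo, min_votes, min_per_flank,
                   min_consistency)
}

#' @rdname classify_embryos
#' @param x A `pgt_verdicts` object.
#' @param ... Unused.
#' @method tidy pgt_verdicts
#' @export
tidy.pgt_verdicts <- function(x, ...) {
  as_tibble(x) |>
    select("embryo", "votes") |>
    unnest("votes")
}

#' @rdname classify_embryos
#' @method glance pgt_verdicts
#' @export
glance.pgt_verdicts <- function(x, ...) {
  tibble(n_embryos = nrow(x),
         n_high_risk = sum(x$status == "high_risk"),
         n_low_risk = sum(x$status == "low_risk"),
         n_inconclusive = sum(x$status == "inconclusive"))
}

#' Flat per-embryo linkage report
#'
#' Serializes verdicts to a plain tibble (no list-columns), suitable
#' for [write_report()].
#'
#' @param verdicts A [classify_embryos()] result.
#' @return A tibble with one row per embryo.
#' @export
linkage_report <- function(verdicts) {
  as_tibble(verdicts) |>
    select(-any_of("votes")) |>
    mutate(across(ends_with("consistency"), ~ round(.x, 4)))
}
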