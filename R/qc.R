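#' Genotype QC thresholds
#'
#' Depth and allele-fraction filters applied to shallow-coverage,
#' WGA-amplified genotype observations before linkage analysis.  Sites
#' below `min_depth` reads are discarded.  The two published
#' allele-fraction filters (heterozygotes kept only inside
#' \[0.2, 0.8\]; homozygotes kept only outside (0.1, 0.9)) combine into
#' one decision rule on the alt-allele fraction `af`:
#'
#' * `af <= 0.1` — homozygous reference
#' * `0.2 <= af <= 0.8` — heterozygous
#' * `af >= 0.9` — homozygous alternate
#' * the gaps `(0.1, 0.2)` and `(0.8, 0.9)` — low quality, filtered
#'
#' so that every fraction maps to exactly one outcome.
#'
#' @param min_depth Minimum total reads for a usable call (default 4).
#' @param het_af Closed interval of alt fractions called heterozygous.
#' @param hom_af_exclude Open interval outside which a call is
#'   homozygous.
#' @return A `pgt_qc_thresholds` list.
#' @export
qc_thresholds <- function(min_depth = 4, het_af = c(0.2, 0.8),
                          hom_af_exclude = c(0.1, 0.9)) {
  stopifnot(min_depth >= 0, length(het_af) == 2, length(hom_af_exclude) == 2,
            all(het_af >= 0 & het_af <= 1),
            all(hom_af_exclude >= 0 & hom_af_exclude <= 1),
            het_af[1] <= het_af[2],
            # the het band must sit inside the hom exclusion zone so the
            # rule partitions [0,1]
            hom_af_exclude[1] <= het_af[1], het_af[2] <= hom_af_exclude[2])
  structure(list(min_depth = min_depth, het_af = het_af,
                 hom_af_exclude = hom_af_exclude),
            class = "pgt_qc_thresholds")
}

#' Call a diploid genotype from allele depths
#'
#' Vectorized decision rule; see [qc_thresholds()] for the bands.
#' Zero total depth yields `no_call`, depth below the floor
#' `low_depth`, fractions in the low-quality gaps `ambiguous_af`; the
#' remaining classes are `hom_ref`, `het`, `hom_alt`, for which the
#' allele columns `a1`/`a2` are populated from `ref`/`alt`.
#'
#' @param ad_ref,ad_alt Reads supporting the reference / alternate
#'   allele (non-negative, recycled to a common length).
#' @param ref,alt Allele symbols.
#' @param thresholds A [qc_thresholds()] object.
#' @return A tibble with `dp`, `af`, `class`, `a1`, `a2`.
#' @examples
#' call_genotype(c(2, 17, 10, 0), c(1, 3, 10, 40), "A", "G")
#' @export
call_genotype <- function(ad_ref, ad_alt, ref = "A", alt = "B",
                          thresholds = qc_thresholds()) {
  stopifnot(all(ad_ref >= 0, na.rm = TRUE), all(ad_alt >= 0, na.rm = TRUE))
  n <- max(length(ad_ref), length(ad_alt))
  ad_ref <- rep_len(ad_ref, n); ad_alt <- rep_len(ad_alt, n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  dp <- ad_ref + ad_alt
  af <- ifelse(dp > 0, ad_alt / dp, NA_real_)
  thr <- thresholds
  class <- case_when(
    dp == 0 ~ "no_call",
    dp < thr$min_depth ~ "low_depth",
    af <= thr$hom_af_exclude[1] ~ "hom_ref",
    af >= thr$hom_af_exclude[2] ~ "hom_alt",
    af >= thr$het_af[1] & af <= thr$het_af[2] ~ "het",
    .default = "ambiguous_af"
  )
  called <- class %in% c("hom_ref", "het", "hom_alt")
  a1 <- ifelse(called, ifelse(class == "hom_alt", alt, ref), NA_character_)
  a2 <- ifelse(called, ifelse(class == "hom_ref", ref, alt), NA_character_)
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  tibble(dp = dp, af = af, class = class, a1 = lo, a2 = hi)
}

#' Apply genotype QC to a sample's observations
#'
#' Calls genotypes from allele depths and keeps only passing sites.
#'
#' @param observations Tibble with at least `ad_ref`, `ad_alt`, `ref`,
#'   `alt` (typically also `rsid`, `chrom`, `pos`, `sample`).
#' @param thresholds A [qc_thresholds()] object.
#' @return A `pgt_qc` object: list with `$calls` (passing sites, the
#'   input columns plus `dp`, `af`, `class`, `a1`, `a2`) and
#'   `$summary` (one row per sample: sites in, passing, and counts
#'   removed by each rule).  `tidy()` returns the calls, `glance()` the
#'   summary.
#' @export
apply_qc <- function(observations, thresholds = qc_thresholds()) {
  stopifnot(all(c("ad_ref", "ad_alt", "ref", "alt") %in% names(observations)))
  called <- observations |>
    select(-any_of(c("dp", "af", "a1", "a2", "class"))) |>
    bind_cols(call_genotype(observations$ad_ref, observations$ad_alt,
                            observations$ref, observations$alt, thresholds))
  grouping <- if ("sample" %in% names(called)) "sample" else character()
  summary <- called |>
    group_by(across(all_of(grouping))) |>
    summarise(
      n_sites = n(),
      n_pass = sum(.data$class %in% c("hom_ref", "het", "hom_alt")),
      n_no_call = sum(.data$class == "no_call"),
      n_low_depth = sum(.data$class == "low_depth"),
      n_ambiguous_af = sum(.data$class == "ambiguous_af"),
      .groups = "drop"
    )
  structure(
    list(calls = filter(called,
                        .data$class %in% c("hom_ref", "het", "hom_alt")),
         summary = summary,
         thresholds = thresholds),
    class = "pgt_qc"
  )
}

#' @export
print.pgt_qc <- function(x, ...) {
  cat("<pgt_qc> ", sum(x$summary$n_pass), "/", sum(x$summary$n_sites),
      " site calls pass QC (min depth ", x$thresholds$min_depth, ")\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname apply_qc
#' @param x A `pgt_qc` object.
#' @param ... Unused.
#' @method tidy pgt_qc
#' @export
tidy.pgt_qc <- function(x, ...) x$calls

#' @rdname apply_qc
#' @method glance pgt_qc
#' @export
glance.pgt_qc <- function(x, ...) x$summary
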