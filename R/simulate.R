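#' GRCh37 autosome lengths
#'
#' Chromosome sizes used for the simulated genome grid (autosomes only;
#' sex-chromosome ploidy is out of scope).
#'
#' @return A tibble with `chrom`, `length`.
#' @export
hg19_autosomes <- function() {
  tibble(
    chrom = paste0("chr", 1:22),
    length = c(249250621, 243199373, 198022430, 191154276, 180915260,
               171115067, 159138663, 146364022, 141213431, 135534747,
               135006516, 133851895, 115169878, 107349540, 102531392,
               90354753, 81195210, 78077248, 59128983, 63025520,
               48129895, 51304566)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic pedigree/embryo generator.  Defaults
#' emulate the shallow-sequencing PGT setting the package targets: a
#' carrier father with a heterozygous tandem duplication
#' (`chr1:146305863-147992406`, one extra copy on paternal haplotype 1),
#' a non-carrier mother, an affected proband, informative-SNP panels in
#' the 2 Mb flanks, about five million valid reads genome-wide, and
#' WGA-style allele dropout.
#'
#' @param dup_region `pgt_region` carrying the duplication.
#' @param flank_bp Flank window for informative SNPs (bp, default 2e6).
#' @param n_snps_flank SNPs simulated per flank side (default 20).
#' @param n_snps_inside SNPs simulated inside the duplication
#'   (default 10).
#' @param maf_range Range the per-site minor-allele frequency is drawn
#'   from (default \[0.1, 0.5\]).
#' @param mean_site_depth Mean reads per targeted SNP site (default 30;
#'   genome-wide coverage in this assay is far shallower, but SNP
#'   typing relies on recovered depth at the targeted sites).
#' @param depth_dispersion Negative-binomial size for per-site depth;
#'   `Inf` (default) gives Poisson depth.
#' @param ado_rate Probability that a truly present allele drops out
#'   before amplification (per distinct allele per site; default 0.05).
#' @param false_allele_rate Probability a read reports the other allele
#'   (default 0.01).
#' @param reads_total Genome-wide valid reads for copy-number binning
#'   (default 5e6).
#' @param reads_per_bin Optional fixed baseline mean per full bin;
#'   when `NULL`, derived from `reads_total` and the covered genome.
#' @param bin_size_bp Bin width for read counting (default 1e6; use
#'   4e5 for the targeted high-resolution pass).
#' @param recomb_prob Per-meiosis probability of a single crossover
#'   within the simulated SNP window (default 0.01).
#' @param chroms Chromosomes simulated for binning (autosomes).
#' @param seed Optional integer seed; generators are deterministic
#'   given a seed.
#' @return A `pgt_sim_config` list.
#' @export
sim_config <- function(dup_region = parse_region("chr1:146305863-147992406"),
                       flank_bp = 2e6,
                       n_snps_flank = 20,
                       n_snps_inside = 10,
                       maf_range = c(0.1, 0.5),
                       mean_site_depth = 30,
                       depth_dispersion = Inf,
                       ado_rate = 0.05,
                       false_allele_rate = 0.01,
                       reads_total = 5e6,
                       reads_per_bin = NULL,
                       bin_size_bp = 1e6,
                       recomb_prob = 0.01,
                       chroms = paste0("chr", 1:22),
                       seed = NULL) {
  stopifnot(inherits(dup_region, "pgt_region"), flank_bp > 0,
            n_snps_flank >= 1, n_snps_inside >= 0,
            all(maf_range >= 0 & maf_range <= 0.5),
            maf_range[1] <= maf_range[2],
            mean_site_depth > 0, ado_rate >= 0, ado_rate <= 1,
            false_allele_rate >= 0, false_allele_rate <= 1,
            reads_total > 0, bin_size_bp > 0,
            recomb_prob >= 0, recomb_prob <= 1)
  structure(
    list(dup_region = dup_region, flank_bp = flank_bp,
         n_snps_flank = n_snps_flank, n_snps_inside = n_snps_inside,
         maf_range = maf_range, mean_site_depth = mean_site_depth,
         depth_dispersion = depth_dispersion, ado_rate = ado_rate,
         false_allele_rate = false_allele_rate, reads_total = reads_total,
         reads_per_bin = reads_per_bin, bin_size_bp = bin_size_bp,
         recomb_prob = recomb_prob, chroms = chroms, seed = seed),
    class = "pgt_sim_config"
  )
}

draw_positions <- function(lo, hi, n) sort(sample(seq(lo, hi), n))

#' Simulate a carrier-father pedigree
#'
#' Draws a SNP panel inside the duplication and in its two flanks and
#' four parental haplotypes from per-site allele frequencies.  Paternal
#' haplotype 1 carries the duplication (the father's copy number is 3
#' inside the region, 2 outside).  Haplotypes are redrawn (bounded)
#' until each flank holds at least one informative site (father
#' heterozygous, mother homozygous), since linkage analysis needs both
#' flanks.
#'
#' @param config A [sim_config()]; `config$seed`, when set, makes the
#'   draw deterministic.
#' @return A `pgt_pedigree`: list with `$panel` (tibble: `rsid`,
#'   `chrom`, `pos`, `side`, `ref`, `alt`, `maf`, haplotype allele
#'   columns `f_hap1`, `f_hap2`, `m_hap1`, `m_hap2`), `$dup_region`,
#'   `$flank_bp`.
#' @export
simulate_pedigree <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  reg <- config$dup_region
  pos <- c(draw_positions(max(1, reg$start - config$flank_bp), reg$start - 1,
                          config$n_snps_flank),
           if (config$n_snps_inside > 0)
             draw_positions(reg$start, reg$end, config$n_snps_inside),
           draw_positions(reg$end + 1, reg$end + config$flank_bp,
                          config$n_snps_flank))
  pos <- sort(pos)
  n <- length(pos)
  side <- case_when(pos < reg$start ~ "upstream",
                    pos > reg$end ~ "downstream",
                    .default = "inside")
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- map_chr(ref, function(r) sample(setdiff(bases, r), 1))
  maf <- runif(n, config$maf_range[1], config$maf_range[2])
  draw_hap <- function() ifelse(runif(n) < maf, alt, ref)
  for (attempt in seq_len(100)) {
    f_hap1 <- draw_hap(); f_hap2 <- draw_hap()
    m_hap1 <- draw_hap(); m_hap2 <- draw_hap()
    informative <- f_hap1 != f_hap2 & m_hap1 == m_hap2
    if (any(informative[side == "upstream"]) &&
        any(informative[side == "downstream"])) {
      panel <- tibble(
        rsid = sprintf("snp%05d", seq_len(n)), chrom = reg$chrom,
        pos = pos, side = side, ref = ref, alt = alt, maf = maf,
        f_hap1 = f_hap1, f_hap2 = f_hap2, m_hap1 = m_hap1, m_hap2 = m_hap2
      )
      return(structure(list(panel = panel, dup_region = reg,
                            flank_bp = config$flank_bp),
                       class = "pgt_pedigree"))
    }
  }
  abort(paste("could not draw a pedigree with an informative SNP on each",
              "flank in 100 attempts; increase n_snps_flank or widen",
              "maf_range"))
}

#' @export
print.pgt_pedigree <- function(x, ...) {
  cat("<pgt_pedigree> ", nrow(x$panel), " SNPs around ",
      format_region(x$dup_region), " (flank ", x$flank_bp / 1e6, " Mb)\n",
      sep = "")
  invisible(x)
}

hap_at <- function(pos, start_hap, breakpoint) {
  if (is.null(breakpoint)) rep(start_hap, length(pos))
  else ifelse(pos < breakpoint, start_hap, 3L - start_hap)
}

## Carve [start,end] on `chrom` out of a piecewise cn profile and set
## (or shift) its copy number there.  Profiles are small (tens of rows).
profile_set <- function(prof, chrom, start, end, cn = NULL, delta = NULL) {
  out <- list()
  for (k in seq_len(nrow(prof))) {
    r <- prof[k, ]
    if (r$chrom != chrom || r$end < start || r$start > end) {
      out[[length(out) + 1]] <- r
      next
    }
    if (r$start < start) {
      pre_end <- start - 1
      out[[length(out) + 1]] <-
        tibble(chrom = chrom, start = r$start, end = pre_end, cn = r$cn)
    }
    new_cn <- if (!is.null(cn)) cn else r$cn + delta
    mid_start <- max(r$start, start)
    mid_end <- min(r$end, end)
    out[[length(out) + 1]] <-
      tibble(chrom = chrom, start = mid_start, end = mid_end, cn = new_cn)
    if (r$end > end) {
      post_start <- end + 1
      out[[length(out) + 1]] <-
        tibble(chrom = chrom, start = post_start, end = r$end, cn = r$cn)
    }
  }
  bind_rows(out)
}

base_cn_profile <- function(chroms = paste0("chr", 1:22)) {
  hg19_autosomes() |>
    filter(.data$chrom %in% chroms) |>
    transmute(.data$chrom, start = 1, end = .data$length, cn = 2)
}

#' Copy-number profile of a pedigree member
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param who `"father"` (CN 3 over the duplication) or `"mother"`
#'   (flat diploid).
#' @param chroms Chromosomes covered by the profile.
#' @return A tibble `chrom`, `start`, `end`, `cn` partitioning each
#'   chromosome.
#' @export
cn_profile_parent <- function(pedigree, who = c("father", "mother"),
                              chroms = paste0("chr", 1:22)) {
  who <- match.arg(who)
  prof <- base_cn_profile(chroms)
  if (who == "father") {
    reg <- pedigree$dup_region
    prof <- profile_set(prof, reg$chrom, reg$start, reg$end, delta = 1)
  }
  prof
}

#' Simulate one embryo (meiosis + optional aberrations)
#'
#' Transmitted parental haplotypes are drawn uniformly; with
#' probability `recomb_prob` a single crossover is placed uniformly in
#' the simulated SNP window.  The embryo's copy number is 3 over the
#' duplication exactly when a paternal-haplotype-1 segment covering it
#' is transmitted; whole-chromosome aneuploidies shift all bins of the
#' chromosome by one copy, and `extra_cnvs` installs arbitrary
#' segmental copy numbers.
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param config A [sim_config()].
#' @param aneuploidies Optional tibble with `chrom`, `type`
#'   (`"gain"`/`"loss"`) for whole-chromosome aberrations.
#' @param extra_cnvs Optional tibble with `chrom`, `start`, `end`,
#'   `cn` for segmental aberrations.
#' @param paternal_hap,maternal_hap Force the transmitted haplotype
#'   (1 or 2, no crossover); used e.g. to construct the affected
#'   proband, which carries paternal haplotype 1.
#' @return A `pgt_embryo`: list with `$transmission` (per-site tibble
#'   of transmitted haplotypes and alleles), `$cn_profile`,
#'   `$pat_hap_start`, `$pat_breakpoint` (NULL if none), the maternal
#'   equivalents, and `$dup_transmitted`.
#' @export
simulate_embryo <- function(pedigree, config = sim_config(),
                            aneuploidies = NULL, extra_cnvs = NULL,
                            paternal_hap = NULL, maternal_hap = NULL) {
  panel <- pedigree$panel
  reg <- pedigree$dup_region
  window <- c(max(1, reg$start - pedigree$flank_bp),
              reg$end + pedigree$flank_bp)
  draw_side <- function(forced) {
    if (!is.null(forced)) {
      list(start = as.integer(forced), bp = NULL)
    } else {
      list(start = sample(1:2, 1),
           bp = if (runif(1) < config$recomb_prob)
             runif(1, window[1], window[2]) else NULL)
    }
  }
  pat <- draw_side(paternal_hap)
  mat <- draw_side(maternal_hap)
  pat_hap <- hap_at(panel$pos, pat$start, pat$bp)
  mat_hap <- hap_at(panel$pos, mat$start, mat$bp)
  transmission <- tibble(
    rsid = panel$rsid, chrom = panel$chrom, pos = panel$pos,
    side = panel$side,
    pat_hap = pat_hap, mat_hap = mat_hap,
    pat_allele = ifelse(pat_hap == 1L, panel$f_hap1, panel$f_hap2),
    mat_allele = ifelse(mat_hap == 1L, panel$m_hap1, panel$m_hap2)
  )
  prof <- base_cn_profile(config$chroms)
  if (!is.null(aneuploidies) && nrow(aneuploidies) > 0) {
    for (k in seq_len(nrow(aneuploidies))) {
      delta <- if (aneuploidies$type[k] == "gain") 1 else -1
      len <- hg19_autosomes()$length[hg19_autosomes()$chrom ==
                                       aneuploidies$chrom[k]]
      prof <- profile_set(prof, aneuploidies$chrom[k], 1, len, delta = delta)
    }
  }
  # duplication carried on paternal hap 1: mark each sub-interval of the
  # region where the transmitted paternal haplotype is 1
  dup_pieces <- tibble(start = reg$start, end = reg$end)
  if (!is.null(pat$bp) && pat$bp > reg$start && pat$bp <= reg$end) {
    dup_pieces <- tibble(start = c(reg$start, ceiling(pat$bp)),
                         end = c(ceiling(pat$bp) - 1, reg$end))
  }
  for (k in seq_len(nrow(dup_pieces))) {
    mid <- (dup_pieces$start[k] + dup_pieces$end[k]) / 2
    if (hap_at(mid, pat$start, pat$bp) == 1L) {
      prof <- profile_set(prof, reg$chrom, dup_pieces$start[k],
                          dup_pieces$end[k], delta = 1)
    }
  }
  if (!is.null(extra_cnvs) && nrow(extra_cnvs) > 0) {
    for (k in seq_len(nrow(extra_cnvs))) {
      prof <- profile_set(prof, extra_cnvs$chrom[k], extra_cnvs$start[k],
                          extra_cnvs$end[k], cn = extra_cnvs$cn[k])
    }
  }
  structure(
    list(transmission = transmission, cn_profile = prof,
         pat_hap_start = pat$start, pat_breakpoint = pat$bp,
         mat_hap_start = mat$start, mat_breakpoint = mat$bp,
         aneuploidies = aneuploidies,
         dup_transmitted = hap_at((reg$start + reg$end) / 2, pat$start,
                                  pat$bp) == 1L,
         dup_region = reg),
    class = "pgt_embryo"
  )
}

#' Per-site true allele dosage of a family member
#'
#' Counts how many copies of the reference and alternate allele each
#' individual truly carries at every panel site.  The carrier father
#' holds haplotype 1 twice inside the duplication (CN 3); an embryo
#' that inherited a haplotype-1 segment over the region likewise
#' carries its paternal allele twice there.
#'
#' @param pedigree A [simulate_pedigree()] result.
#' @param who `"father"`, `"mother"`, or a `pgt_embryo`.
#' @return Tibble `rsid`, `chrom`, `pos`, `ref`, `alt`, `n_ref`,
#'   `n_alt`.
#' @export
allele_dosage <- function(pedigree, who) {
  panel <- pedigree$panel
  inside <- panel$side == "inside"
  if (inherits(who, "pgt_embryo")) {
    tr <- who$transmission
    stopifnot(identical(tr$rsid, panel$rsid))
    pat_copies <- 1L + as.integer(inside & tr$pat_hap == 1L)
    n_alt <- (tr$pat_allele == panel$alt) * pat_copies +
      (tr$mat_allele == panel$alt)
    n_ref <- (tr$pat_allele == panel$ref) * pat_copies +
      (tr$mat_allele == panel$ref)
  } else if (identical(who, "father")) {
    hap1_copies <- 1L + as.integer(inside)
    n_alt <- (panel$f_hap1 == panel$alt) * hap1_copies +
      (panel$f_hap2 == panel$alt)
    n_ref <- (panel$f_hap1 == panel$ref) * hap1_copies +
      (panel$f_hap2 == panel$ref)
  } else if (identical(who, "mother")) {
    n_alt <- (panel$m_hap1 == panel$alt) + (panel$m_hap2 == panel$alt)
    n_ref <- (panel$m_hap1 == panel$ref) + (panel$m_hap2 == panel$ref)
  } else {
    abort("who must be \"father\", \"mother\", or a pgt_embryo")
  }
  tibble(rsid = panel$rsid, chrom = panel$chrom, pos = panel$pos,
         ref = panel$ref, alt = panel$alt,
         n_ref = as.integer(n_ref), n_alt = as.integer(n_alt))
}

#' Simulate allele-depth observations at SNP sites
#'
#' Sequencing-style noise on top of true allele dosage: total depth is
#' Poisson (or negative binomial when `depth_dispersion` is finite)
#' around `mean_site_depth`; each distinct allele present drops out
#' independently with probability `ado_rate` before reads are drawn
#' (WGA allele dropout — both dropping yields zero depth); surviving
#' reads split binomially in proportion to dosage (so a CN-3
#' heterozygous site averages alt fractions 1/3 or 2/3); finally each
#' read flips to the other allele with probability
#' `false_allele_rate`.
#'
#' @param dosage An [allele_dosage()] tibble.
#' @param config A [sim_config()].
#' @return The dosage tibble plus `ad_ref`, `ad_alt`, `dp`, `af`.
#' @export
simulate_allele_depths <- function(dosage, config = sim_config()) {
  n <- nrow(dosage)
  dp <- if (is.finite(config$depth_dispersion)) {
    rnbinom(n, size = config$depth_dispersion, mu = config$mean_site_depth)
  } else {
    rpois(n, config$mean_site_depth)
  }
  keep_ref <- dosage$n_ref > 0 & runif(n) >= config$ado_rate
  keep_alt <- dosage$n_alt > 0 & runif(n) >= config$ado_rate
  dose_ref <- dosage$n_ref * keep_ref
  dose_alt <- dosage$n_alt * keep_alt
  total <- dose_ref + dose_alt
  dp <- ifelse(total > 0, dp, 0L)
  ad_alt <- rbinom(n, dp, ifelse(total > 0, dose_alt / pmax(total, 1), 0))
  ad_ref <- dp - ad_alt
  if (config$false_allele_rate > 0) {
    flip_to_ref <- rbinom(n, ad_alt, config$false_allele_rate)
    flip_to_alt <- rbinom(n, ad_ref, config$false_allele_rate)
    ad_alt <- ad_alt - flip_to_ref + flip_to_alt
    ad_ref <- dp - ad_alt
  }
  dosage |>
    mutate(ad_ref = ad_ref, ad_alt = ad_alt, dp = ad_ref + ad_alt,
           af = ifelse(.data$dp > 0, ad_alt / .data$dp, NA_real_))
}

#' Simulate a whole family's SNP observations
#'
#' Draws a pedigree, the affected proband (forced paternal
#' haplotype 1), and `n_embryos` embryos, then simulates allele-depth
#' observations for every individual.  Sample names follow the
#' pedigree-table convention: `Male`, `Female`, `Proband`, `E1`..`En`.
#'
#' @param config A [sim_config()]; set `config$seed` for a
#'   deterministic family.
#' @param n_embryos Number of embryos (default 5).
#' @param embryo_aneuploidies Optional named list
#'   (`E1` = tibble(chrom, type), ...) of whole-chromosome
#'   aberrations.
#' @return List with `$pedigree`, `$proband`, `$embryos` (named list
#'   of `pgt_embryo`), and `$observations` (long tibble over all
#'   samples).
#' @export
simulate_family <- function(config = sim_config(), n_embryos = 5,
                            embryo_aneuploidies = NULL) {
  pedigree <- simulate_pedigree(config)
  proband <- simulate_embryo(pedigree, config, paternal_hap = 1)
  embryo_names <- if (n_embryos > 0) paste0("E", seq_len(n_embryos))
    else character()
  embryos <- setNames(map(embryo_names, function(e) {
    simulate_embryo(pedigree, config,
                    aneuploidies = embryo_aneuploidies[[e]])
  }), embryo_names)
  obs_one <- function(who, name) {
    simulate_allele_depths(allele_dosage(pedigree, who), config) |>
      mutate(sample = name, .after = "alt")
  }
  observations <- bind_rows(
    obs_one("father", "Male"),
    obs_one("mother", "Female"),
    obs_one(proband, "Proband"),
    imap(embryos, obs_one) |> list_rbind()
  )
  list(pedigree = pedigree, proband = proband, embryos = embryos,
       observations = observations)
}

#' Simulate binned read counts from a copy-number profile
#'
#' Bins are laid on a grid anchored at coordinate 0 in multiples of
#' `bin_size` (1-based bounds; the final partial bin of a chromosome is
#' kept with its expectation scaled by covered length).  Each bin's
#' count is Poisson with mean
#' `reads_per_bin * (covered / bin_size) * (cn / 2)`, where `cn` is the
#' profile copy number averaged over the bin by overlap length, so the
#' expected genome-wide total equals `reads_total` scaled by the
#' covered genome when the profile is diploid.
#'
#' @param cn_profile Tibble `chrom`, `start`, `end`, `cn` partitioning
#'   each simulated chromosome (see [cn_profile_parent()],
#'   [simulate_embryo()]).
#' @param config A [sim_config()].
#' @param bin_size Bin width in bp (default `config$bin_size_bp`).
#' @param reads_per_bin Baseline mean count per full diploid bin
#'   (default derived from `config$reads_total` over the covered
#'   genome).
#' @param chroms Chromosomes to bin (default: those in the profile).
#' @return Tibble `chrom`, `start`, `end`, `count` with attributes
#'   `bin_size` and `reads_per_bin`.
#' @export
simulate_bin_counts <- function(cn_profile, config = sim_config(),
                                bin_size = NULL, reads_per_bin = NULL,
                                chroms = NULL) {
  bin_size <- bin_size %||% config$bin_size_bp
  stopifnot(bin_size > 0)
  chroms <- chroms %||% unique(cn_profile$chrom)
  sizes <- hg19_autosomes()
  lens <- setNames(sizes$length, sizes$chrom)
  chrom_len <- map_dbl(chroms, function(ch) {
    if (ch %in% names(lens)) lens[[ch]]
    else max(cn_profile$end[cn_profile$chrom == ch])
  })
  reads_per_bin <- reads_per_bin %||% config$reads_per_bin %||%
    (config$reads_total * bin_size / sum(chrom_len))
  bins <- map2(chroms, chrom_len, function(ch, len) {
    n_bins <- ceiling(len / bin_size)
    start <- (seq_len(n_bins) - 1) * bin_size + 1
    end <- pmin(seq_len(n_bins) * bin_size, len)
    tibble(chrom = ch, start = start, end = end)
  }) |> list_rbind()
  # overlap-weighted mean copy number per bin
  cn_num <- numeric(nrow(bins))
  covered <- numeric(nrow(bins))
  for (k in seq_len(nrow(cn_profile))) {
    r <- cn_profile[k, ]
    hit <- bins$chrom == r$chrom & bins$start <= r$end & bins$end >= r$start
    if (!any(hit)) next
    ov <- pmin(bins$end[hit], r$end) - pmax(bins$start[hit], r$start) + 1
    cn_num[hit] <- cn_num[hit] + ov * r$cn
    covered[hit] <- covered[hit] + ov
  }
  if (any(covered == 0)) {
    # bins outside the profile (profile must partition each chromosome)
    abort("cn_profile does not cover all bins of the requested chromosomes")
  }
  expected <- reads_per_bin * (covered / bin_size) * (cn_num / covered) / 2
  bins$count <- rpois(nrow(bins), expected)
  attr(bins, "bin_size") <- bin_size
  attr(bins, "reads_per_bin") <- reads_per_bin
  bins
}
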