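#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata/`; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
pgt_example <- function(file = "table1_informative_snps.tsv") {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pgtdup")))
  }
  path <- system.file("extdata", file, package = "pgtdup")
  if (!nzchar(path)) abort(paste0("no packaged example file '", file, "'"))
  path
}

table1_samples <- c("Male", "Female", "Proband", paste0("E", 1:5))

split_gt <- function(gt) {
  gt <- as.character(gt)
  no_call <- is.na(gt) | gt %in% c("./", "./.", ".", "")
  parts <- str_split(ifelse(no_call, "NA/NA", gt), "/", simplify = TRUE)
  a1 <- ifelse(no_call, NA_character_, parts[, 1])
  a2 <- ifelse(no_call, NA_character_, parts[, 2])
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  tibble(a1 = lo, a2 = hi)
}

#' Read a pedigree + embryo genotype table
#'
#' Reads the published-table layout: one row per SNP with columns
#' `RSID`, `POS` and one genotype column per individual (`Male`,
#' `Female`, `Proband`, `E1`..`E5`), genotypes written `"C/G"` and
#' no-calls `"./"`.  Genotypes are unordered allele pairs: `"C/G"` and
#' `"G/C"` are the same call and are stored with alleles sorted.
#'
#' The packaged fixture ([pgt_example()]) transcribes the published
#' table for the 1q21.1q21.2 duplication family: 22 SNPs typed in 8
#' individuals, with two no-calls (both in embryo E2).  Two marker ids
#' that carry a stray thousands separator in the typeset table are
#' normalized to plain rsids (`rs117176741`, `rs17581597`).
#'
#' @param path TSV file path.
#' @param chrom Chromosome to record for every site (the table itself
#'   prints positions only); default `"chr1"`.
#' @return A long tibble with one row per individual per site:
#'   `rsid`, `chrom`, `pos`, `sample`, `a1`, `a2` (`NA` alleles for a
#'   no-call).
#' @export
read_table1_tsv <- function(path, chrom = "chr1") {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("RSID", "POS", table1_samples)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("genotype table is missing column(s) ",
                 paste(missing, collapse = ", "),
                 "; expected header: ", paste(required, collapse = ", ")))
  }
  if (nrow(tab) == 0) abort("genotype table has a header but no rows")
  tab |>
    mutate(pos = as.numeric(str_remove_all(.data$POS, ","))) |>
    select(rsid = "RSID", "pos", all_of(table1_samples)) |>
    pivot_longer(all_of(table1_samples), names_to = "sample",
                 values_to = "gt") |>
    mutate(chrom = chrom, split_gt(.data$gt), .keep = "unused") |>
    select("rsid", "chrom", "pos", "sample", "a1", "a2") |>
    arrange(.data$pos, match(.data$sample, table1_samples))
}

#' Read genotypes from a VCF file
#'
#' Expects VCF 4.2 with a per-sample `GT` field and, when present, `AD`
#' (allele depths) and `DP`.  Only biallelic SNV records are supported;
#' multiallelic records raise an error (split them upstream, e.g. with
#' `bcftools norm -m-`).  Missing genotypes (`./.`) become no-calls.
#' Contig names are passed through unmodified.
#'
#' @param path VCF file path (plain text or gzip).
#' @return A long tibble with columns `rsid`, `chrom`, `pos`, `ref`,
#'   `alt`, `sample`, `a1`, `a2`, `ad_ref`, `ad_alt`, `dp`, `af`.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) abort("VCF contains no variant records")
  fmt <- v@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, logical(1)))) {
    abort("VCF FORMAT lacks the GT field on some records")
  }
  alt <- v@fix[, "ALT"]
  if (any(str_detect(alt, ","))) {
    abort("multiallelic VCF records are not supported; split them first")
  }
  fix <- tibble(
    rsid = ifelse(is.na(v@fix[, "ID"]) | v@fix[, "ID"] == ".",
                  paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"]),
                  v@fix[, "ID"]),
    chrom = v@fix[, "CHROM"],
    pos = as.numeric(v@fix[, "POS"]),
    ref = v@fix[, "REF"], alt = alt
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  has_ad <- all(vapply(strsplit(fmt, ":"), function(f) "AD" %in% f, logical(1)))
  ad <- if (has_ad) vcfR::extract.gt(v, element = "AD") else NULL
  samples <- colnames(gt)
  out <- map(samples, function(s) {
    g <- gsub("|", "/", unname(gt[, s]), fixed = TRUE)
    no_call <- is.na(g) | g %in% c("./.", ".")
    idx <- str_split(ifelse(no_call, "./.", g), "/", simplify = TRUE)
    allele_of <- function(i) ifelse(i == "0", fix$ref,
                                    ifelse(i == "1", fix$alt, NA_character_))
    a1 <- ifelse(no_call, NA_character_, allele_of(idx[, 1]))
    a2 <- ifelse(no_call, NA_character_, allele_of(idx[, 2]))
    lo <- pmin(a1, a2)
    hi <- pmax(a1, a2)
    res <- fix |> mutate(sample = s, a1 = lo, a2 = hi)
    if (!is.null(ad)) {
      av <- unname(ad[, s])
      dd <- str_split(ifelse(is.na(av), "NA,NA", av), ",",
                      simplify = TRUE)
      res$ad_ref <- suppressWarnings(as.numeric(dd[, 1]))
      res$ad_alt <- suppressWarnings(as.numeric(dd[, 2]))
      res$dp <- res$ad_ref + res$ad_alt
      res$af <- ifelse(res$dp > 0, res$ad_alt / res$dp, NA_real_)
    }
    res
  })
  list_rbind(out)
}

#' Write genotype observations as VCF 4.2
#'
#' Writes one biallelic record per site with `GT:AD:DP` per sample, the
#' inverse of [read_genotypes_vcf()].  Sites where a sample has no call
#' are written `./.`.
#'
#' @param geno Long tibble with `rsid`, `chrom`, `pos`, `ref`, `alt`,
#'   `sample`, `a1`, `a2` and optionally `ad_ref`, `ad_alt`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(all(c("rsid", "chrom", "pos", "ref", "alt", "sample",
                  "a1", "a2") %in% names(geno)))
  has_ad <- all(c("ad_ref", "ad_alt") %in% names(geno))
  idx_of <- function(a, ref, alt) ifelse(is.na(a), ".",
                                         ifelse(a == ref, "0", "1"))
  geno <- geno |>
    mutate(
      gt = paste0(idx_of(.data$a1, .data$ref, .data$alt), "/",
                  idx_of(.data$a2, .data$ref, .data$alt)),
      field = if (has_ad) {
        paste0(.data$gt, ":", .data$ad_ref, ",", .data$ad_alt, ":",
               .data$ad_ref + .data$ad_alt)
      } else .data$gt
    )
  wide <- geno |>
    select("rsid", "chrom", "pos", "ref", "alt", "sample", "field") |>
    pivot_wider(names_from = "sample", values_from = "field")
  samples <- setdiff(names(wide), c("rsid", "chrom", "pos", "ref", "alt"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pgtdup",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_ad) '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    if (has_ad) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fmt <- if (has_ad) "GT:AD:DP" else "GT"
  body <- apply(wide, 1, function(r) {
    paste(c(r[["chrom"]],
            format(as.numeric(r[["pos"]]), scientific = FALSE, trim = TRUE),
            r[["rsid"]], r[["ref"]], r[["alt"]], ".", "PASS", ".", fmt,
            unlist(r[samples])), collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write per-bin read counts
#'
#' Plain TSV with columns `chrom`, `start`, `end`, `count`
#' (1-based inclusive bin bounds on a grid anchored at coordinate 0).
#'
#' @param path TSV path.
#' @return A tibble of bins.
#' @export
read_bin_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "d", end = "d", count = "d"), progress = FALSE)
}

#' @param bins Bin tibble with `chrom`, `start`, `end`, `count`.
#' @rdname read_bin_counts
#' @export
write_bin_counts <- function(bins, path) {
  readr::write_tsv(bins[, c("chrom", "start", "end", "count")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write segments as a seg-style TSV
#'
#' Columns `sample`, `chrom`, `start`, `end`, `n_bins`,
#' `mean_log2ratio`, `cn`, `call`.  An empty segment table writes a
#' header-only file; [read_segments()] parses the same layout back.
#'
#' @param segments Segment tibble (see [segment_bins()]); must carry
#'   `chrom`, `start`, `end`, `n_bins`, `mean_ratio`.
#' @param path Output path.
#' @param sample Sample name recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, sample = "sample") {
  out <- tibble(
    sample = rep(sample, nrow(segments)),
    chrom = segments$chrom,
    start = segments$start, end = segments$end,
    n_bins = segments$n_bins,
    mean_log2ratio = log2(pmax(segments$mean_ratio, 2^-10)),
    cn = round(2 * segments$mean_ratio, 3),
    call = if ("call" %in% names(segments)) segments$call else
      ifelse(2 * segments$mean_ratio >= 2.5, "gain",
             ifelse(2 * segments$mean_ratio <= 1.5, "loss", "neutral"))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = "c", chrom = "c", start = "d", end = "d", n_bins = "d",
    mean_log2ratio = "d", cn = "d", call = "c"), progress = FALSE)
}

#' Write a per-embryo report TSV
#'
#' @param report Report tibble from [combine_reports()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
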