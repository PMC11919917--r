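dup_region <- function() parse_region("chr1:146305863-147992406")

table1_geno <- function() read_table1_tsv(pgt_example())

# raw fixture table, used as the independent source of the printed
# distance and phased-haplotype columns
table1_raw <- function() {
  readr::read_tsv(pgt_example(), col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

# tiny long genotype tibble from a compact spec:
# list(rsid = c(pos, Male, Female, Proband, ...))
make_geno <- function(sites, chrom = "chr1") {
  rows <- lapply(names(sites), function(rs) {
    v <- sites[[rs]]
    samples <- names(v)[-1]
    gt <- unlist(v[-1])
    alleles <- strsplit(ifelse(gt == "./", "NA/NA", gt), "/")
    tibble::tibble(
      rsid = rs, chrom = chrom, pos = as.numeric(v[[1]]), sample = samples,
      a1 = vapply(alleles, function(a) sort(a)[1], ""),
      a2 = vapply(alleles, function(a) sort(a)[2], "")
    ) |>
      dplyr::mutate(a1 = ifelse(a1 == "NA", NA_character_, a1),
                    a2 = ifelse(a2 == "NA", NA_character_, a2))
  })
  dplyr::bind_rows(rows)
}

# flat diploid profile over one synthetic chromosome
flat_profile <- function(chrom = "chr1", len = 249250621, cn = 2) {
  tibble::tibble(chrom = chrom, start = 1, end = len, cn = cn)
}
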