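#' Genomic regions
#'
#' A `pgt_region` is a 1-based, fully closed chromosome interval, the
#' convention used by VCF and by clinical CNV coordinates.  The
#' duplication studied throughout the package documentation,
#' `chr1:146305863-147992406` (GRCh37), has length
#' `end - start + 1 = 1,686,544` bp, i.e. about 1.69 Mb.
#'
#' @param text A region string `"<chrom>:<start>-<end>"`.  Thousands
#'   separators (commas) inside the coordinates are tolerated.
#' @return A `pgt_region` object (list with `chrom`, `start`, `end`).
#' @examples
#' r <- parse_region("chr1:146305863-147992406")
#' region_length(r) / 1e6
#' @export
parse_region <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  m <- str_match(str_remove_all(text, ","),
                 "^([A-Za-z0-9_.]+):([0-9]+)-([0-9]+)$")
  if (is.na(m[1, 1])) {
    abort(paste0("malformed region string: '", text,
                 "' (expected '<chrom>:<start>-<end>')"))
  }
  start <- as.numeric(m[1, 3])
  end <- as.numeric(m[1, 4])
  if (start > end) {
    abort(paste0("region start exceeds end in '", text, "': start ",
                 format(start, scientific = FALSE), " > end ",
                 format(end, scientific = FALSE)))
  }
  if (start < 1) abort(paste0("region start must be >= 1 in '", text, "'"))
  region(m[1, 2], start, end)
}

#' @param chrom Chromosome name (kept verbatim, e.g. `"chr1"`).
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @rdname parse_region
#' @export
region <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L,
            start >= 1, start <= end)
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end)),
            class = "pgt_region")
}

#' @param region A `pgt_region`.
#' @rdname parse_region
#' @export
format_region <- function(region) {
  stopifnot(inherits(region, "pgt_region"))
  sprintf("%s:%s-%s", region$chrom,
          format(region$start, scientific = FALSE, trim = TRUE),
          format(region$end, scientific = FALSE, trim = TRUE))
}

#' @rdname parse_region
#' @export
region_length <- function(region) {
  stopifnot(inherits(region, "pgt_region"))
  region$end - region$start + 1
}

#' @export
print.pgt_region <- function(x, ...) {
  cat("<pgt_region> ", format_region(x), "  (",
      format(region_length(x), big.mark = ","), " bp)\n", sep = "")
  invisible(x)
}

#' Export a region as a BED interval
#'
#' BED is 0-based half-open; the closed 1-based region is converted at
#' this boundary (start - 1, end unchanged).
#'
#' @param region A `pgt_region`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(region, path) {
  stopifnot(inherits(region, "pgt_region"))
  writeLines(sprintf("%s\t%s\t%s", region$chrom,
                     format(region$start - 1, scientific = FALSE, trim = TRUE),
                     format(region$end, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}
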