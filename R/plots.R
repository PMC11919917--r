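#' Plot a segmented copy-number profile
#'
#' Per-bin copy-number estimates along a genomic index with segment
#' means overlaid, the standard karyogram-style CNV sketch.
#'
#' @param object A `pgt_segments` object from [segment_bins()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pgt_segments
#' @export
autoplot.pgt_segments <- function(object, ...) {
  bins <- attr(object, "bins")
  chrom_order <- unique(bins$chrom)
  bins <- bins |>
    mutate(chrom = factor(.data$chrom, levels = chrom_order)) |>
    arrange(.data$chrom, .data$start) |>
    mutate(idx = row_number())
  offsets <- bins |>
    group_by(.data$chrom) |>
    summarise(offset = min(.data$idx) - 1, .groups = "drop")
  segs <- as_tibble(object) |>
    left_join(offsets, by = "chrom") |>
    mutate(x0 = .data$offset + .data$first_bin - 0.5,
           x1 = .data$offset + .data$last_bin + 0.5)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$idx,
                                     y = 2 * .data$ratio)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chrom), size = 0.5,
                        show.legend = FALSE) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x0, xend = .data$x1,
                   y = 2 * .data$mean_ratio, yend = 2 * .data$mean_ratio),
      colour = "red", linewidth = 0.9, inherit.aes = FALSE) +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(0, 4)) +
    ggplot2::labs(x = "bin index", y = "copy number estimate") +
    ggplot2::theme_minimal()
}

#' Plot per-SNP haplotype votes for a set of embryos
#'
#' Tile map of hap-1 / hap-2 / no-call votes across the informative
#' SNP panel, ordered by position, one row per embryo — the
#' at-a-glance linkage picture used to read off transmitted
#' haplotypes and spot flank discordance.
#'
#' @param object A `pgt_verdicts` object from [classify_embryos()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pgt_verdicts
#' @export
autoplot.pgt_verdicts <- function(object, ...) {
  votes <- tidy(object) |>
    mutate(rsid = factor(.data$rsid, levels = unique(.data$rsid[
      order(.data$pos)])))
  ggplot2::ggplot(votes, ggplot2::aes(x = .data$rsid, y = .data$embryo,
                                      fill = .data$vote)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(hap1 = "#c0392b",
                                          hap2 = "#2980b9",
                                          no_call = "grey80")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "vote") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
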