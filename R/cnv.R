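#' Normalize binned read counts to copy ratios
#'
#' The baseline is the genome-wide median raw count over autosomal
#' bins (self-normalization; no reference cohort is assumed).  Each
#' bin's `ratio` is `count / baseline` and its copy-number estimate
#' `2 * ratio`.
#'
#' @param bins Tibble with `chrom`, `start`, `end`, `count`.
#' @param baseline Optional externally supplied baseline count.
#' @return The bins with `ratio` and `cn_estimate` added; the baseline
#'   is stored in the `"baseline"` attribute.
#' @export
normalize_bins <- function(bins, baseline = NULL) {
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(bins)),
            all(bins$count >= 0))
  autosomal <- bins$chrom %in% paste0("chr", 1:22) |
    bins$chrom %in% as.character(1:22)
  if (!any(autosomal)) abort("no autosomal bins to take a baseline from")
  baseline <- baseline %||% median(bins$count[autosomal])
  if (baseline <= 0) abort("baseline median bin count is zero")
  out <- bins |>
    mutate(ratio = .data$count / baseline,
           cn_estimate = 2 * .data$ratio)
  attr(out, "baseline") <- baseline
  attr(out, "bin_size") <- attr(bins, "bin_size") %||%
    max(bins$end - bins$start + 1)
  out
}

#' Circular binary segmentation of one chromosome's ratios
#'
#' Recursively searches the circular arc `(i, j]` maximizing a
#' two-sample t-like statistic between the arc and its complement
#' (computed on untransformed ratios, common-variance form).  A split
#' is accepted when its permutation p-value is below `alpha`
#' (`n_perm` shuffles of the current segment, early-stopped once
#' significance is unreachable) and recursion continues on the
#' resulting pieces.  Adjacent segments whose means differ by less
#' than `merge_eps` are merged afterwards.  Results are deterministic
#' for a fixed R random seed (`set.seed()` before calling).
#'
#' @param x Numeric vector of per-bin ratios for one chromosome.
#' @param alpha Significance level for a split (default 0.01).
#' @param n_perm Permutations per tested split (default 1000, minimum
#'   100).
#' @param min_bins Minimum bins in the tested arc and its complement
#'   (default 2).
#' @param merge_eps Post-hoc mean-merge tolerance on the ratio scale
#'   (default 0.05).
#' @return Tibble with `first_bin`, `last_bin` (1-based inclusive
#'   indices), `n_bins`, `mean_ratio`; segments partition `seq_along(x)`.
#' @export
cbs_segment <- function(x, alpha = 0.01, n_perm = 1000, min_bins = 2,
                        merge_eps = 0.05) {
  stopifnot(is.numeric(x), length(x) >= 1, n_perm >= 100,
            alpha > 0, alpha < 1, min_bins >= 1)
  max_exceed <- max(1L, as.integer(ceiling(alpha * n_perm)))
  ends <- cbs_recurse(x, 1L, length(x), alpha, n_perm, min_bins, max_exceed)
  first <- c(1L, head(ends, -1) + 1L)
  segs <- tibble(first_bin = first, last_bin = ends)
  segs$mean_ratio <- map2_dbl_(segs$first_bin, segs$last_bin,
                               function(a, b) mean(x[a:b]))
  # merge adjacent segments with nearly equal means
  repeat {
    if (nrow(segs) < 2) break
    gaps <- abs(diff(segs$mean_ratio))
    if (all(gaps >= merge_eps)) break
    k <- which.min(gaps)
    merged <- tibble(first_bin = segs$first_bin[k],
                     last_bin = segs$last_bin[k + 1])
    merged$mean_ratio <- mean(x[merged$first_bin:merged$last_bin])
    segs <- bind_rows(if (k > 1) segs[seq_len(k - 1), ],
                      merged,
                      if (k + 1 < nrow(segs)) segs[seq(k + 2, nrow(segs)), ])
  }
  segs |>
    mutate(n_bins = .data$last_bin - .data$first_bin + 1L,
           .after = "last_bin")
}

map2_dbl_ <- function(a, b, f) vapply(seq_along(a),
                                      function(k) f(a[k], b[k]), numeric(1))

cbs_recurse <- function(x, lo, hi, alpha, n_perm, min_bins, max_exceed) {
  n <- hi - lo + 1L
  if (n < 2L * min_bins) return(hi)
  seg <- x[lo:hi]
  scan <- cbs_max_arc(seg, min_bins)
  if (scan$stat <= 0) return(hi)
  pt <- cbs_perm_test(seg, scan$stat, n_perm, max_exceed, min_bins)
  significant <- pt$exceed < max_exceed &&
    pt$exceed / n_perm < alpha
  if (!significant) return(hi)
  i <- scan$i; j <- scan$j  # 0-based boundaries of arc (i, j] within seg
  bounds <- integer()
  if (i > 0) bounds <- c(bounds, cbs_recurse(x, lo, lo + i - 1L, alpha,
                                             n_perm, min_bins, max_exceed))
  bounds <- c(bounds, cbs_recurse(x, lo + i, lo + j - 1L, alpha, n_perm,
                                  min_bins, max_exceed))
  if (j < n) bounds <- c(bounds, cbs_recurse(x, lo + j, hi, alpha, n_perm,
                                             min_bins, max_exceed))
  bounds
}

#' Segment normalized bins genome-wide
#'
#' Runs [cbs_segment()] independently on each chromosome's ratio track
#' and maps segment indices back to genomic coordinates.
#'
#' @param bins Normalized bins from [normalize_bins()] (must carry
#'   `ratio`).
#' @param ... Passed to [cbs_segment()] (`alpha`, `n_perm`,
#'   `min_bins`, `merge_eps`).
#' @param seed Optional seed set (locally) before segmentation so a
#'   run is reproducible in isolation.
#' @return A `pgt_segments` tibble: `chrom`, `first_bin`, `last_bin`,
#'   `start`, `end`, `n_bins`, `mean_ratio`, with the input bins kept
#'   in the `"bins"` attribute for plotting.
#' @export
segment_bins <- function(bins, ..., seed = NULL) {
  stopifnot("ratio" %in% names(bins))
  if (!is.null(seed)) set.seed(seed)
  segs <- bins |>
    group_by(.data$chrom) |>
    group_modify(function(d, key) {
      s <- cbs_segment(d$ratio, ...)
      s$start <- d$start[s$first_bin]
      s$end <- d$end[s$last_bin]
      s
    }) |>
    ungroup() |>
    select("chrom", "first_bin", "last_bin", "start", "end", "n_bins",
           "mean_ratio")
  structure(segs, class = c("pgt_segments", class(segs)),
            bins = bins,
            bin_size = attr(bins, "bin_size"),
            baseline = attr(bins, "baseline"))
}

#' @rdname segment_bins
#' @param x A `pgt_segments` object.
#' @param ... Unused.
#' @method tidy pgt_segments
#' @export
tidy.pgt_segments <- function(x, ...) as_tibble(x)

#' @rdname segment_bins
#' @method glance pgt_segments
#' @export
glance.pgt_segments <- function(x, ...) {
  tibble(n_segments = nrow(x), n_chromosomes = n_distinct(x$chrom),
         baseline = attr(x, "baseline") %||% NA_real_,
         bin_size = attr(x, "bin_size") %||% NA_real_)
}

round_cn <- function(r) {
  # nearest integer, ties rounding half away from the diploid state
  ifelse(r >= 2, floor(r + 0.5), ceiling(r - 0.5))
}

#' Call copy-number gains and losses from segments
#'
#' A segment is a gain when its mean copy-number estimate
#' (`2 * mean_ratio`) is at least `gain_cn` and a loss when at most
#' `loss_cn`.  Two reporting modes mirror dual-resolution PGT-A
#' practice:
#'
#' * `"genome"` — whole-genome screening at coarse bins; only events
#'   larger than `min_size_genome` (default 4 Mb) are reported, and a
#'   call spanning a whole chromosome is reported as an aneuploidy
#'   (`"+21"`, `"-20"`).
#' * `"target"` — high-resolution interrogation of a known `region`;
#'   events larger than `min_size_target` (default 1 Mb) on the
#'   region's chromosome are reported.  For a segment overlapping the
#'   region, the reported event is the span of grid bins fully
#'   contained in the region (the inner-bin convention): a bin
#'   partially straddling a duplication boundary carries an
#'   intermediate dose and does not attest the full event, so the
#'   reported size is conservative — a 1.69 Mb duplication on a
#'   0-anchored 400-kb grid reports 3 bins, about 1.20 Mb.
#'
#' @param segments A [segment_bins()] result.
#' @param mode `"genome"` or `"target"`.
#' @param region Required in target mode: the interrogated
#'   `pgt_region`.
#' @param gain_cn,loss_cn Copy-number thresholds (defaults 2.5 / 1.5,
#'   the midpoints between integer states of a non-mosaic diploid).
#' @param min_size_genome,min_size_target Minimum reported event sizes
#'   (bp).
#' @return Tibble of calls: `chrom`, `start`, `end`, `n_bins`,
#'   `type` (`gain`/`loss`), `cn`, `mean_ratio`, `size_bp`,
#'   `whole_chromosome`, `label`.
#' @export
call_cnvs <- function(segments, mode = c("genome", "target"), region = NULL,
                      gain_cn = 2.5, loss_cn = 1.5,
                      min_size_genome = 4e6, min_size_target = 1e6) {
  mode <- match.arg(mode)
  if (mode == "target" && !inherits(region, "pgt_region")) {
    abort("target mode requires a `region` (pgt_region)")
  }
  bins <- attr(segments, "bins")
  segs <- as_tibble(segments) |>
    mutate(cn_mean = 2 * .data$mean_ratio,
           type = case_when(.data$cn_mean >= gain_cn ~ "gain",
                            .data$cn_mean <= loss_cn ~ "loss",
                            .default = NA_character_)) |>
    filter(!is.na(.data$type))
  if (mode == "target") segs <- filter(segs, .data$chrom == region$chrom)
  if (nrow(segs) == 0) return(empty_cnv_calls())
  n_bins_chrom <- bins |> count(.data$chrom, name = "chrom_bins")
  segs <- segs |> left_join(n_bins_chrom, by = "chrom")
  calls <- pmap(segs, function(chrom, first_bin, last_bin, start, end,
                               n_bins, mean_ratio, cn_mean, type,
                               chrom_bins, ...) {
    rep_start <- start; rep_end <- end; rep_bins <- n_bins
    if (mode == "target" && start <= region$end && end >= region$start) {
      lo <- max(start, region$start)
      hi <- min(end, region$end)
      b <- bins |>
        filter(.data$chrom == region$chrom,
               .data$start >= lo, .data$end <= hi)
      rep_bins <- nrow(b)
      if (rep_bins == 0) return(NULL)
      rep_start <- min(b$start); rep_end <- max(b$end)
    }
    whole <- n_bins == chrom_bins
    size <- rep_end - rep_start + 1
    cn <- round_cn(cn_mean)
    label <- if (whole) {
      paste0(if (type == "gain") "+" else "-", sub("^chr", "", chrom))
    } else {
      sprintf("%s(%s:%.2f-%.2fMb)(~%.2f Mb)",
              if (type == "gain") "dup" else "del", chrom,
              rep_start / 1e6, rep_end / 1e6, size / 1e6)
    }
    tibble(chrom = chrom, start = rep_start, end = rep_end,
           n_bins = rep_bins, type = type, cn = cn,
           mean_ratio = mean_ratio, size_bp = size,
           whole_chromosome = whole, label = label)
  })
  calls <- list_rbind(purrr::compact(calls))
  if (nrow(calls) == 0) return(empty_cnv_calls())
  min_size <- if (mode == "genome") min_size_genome else min_size_target
  calls |> filter(.data$whole_chromosome | .data$size_bp > min_size)
}

empty_cnv_calls <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric(),
         n_bins = integer(), type = character(), cn = numeric(),
         mean_ratio = numeric(), size_bp = numeric(),
         whole_chromosome = logical(), label = character())
}

#' Estimate the copy number of a target region
#'
#' Averages the normalized copy ratio over the grid bins fully
#' contained in the region and rounds `2 * mean_ratio` to the nearest
#' integer (ties round away from the diploid state, so 2.5 becomes 3
#' and 1.5 becomes 1).
#'
#' @param bins Normalized bins from [normalize_bins()].
#' @param region The interrogated `pgt_region`.
#' @return One-row tibble: `cn`, `mean_ratio`, `n_bins`.
#' @export
estimate_target_cn <- function(bins, region) {
  stopifnot("ratio" %in% names(bins), inherits(region, "pgt_region"))
  inside <- bins |>
    filter(.data$chrom == region$chrom, .data$start >= region$start,
           .data$end <= region$end)
  if (nrow(inside) == 0) {
    abort(paste("no bin lies fully inside the target region;",
                "use a smaller bin size"))
  }
  mr <- mean(inside$ratio)
  tibble(cn = round_cn(2 * mr), mean_ratio = mr, n_bins = nrow(inside))
}
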