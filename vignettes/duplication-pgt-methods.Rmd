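---
title: "Methods: SNP-linkage PGT and binned copy-number analysis for a tandem microduplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-linkage PGT and binned copy-number analysis for a tandem microduplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgtdup)
library(dplyr)
```

## The problem

A couple in which one partner carries a pathogenic tandem
microduplication — here a ~1.69 Mb event at 1q21.1q21.2,
`chr1:146305863-147992406` (GRCh37) — can use preimplantation genetic
testing to select embryos that did not inherit the duplicated
haplotype.  Two complementary analyses run on the same shallow
sequencing data from each trophectoderm biopsy:

* **PGT-M by SNP linkage.** The duplication itself is too small for
  reliable direct detection at whole-genome screening resolution, but
  the carrier parent's two haplotypes can be distinguished by
  informative SNPs around (and inside) the duplication.  An affected
  child (the proband) anchors the phase: whichever paternal allele
  series the proband inherited is, by definition, the high-risk
  haplotype (hap 1); the other is low-risk (hap 2).  Each embryo is
  then classified by per-SNP votes.
* **PGT-A by binned copy number.** Reads are counted in fixed genomic
  bins, normalized to the genome-wide median, segmented with circular
  binary segmentation (CBS), and thresholded into gains and losses at
  two resolutions: a 1 Mb-bin genome screen for aneuploidy and large
  CNVs (reported above 4 Mb), and a 400 kb-bin targeted pass over the
  duplication (reported above 1 Mb).

An embryo is transfer-eligible only when it is unaffected by linkage
*and* clean on the copy-number screen; the two target-region results
also cross-check one another.

## Informative SNPs and proband-anchored phasing

A site is informative when the carrier father is heterozygous and the
mother homozygous.  Within a ±2 Mb flank window of the duplication
(`flank_bp`, configurable), the embryo's paternal allele is the embryo
genotype minus one maternal allele, and maps directly to hap 1 or
hap 2.  Inside the duplication a second rule applies: at sites where
the proband is additionally homozygous for the mother's allele, an
affected offspring (who carries the duplicated paternal segment, hence
two copies of the shared allele plus the maternal one) types
homozygous like the proband, while an unaffected offspring types
heterozygous.  Phasing drops sites whose proband genotype is
Mendelian-impossible given the parents, and fails loudly if nothing
remains.

Genotypes are treated throughout as unordered allele pairs; phase is
inferred, never read from input order.

### Verdict thresholds

The published analysis reports per-embryo haplotype calls but no
explicit vote thresholds, so the classifier's defaults are this
package's own conservative choice: at least 3 informative votes, at
least 1 vote on *each* flank, and a majority consistency of at least
0.9.  Anything less is `inconclusive` — never a risk call.  A
disagreement between the upstream and downstream flank majorities
raises a recombination flag and likewise forces `inconclusive`,
because a crossover between a flank and the duplication breaks the
linkage the call rests on.  The consequence, visible in the
simulation tests, is that genotyping errors route to `inconclusive`
rather than to the wrong haplotype.

### Genotype QC

Observations are filtered before linkage: sites under 4× depth are
removed, and the two published allele-fraction filters are unified
into a single partition of the alt-fraction axis — homozygous at
`af ≤ 0.1` or `af ≥ 0.9`, heterozygous at `0.2 ≤ af ≤ 0.8`, and the
gaps `(0.1, 0.2)` and `(0.8, 0.9)` treated as low quality and
filtered.  This is the only reading under which both stated filters
are simultaneously operative, and it makes the decision rule total:
every fraction maps to exactly one outcome.  Boundary values are kept
(closed heterozygous band).  Variant-caller quality scores are out of
scope; "low quality" here means the fraction gaps only.

## Copy-number analysis

Bins lie on a grid anchored at coordinate 0 in multiples of the bin
size.  Counts are normalized by the autosomal median (self-median
rather than a reference cohort, which the source material does not
specify), giving `ratio = count / baseline` and `cn = 2 × ratio`.

CBS is implemented from its definition: the best circular arc `(i, j]`
maximizes a two-sample t-like statistic between arc and complement
(common-variance form, computed on untransformed ratios; the
exhaustive reference search in the test suite uses the same
definition), a split is accepted when its permutation p-value over
1000 within-segment shuffles falls below `alpha = 0.01`, recursion
continues on the pieces (minimum arc width 2 bins), and adjacent
segments with means closer than 0.05 are merged.  The permutation
loop stops early once significance is unreachable.  The scan and the
permutation kernel are compiled (Rcpp) and draw from R's RNG, so a
single `set.seed()` makes a whole run reproducible.

Gains require a segment mean CN of at least 2.5 and losses at most
1.5 — midpoints between integer states for a non-mosaic diploid
sample; both thresholds are arguments.

### The reported-size convention

The duplication spans 1.69 Mb but contains exactly three complete
400-kb grid bins (146,400,001–147,600,000).  The bin straddling the
region *end* overlaps it by 98%, so CBS almost always includes that
bin in the gain segment; a naive segment-span size would read
~1.6 Mb.  The package instead reports targeted events by the span of
grid bins **fully contained in the interrogated region** — the
inner-bin convention — which yields 1.20 Mb and matches the clinical
report this workflow reproduces.  This is why target mode requires
the region argument: the region defines which bins can attest the
event.  The convention is conservative (partially overlapping bins
carry an intermediate dose and never attest a full extra copy) and is
a documented reconstruction of the reported value, not a claim about
the original authors' code.  The target-region copy-number estimate
uses the same fully-contained bins: `round(2 × mean ratio)`, ties
rounding away from 2 so that an ambiguous 2.5 is flagged as a gain
rather than silently normal.

Whole-chromosome segments that pass a threshold are reported as
signed aneuploidies (`+21`, `-20`).  Event nomenclature uses
coordinate strings rather than cytobands (no offline cytoband table
is bundled); sizes and calls are unaffected.

## The synthetic generator

No sequencing data are distributed with this package; every analysis
stage is exercised against a generator that emulates the study
conditions:

* a carrier father (one extra copy of the region on haplotype 1), a
  non-carrier mother, an affected proband (forced paternal hap 1),
  and any number of embryos;
* SNP panels drawn in the duplication and its ±2 Mb flanks, with
  per-site minor-allele frequencies uniform on \[0.1, 0.5\] and a
  bounded-resampling guarantee of at least one informative site per
  flank;
* meiosis with a single-crossover model (`recomb_prob`, default 0.01
  per meiosis within the ~5.7 Mb window) rather than a genetic map —
  the window is short and the pipeline only needs flank discordance
  to be reachable;
* allele-depth observations with Poisson depth (negative-binomial
  overdispersion available via `depth_dispersion`), per-allele WGA
  dropout (`ado_rate`, default 0.05), dosage-proportional read draws
  (a CN-3 heterozygous site averages alt fractions 1/3 or 2/3), and a
  per-read allele-flip error (`false_allele_rate`, default 0.01);
* binned Poisson read counts with expectation
  `reads_per_bin × cn/2`, copy number averaged over each bin by
  overlap length, scaled so a diploid genome totals `reads_total`
  (default five million valid reads, the assay's scale; the phrase
  "about 5 Mb of valid reads" is ambiguous between megabases and
  millions of reads, so the generator parameterizes `reads_per_bin`
  directly and treats 5×10⁶ as an illustrative default).

`mean_site_depth` defaults to 30: genome-wide coverage in this assay
is 2–3×, but SNP typing rests on recovered depth at targeted sites;
the shallow regime is exercised explicitly in tests (mean 2.5, where
the 4× QC floor removes the Poisson-predicted ~76% of sites).  The
embryo-level dropout rate and depth distribution are not published
values; they are exposed defaults, chosen once as plausible for
MALBAC-amplified few-cell data.

What the generator does **not** model: GC and mappability bias,
MALBAC amplification waviness, mosaicism, read-level errors, or
sex-chromosome ploidy.  Passing tests therefore demonstrate the
correctness of the algorithms under the stated statistical model, not
robustness to every artefact of real WGA sequencing.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; BED export converts
  at the boundary.
* Multiallelic VCF records are rejected (the method is defined on
  biallelic SNPs); missing genotypes become no-calls, never errors.
* A zero-depth site is a no-call, not an error; an all-no-call embryo
  is `inconclusive`.
* The arc search breaks ties toward the shortest, leftmost arc, and
  the reference search in the tests mirrors that order.
* A constant segment (zero variance) is never split.
* `estimate_target_cn` errors, with advice to shrink the bin size,
  when no bin lies fully inside the region.

## Problem sizes in the test suite

The simulation-based checks use: 100 independent seeds for the
targeted 1.20 Mb gain recovery and for the copy-number estimates
(baseline 500 reads per 400-kb bin); one 22-autosome genome screen
for the triple-aneuploidy reproduction; 200 random instances (≤ 50
bins) for the exhaustive-search comparison; 200 null runs for type-I
control; and 500 simulated embryos for classification recovery in an
easy regime chosen inside the documented envelope (dropout 0.02,
mean depth 40, ~20 informative votes, no recombination).  At that
operating point the expected wrong-vote count per embryo is ~0.2, so
the 0.9-consistency gate yields well under 1% inconclusive calls and
a vanishing wrong-call probability — the analytical reason the
recovery criterion is attainable.

## Limitations

Maternal-carrier phasing, phasing without an affected proband
(grandparents, single sperm), mosaic copy numbers, breakpoint
refinement below bin resolution, and clinical decision support beyond
the eligibility boolean are all out of scope.  The concordance column
of a clinical report (orthogonal Sanger confirmation) is replaced by
an internal cross-check between the linkage verdict and target-region
CNV detection; discordance warns loudly instead of being silently
reported.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(sim_config(seed = 42), n_embryos = 3,
                    embryo_aneuploidies = list(
                      E2 = tibble(chrom = "chr21", type = "gain")))
res$report
autoplot(res$verdicts)
autoplot(res$segments$E1$target)
```
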