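---
title: "Copy-number profiling of plasma DNA from shallow WGS: models and design choices"
author: "plasmacnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number profiling of plasma DNA from shallow WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tumors shed DNA into the blood. In a plasma sample from a cancer
patient, a fraction λ of the cell-free DNA (cfDNA) is tumor-derived;
regions gained in the tumor genome are over-represented among plasma
fragments and lost regions are under-represented. Sequencing plasma DNA
at very shallow depth (~0.1x, a few million short single-end reads) and
counting reads in genomic windows therefore recovers the tumor's
copy-number landscape without a biopsy, provided the counting is
careful about mappability and GC bias, and provided the statistics
honestly account for how small the signal is at low tumor fractions.

`plasmacnv` implements that pipeline end to end: reference preparation,
window counting, normalization, segmentation, a battery of z-score
statistics, a detection-limit simulator, and a split-read module that
maps rearrangement junctions (such as the ~3 Mbp interstitial deletion
on chromosome 21 that fuses *TMPRSS2* to *ERG* in about half of
prostate cancers) at base-pair resolution in fragmented cfDNA.

## Reference windows

Read counts are only comparable between regions if every region offers
the same opportunity to receive reads. The package therefore:

1. masks the Y-chromosome pseudo-autosomal region with N
   (`mask_par()`), so PAR sequence exists once in the reference;
2. computes a mappability track (`mappability_track()`): position *p*
   is mappable iff the read-length-mer (default 150 bp) starting at *p*
   contains no N and occurs exactly once in the genome, counting both
   strands. Exact k-mer uniqueness stands in for aligner-based
   uniqueness; it is deterministic, self-contained, and agrees with a
   brute-force k-mer dictionary on every genome we test. A
   `both_strands = FALSE` switch ignores the reverse complement.
3. partitions the mappable positions, in genomic order, into windows of
   `floor(total/n)` or `floor(total/n) + 1` positions
   (`build_windows()`). Windows never cross chromosome boundaries.
   These two rules can conflict: a chromosome holding, say, 29,851
   mappable positions cannot be tiled by windows of 1,988 or 1,989. When
   the exact split is feasible the package produces it; otherwise it
   falls back to a minimal-deviation proportional apportionment and
   warns. Within a chromosome the larger windows always sit last.

Window GC content is the fraction (G+C)/(A+C+G+T) over the window span,
with all-N windows flagged missing.

## Counting and normalization

Alignments (SAM/BAM via Rsamtools) are filtered — unmapped, duplicate
and secondary records are dropped, with an optional mapping-quality
floor (default 0) — and each read increments the window containing its
leftmost aligned base. The per-window ratio is

    ratio_i = (count_i / mean(count)) / f(gc_i),

where `f` is a LOWESS fit of normalized count on GC fraction
(`stats::lowess`, span 0.3, one robustifying iteration; correction is by
division because sequencing GC bias acts multiplicatively on counts).
Ratios are rescaled to mean exactly 1. A control baseline
(`build_baseline()`) stores the per-window mean and SD of GC-corrected
ratios across a cohort of healthy controls of the same sex — X/Y
windows make mixed-sex baselines meaningless — and
`to_log2_ratio()` forms `log2(ratio_i / baseline_mean_i)`.

## Segmentation

Log2 ratio profiles are segmented by circular binary segmentation:
for each chromosome the arc `[i, j)` maximizing the two-sample t
statistic of arc versus complement is found (`circular_max_stat()`,
compiled O(n²) scan on prefix sums), its significance is assessed by
permutation (`permutation_p()`), and accepted splits recurse into the
three resulting pieces. Numerical choices:

* zero within-group variance (noiseless steps) is capped at a sentinel
  of 1e6 so permutation comparison stays finite;
* an arc and its complement have identical |t|; ties break to the
  smallest `i`, then smallest `j`, with a 1e-9 relative tolerance so
  floating-point noise cannot flip the choice;
* `alpha = 0.01`, 10,000 permutations and `min_width = 2` by default;
  the permutation stream is seeded per chromosome from the chromosome
  name, so results do not depend on chromosome iteration order;
* inside the recursion, permutation stops early once enough exceedances
  guarantee p ≥ alpha — the decision and the segmentation are
  unchanged, only the reported p for clearly non-significant splits is
  the running estimate. The exported `permutation_p()` never stops
  early and returns the exact `(1 + #exceed)/(n_perm + 1)`.
* missing windows are skipped in all statistics but stay inside the
  enclosing segment, so segments tile each chromosome; an optional
  `undo_sd` merge of near-equal neighbors is off by default.

## The z-score battery

For a window, segment or region statistic `x` with control mean `m` and
control SD `s`, the z-score is `(x − m)/s`:

* **window z** (`window_z()`): per 1-Mbp bin (equal-mappability windows
  aggregated by midpoint; `bin_ratios()`), against the control cohort.
  When the scored sample *is* a control, its own values are excluded
  (leave-one-out) — controls never serve as their own controls
  (`control_z_matrix()`).
* **segmental z** (`segmental_z()`): `x` is the sum of GC-corrected
  window ratios over a CBS segment; `m`, `s` are the mean and SD of the
  same sum across controls. A trisomy in a pregnancy sample is simply a
  whole-chromosome segment with elevated z.
* **region z** (`region_z()`): for a gene-sized region,
  `reads_expected = length_region / length_genome × reads_total`,
  `ratio = reads_region / reads_expected`, standardized against control
  ratios. `length_genome` is the span covered by the window grid.
* **genome-wide z**: the aneuploidy scalar. Per-bin z-scores are
  squared and summed, `S = Σ z_i²`, and S is standardized against the
  leave-one-out S-scores of the controls.

A windowed region is "normal" when |z| ≤ 3 (`significant_fraction()`).

### Deriving the genome-wide z from S

How the genome-wide z derives from S was an open design choice. Under a
null sample, a z computed against k reference controls is
`sqrt(1 + 1/k)` times a t variate with k − 1 degrees of freedom, so
`E[z²] = (1 + 1/k)(k − 1)/(k − 3)`. A held-out sample uses k = n
controls but a cross-validated control uses k = n − 1, so raw control
S-scores sit ~5% above raw sample S-scores at n = 10 — enough to bias
the genome-wide z of null samples by about −2.5 at 2,500 bins. The
package therefore divides each S by its theoretical null expectation
before standardization (`df_adjust = TRUE` in `aneuploidy_score()`),
putting both on a common scale. This inflation of cross-validated
control variance is a real property of the statistic, and makes ROC
estimates conservative.

One more consequence of small cohorts: conditional on one 10-control
cohort, the genome-wide z of null samples keeps a cohort-specific
offset with SD ≈ 0.33. Calibration statements are therefore averages
over cohort draws; `null_calibration()` scores its null samples in
batches against independently simulated cohorts.

Sample-to-sample structure is summarized by `cluster_samples()`:
Manhattan distance between z profiles (the distances of all windows
summed) under complete linkage (the default of the classic `hclust`
workflow; average/single are available), exported as Newick via ape.

## Simulation engine and study conditions

`simulate_control()` draws per-bin ratios from `Normal(mean, SD)`
truncated at 0; `simulate_case()` multiplies the mean by the diluted
copy-number ratio `1 − λ + λ·ratio` before drawing. The defaults that
define the simulated study are fixed once:

* a ~3,000-bin 1-Mbp grid over GRCh37-scale chromosome lengths
  (`genome_bins()`), matching the roughly 2,900 usable 1-Mbp windows of
  a male genome;
* per-bin noise `sqrt(n_bins / 3e6)` ≈ 0.032 (`depth_noise_sd()`): pure
  counting noise at 3 million mapped reads, the yield of roughly a
  quarter of a benchtop sequencing run;
* a reference cohort of 10 controls, the size of the male control
  cohort the assay was established on;
* prostate-like tumor profiles (`simulate_tumor_profiles()`): 8p loss
  (ratio 0.5, probability 0.4), 8q gain (1.5, 0.35), AR-region gain
  (2.0, 0.33), a TMPRSS2-ERG-like focal deletion (0.5, 0.5) and a few
  random arm-level events — frequencies in line with published
  metastatic prostate cancer series;
* `detection_limit()` scores cases and held-out controls identically
  against the same cohort and summarizes separation with the package's
  own ROC (`roc()`: trapezoid AUC = Mann-Whitney with half-credit for
  ties; operating point = Youden maximum, ties to higher specificity).

Under these conditions, 10% tumor fraction is detected with sensitivity
and specificity well above 0.8, reproducing the method's headline
claim, and 500 held-out null samples score near zero.

### What sampling noise cannot reproduce

The real assay flagged a 1% dilution of a massively aneuploid cell line
(genome-wide z 7.75 against a control maximum of 2.78). That result is
*not* reachable in a simulation whose only noise is iid counting noise:
the expected S elevation of a case is `(λ/σ)² Σ(r_i − 1)²`, about
50–60 at λ = 0.01 for even an extreme synthetic karyotype
(`aberrant_profile()`, ~half the genome altered including ratio-3
amplifications), while the spread of control S-scores is ~95. The
empirical 1% detection is driven by reproducible inter-sample structure
in real sequencing data (GC residuals, position effects) that shifts
every sample's S far more than binomial counting does — structure the
simulator deliberately does not model. The package reports the 1%
experiment honestly (mean case genome-wide z ≈ 0.5 above the null mean,
below the control maximum); at chromosome-level windows the same 1%
case is individually detectable (per-chromosome |z| > 3 for
whole-chromosome events), which is why clustering figures for dilution
series are computed on chromosomal z profiles. This is a stated
limitation, not a tunable.

The synthetic read generator (`generate_fixture()`) emulates: equal
windows with an injected smooth multiplicative GC bias, multinomial
read placement over mappable positions weighted by the diluted copy
ratio, fusion-spanning reads across a planted deletion junction, and a
truth file. It does not emulate fragment-size biology, PCR duplicates,
mapping errors or inter-sample correlated bias — so green end-to-end
tests demonstrate the pipeline's correctness on its own model, not
performance on real plasma.

## Split-read fusion mapping

Plasma DNA is too fragmented for insert-size (read-pair) methods, so
rearrangements are detected from single reads: the first and last
60 bp of each ≥120 bp read are aligned independently (for a 150 bp
read this leaves a 30 bp gap). The built-in aligner
(`align_fragments()`) is exact-seed (k = 20, seeds at offsets 0, k,
2k, ...) plus ungapped extension over both strands: a unique best hit
scores mapping quality 60, ambiguous hits 0. Pairs where either half
has quality < 25 or falls in a user-supplied repeat BED are discarded;
the rest are classified by implied geometry (same-strand gap >
1,000 bp → deletion; negative gap → insertion-like; strand mismatch →
inversion; different chromosomes → interchromosomal). For same-strand
candidates, `refine_breakpoint()` scans every split of the full read
between its two anchors and keeps the split maximizing matched bases,
requiring ≥90% identity per side; ties — microhomology at the
junction — resolve to the leftmost reference coordinate, and the
microhomology length is the number of tying splits minus one.
`call_fusions()` clusters refined junctions within 10 bp and reports
support counts. On fixtures with ≥3 spanning reads per junction,
recovery is base-pair exact (left-aligned), with zero calls on tens of
thousands of concordant reads.

## Problem sizes and tolerances used by the checks

The shipped tests and `scripts/acceptance.R` run entirely on synthetic
data at desk scale, sizes chosen to exercise every code path while
keeping a full run in minutes: mappability oracles on ≤50 kb genomes;
window grids of 20–250 windows over 0.2–1 Mb genomes; CBS on profiles
of 60–500 windows with 2,000 permutations; z-score simulations on the
~3,000-bin grid with cohorts of 10 and 100–500 scored samples; fusion
fixtures with 20 junctions and 10,000 concordant reads. Formula oracles
are checked to 1e-9; distributional checks use two-sided KS at
p > 0.01; detection and recovery rates use the thresholds stated with
each check.

## Known limitations

* Exact k-mer uniqueness is a proxy for aligner mappability; soft-masked
  repeat handling is the user's choice of reference.
* Only CBS is provided as the segmenter (no GLAD or multi-segmenter
  consensus); segment boundaries resolve to window granularity.
* The simulator's iid noise understates real inter-sample correlation;
  detection-limit results are conservative for large cohorts but
  optimistic about how flat real control profiles are.
* Tumor-fraction estimation from allele fractions, fusion annotation
  against gene models, and aligner replacement for real data are out of
  scope; pre-aligned SAM input is the supported route for real samples.
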