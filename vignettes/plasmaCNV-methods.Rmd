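---
title: "Methods: copy-number analysis of plasma cfDNA with plasmaCNV"
author: "plasmaCNV maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number analysis of plasma cfDNA with plasmaCNV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaCNV)
```

## The problem

In patients with advanced cancer, a fraction of the cell-free DNA (cfDNA)
circulating in plasma derives from tumor cells (ctDNA). Because tumor
genomes carry somatic copy-number alterations (SCNAs), the tumor-derived
fraction distorts the genome-wide distribution of sequencing read depth in
a predictable way. plasmaCNV implements a two-assay liquid-biopsy pipeline
built on that signal, oriented toward metastatic breast cancer and the
*FGFR1* amplification at 8p11-12:

1. an inexpensive LINE-1 amplicon screen that reduces a sample to ~40
   chromosome-arm read counts and summarizes aneuploidy as a single
   genome-wide z-score;
2. shallow whole-genome sequencing (sWGS, a few million reads) profiled in
   1-Mb bins, which localizes SCNAs, calls focal amplification of a target
   gene, and supports tumor-fraction estimation;
3. tissue-side anchors (FISH scoring and array copy-number status) and
   cohort-level statistics, including median-split survival analysis.

All coordinates are 0-based half-open; the bundled build is an hg19-like
table of 24 chromosomes with centromere positions at the midpoint of the
hg19 centromeric gaps.

## The admixture forward model

Every quantitative stage rests on one identity. If a genomic region is
present at `c` total copies in tumor cells (diploid background `c = 2`)
and the tumor fraction of the cfDNA is `tf`, its expected depth relative
to a copy-neutral region is

    R(tf, c) = (1 - tf) + tf * c / 2.

`R` is linear in both arguments and `R(tf, 2) = 1` identically. A
noise-free log2 ratio equals `log2 R`, and inverting the identity gives
the absolute copy number of a bin from its log2 ratio and an independently
estimated tumor fraction:

    ACN = 2 * (2^log2Ratio + tf - 1) / tf.

`absolute_copy_number()` applies this inversion exactly; the package's
tests verify the round trip `ACN(log2 R(tf, c), tf) = c` for every integer
state. Noise can drive the inversion below zero, in which case the result
is clipped to 0 and flagged rather than treated as an error. Two numeric
anchors of this model recur throughout the package: a 24-copy amplicon is
still ~0.13 in log2 units at a tumor fraction of only 0.86%, while a
7-copy gain at 0.35% is ~0.013 — far below any calling threshold. The
detectability of a focal amplification is therefore a joint function of
amplitude and tumor fraction, and no single tumor-fraction cutoff
separates detectable from undetectable cases.

## Synthetic data generator

The study conditions this package validates against involve plasma
sequencing data that are not publicly available, so the generator is a
first-class module producing count profiles with known truth.

* **Genotypes** are lists of non-overlapping integer copy-number events on
  a diploid background. The default patient genotype carries
  breast-cancer-typical arm events (1q and 8q gains at 3 copies, 16q and
  17p losses at 1 copy) and, optionally, a 16-copy focal amplification of
  the 1-Mb window harboring *FGFR1* (chr8:38-39 Mb, aligned to the bin
  grid so that recovered copy numbers are exact).
* **Counts** follow a negative binomial with expectation proportional to
  region length x `R(tf, c)` x an optional GC factor, normalized to the
  target depth (default 6,430,000 reads for sWGS, matching the assay's
  typical depth; 100,000 for the arm-level screen). The dispersion
  parameter (default size 200) is defined *per megabase*: a region of
  length L is drawn with size `200 * L / 1e6`. A 1-Mb bin therefore has
  ~7% depth CV while a whole arm, being a sum of many megabase-scale
  units, is counting-statistics limited (~2% CV). A flat per-region size
  would make arm counts as noisy as single bins and cap arm z-scores near
  2 even at 30% tumor fraction, which is inconsistent with the dynamic
  range the arm-level assay is known to have (genome-wide scores in the
  tens at high tumor fraction).
* **GC bias** is an optional multiplicative quadratic in `gc - 0.45`,
  unity at GC 0.45, used to exercise the correction stage;
  `simulate_gc_content()` provides smoothly varying synthetic GC tracks.
* **Cohorts**: controls are independent tumor-fraction-zero profiles with
  seeds derived from one configuration seed (default n = 35, the size of
  the control population the z-score reference emulates). Patient cohorts
  draw tumor fraction log-normal with median 4.6% (sdlog 1.2, spanning
  roughly 0.35%-47%, the observed cohort range), carry the focal
  amplification with prevalence 0.2, and link survival to tumor fraction
  through an exponential model whose log-hazard is linear in log tf
  (baseline median 44 months at the median tumor fraction, administrative
  right-censoring at 72 months — the study's median overall survival and
  follow-up). Setting the hazard slope to 0 yields null cohorts for
  calibration tests.

What the generator does **not** emulate: fragment-length biology,
mappability and replication-timing waves, the true genomic distribution of
LINE-1 amplicons (arm weights default to arm length), sequencing error,
and subclonal heterogeneity. Tests passing on this generator demonstrate
the correctness and calibration of the statistical machinery under the
stated noise model, not performance on real libraries.

## Arm-level aneuploidy z-scores

Arm counts are normalized to fractions over the retained arms: autosomal
arms minus the acrocentric short arms (13p, 14p, 15p, 21p, 22p), 39 arms
in total. Sex chromosomes are excluded by default (configurable): the
cohort being emulated is female and the copy-neutral interpretation of X
is cohort-dependent. Each arm is standardized against a healthy control
cohort, `z_a = (f_a - mu_a) / sd_a` (SD with n-1 denominator), and the
squared z-scores are summed into `S`.

`S` alone has expectation ~39 (the number of retained arms) for a
perfectly healthy sample, which is incompatible with the single-digit
healthy range and the conventional "> 3" aneuploidy threshold used with
this assay. The package therefore standardizes a second time against the
control distribution of `S` itself, computed leave-one-out (each control
scored against the reference built from the remaining n-1, avoiding
self-inclusion bias):

    gw_z = (S - mean(S_controls)) / sd(S_controls).

This two-stage score is centred near 0 for healthy samples, calibrated
(fewer than 5% of null samples exceed 3 in the package's tests), and
reproduces the expected dynamic range. The raw `S` is always reported
alongside, and `standardized = FALSE` restores the raw mode, since the
exact normalization used by the original assay implementation is not
fully specified. Samples under 100,000 reads are flagged in QC output,
not rejected.

Because low-tumor-fraction signal sits well below arm-level counting
noise, monotonicity of `gw_z` in tumor fraction is a property of its
expectation; the test suite estimates it with 100 replicates per
tumor-fraction rung using common random numbers across rungs.

## sWGS log2 ratios, segmentation, and focal calling

**GC correction** fits depth against GC by loess (span 0.3, degree 2)
over bins with GC in [0.3, 0.6] and rescales each bin by
`median(count) / fitted(gc)`; out-of-range or GC-less bins are excluded
with a recorded reason. **Log2 ratios** divide the sample's per-bin
fraction by the median fraction across a panel of healthy controls; bins
with a zero or undefined control median are excluded.

**Segmentation** is a deliberately simple deterministic alternative to
circular binary segmentation, adequate at 1-Mb resolution: recursive
binary splitting at the position maximizing the pooled-variance
two-sample t statistic, accepting a split when p < 1e-4 and both sides
keep >= 3 bins, followed by a local sweep that shifts each accepted
breakpoint within +/-3 bins to the SSE-minimizing position. Breakpoint
*detection* runs on values winsorized toward a running median (window 5,
2.5 MADs): a single-bin amplicon would otherwise inflate the
within-segment variance and mask the adjacent arm-level breakpoint.
Winsorization is skipped when the residual MAD is zero, so noise-free
step profiles split exactly at the step; segment *means* are always
computed from raw values, so the bin-weighted mean of segment means
equals the profile mean exactly. Segments are labelled gain / loss /
balanced at +/-0.1 log2 units.

**Focal amplification calling** uses three configurable criteria, all
required: the gene-window mean log2 ratio is at least `min_log2` (0.1);
it exceeds the median of its chromosome arm by at least `min_delta`
(0.1), so whole-arm gains alone never fire; and the contiguous run of
bins around the gene staying `min_delta` above the arm median spans at
most `max_len` (20 Mb). The run, not the covering segment, measures
focality: under the minimum-segment-size rule a 1-Mb amplicon can never
be isolated as its own segment, so a covering-segment criterion could
never pass at the resolution the pipeline targets. The 0.1 thresholds
are matched to the labelling scale and chosen so that a high-amplitude
amplification (24 copies at 0.86% tumor fraction, log2 ~0.13) is
callable while a 7-copy gain at 0.35% (log2 ~0.013) is not — the
qualitative detection boundary the assay exhibits. They are thresholds
on noise-free means; on real single samples the per-bin noise at this
depth (~0.1 log2 units) makes calls near the threshold unstable, which
is why all criteria inputs are recorded in the call object.

## Tumor-fraction estimation

A simplified, deterministic stand-in for HMM-based estimators such as
ichorCNA (explicitly out of scope). Over a grid tf in {0.0025, ...,
0.8}, each segment is assigned the integer copy state c in 0..8 whose
`R(tf, c)` is closest to its observed `2^mean_log2`, and the reported
estimate minimizes

    score(tf) = sum_s w_s (m_s - R(tf, c_s))^2
              + penalty * sum_s w_s |c_s - 2| / 2,

with bin-share weights `w_s`. Two numerical choices matter:

* **The aberration penalty** (default 5e-4) exists to resolve a real
  degeneracy: the substitution `tf -> tf/2, c -> 2 + 2(c - 2)` leaves
  every fitted value — hence the squared error — exactly unchanged, so an
  unpenalized fit cannot distinguish a tumor fraction from its half at
  doubled amplitudes. Penalizing distance from diploid breaks the tie
  toward the less aberrant genome. The weight is bounded below by the
  squared noise of small-segment means (~4e-4; any smaller and extreme
  states absorb noise at spuriously small tf) and above by the signal
  `(tf/2)^2` at the smallest tumor fraction the estimator should recover
  (~6e-4 at tf 0.05); 5e-4 sits inside that window.
* **Ties are broken toward the smallest tumor fraction**, so an
  all-balanced (unidentifiable) profile returns the grid minimum, flagged
  `low_confidence` (under 5% aberrant bins).

Segments within 3 Mb of a called focal amplification should be masked
from the fit (`mask`): a single amplicon above the 8-copy state cap
would otherwise pull the genome-wide estimate. On noise-free profiles of
the default genotype the estimator recovers on-grid tumor fractions
exactly; under the generator's noise model the median absolute error
across tf 0.05-0.4 is within 0.03 (test suite, 20 replicates per rung).

## Tissue stages and cohort statistics

FISH scoring follows the two-tier rules as printed in the scored cohort
table: **amplified** if the gene/centromere ratio is >= 2.0 or the mean
gene signals per nucleus >= 6.0; otherwise **low amplified** if >= 50% of
tumor cells carry >= 5 signals or >= 10% carry >= 15 signals or clusters;
otherwise balanced. All thresholds are inclusive (the table-header
convention, which reproduces every printed per-row status, including the
case sitting exactly at a 60% quotient), and the main tier takes
precedence. The centromere count is informational; a ratio inconsistent
with gene/centromere counts by more than 10% draws a warning only.
Array (Oncoscan-style) status uses a copy-number >= 3 gain threshold,
the smallest printed "gain" value in the bundled table. Concordance
treats FISH amplified/low-amplified as positive and array gain as
positive, reporting the agreement percentage rounded to the nearest
integer with discordant cases listed.

Survival analysis uses the product-limit estimator with log-log
Greenwood 95% intervals and the two-group log-rank test (chi-squared,
df 1), both via the survival package behind the module's interface, and
verified in the tests against hand-computed product-limit and log-rank
oracles. Median splits assign values equal to the median to the **low**
group — a convention that must be fixed for determinism because the
bundled plasma cohort has two samples exactly at the tumor-fraction
median, where the choice changes group sizes. Threshold counts use
strict inequality ("greater than 3"), matching the wording of the
summaries they reproduce.

## Bundled data

`fgfr1_fish_cohort()`, `fgfr1_oncoscan_cohort()` and
`fgfr1_plasma_cohort()` return the printed per-case tables of a
published 100-patient metastatic breast cancer cohort (20 FISH-positive
cases; 11 with array confirmation; 20 with plasma profiling). They are
the package's desk-scale ground truth: re-classifying the FISH table
reproduces the printed 17 amplified / 3 low-amplified split, the array
comparison gives 91% concordance with a single discordant case, and the
plasma table reproduces median z-score 2.2, median tumor fraction 4.6%,
8 samples with z > 3, 12 with tumor fraction > 3%, and an R-squared of
0.81 between the two tumor-burden estimates. The plasma table is stored
verbatim, including one internally inconsistent row (a FISH-amplified
case at 3.9% tumor fraction with a negative plasma call) that the
surrounding text of the source cohort would contradict; no statistic
asserted by this package depends on it.

## Problem sizes and limitations

The test suite and examples run at the study's own scales — 1-Mb bins
genome-wide (~3,100 bins), 6.43 million reads per sWGS profile, 100,000
reads per arm profile, 35 controls — with replicate counts (20-300 per
property) chosen so that each stochastic check estimates its quantity to
well within the asserted tolerance. Known limitations: no allele-specific
or subclonal copy number, no ploidy estimation, no mappability or
fragmentomics modelling, breakpoints only at bin resolution, and the
tumor-fraction estimator is a grid fit, not a reimplementation of the
HMM it stands in for; its absolute values on real data should be
interpreted accordingly.
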