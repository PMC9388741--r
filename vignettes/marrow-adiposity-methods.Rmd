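---
title: "Quantifying marrow adiposity and screening circulating miRNAs after spinal cord injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying marrow adiposity and screening circulating miRNAs after spinal cord injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowmir)
```

# The scientific problem

Spinal cord injury (SCI) triggers rapid, severe bone loss below the level of
the lesion, and the marrow of unloaded long bones converts from hematopoietic
to adipose tissue. `marrowmir` implements the computational machinery for
studying that process through two linked measurements: plasma miRNA
abundance from small-RNA sequencing (miR-148a-3p being the biomarker of
interest) and marrow adipose tissue (MAT) volume at the knee quantified from
calibrated CT. Around those sit the supporting analyses such a study needs:
cohort characteristic testing from summary statistics, novel-miRNA hairpin
filtering, predicted-target consensus, and univariate/multivariable
association modelling.

Because subject-level data from such a cohort cannot ship with a package,
every stage is paired with a seeded synthetic-data generator that produces
inputs with known ground truth. The generators are first-class, tested code:
the package's claims about its pipelines are claims verified against those
ground truths.

# QCT quantification of marrow adipose tissue

A knee CT scan with an in-field calibration phantom is processed in five
deterministic steps.

1. **Calibration.** The mean HU of each phantom rod ROI is regressed on the
   rod's known bone-equivalent density, giving a per-scan linear map
   $\rho(\mathrm{HU}) = a\,\mathrm{HU} + b$ in g/cm^3^. At least two rods
   with distinct HU are required; the fit is ordinary least squares.
2. **Periosteal segmentation.** Voxels with calibrated density at or above
   0.15 g/cm^3^ are thresholded; the largest 26-connected component is the
   bone (rods and table parts form smaller components); interior holes are
   filled slice-wise (background not reachable from the in-plane border) and
   then in 3-D. The hole filling automates the manual correction of missing
   low-density surface voxels that interactive protocols need. A genuine
   perforation through the full cortical thickness of a one-voxel wall is
   *not* sealed — at clinical CT resolution the cortex is several voxels
   thick, so a single sub-threshold surface voxel leaves the shell closed.
3. **Cortical/trabecular split.** The periosteal mask is eroded in-plane by
   a Euclidean disc whose radius is `round(3.5 mm / pixel size)` pixels
   (round half away from zero; the divisor is the in-plane pixel size, not
   the slice thickness, hence the slice-wise erosion). The eroded mask is
   trabecular; the removed rim is cortical. The two tile the periosteal
   mask exactly, an invariant asserted in the tests.
4. **Region partition.** Bone length is the slice extent of the segmented
   mask (not the scan extent, which is acquisition-dependent). From the
   joint-facing reference end, the epiphysis, metaphysis and diaphysis are
   the consecutive bands [0, 10%), [10%, 20%) and [20%, 30%) of bone
   length, with edges at `floor(fraction * n_slices)` and half-open slabs.
   We read the three published percentages as cumulative band edges rather
   than band midpoints; the edges are configurable.
5. **MAT and BMC.** MAT volume per region counts trabecular voxels with
   attenuation in the inclusive window $[-205, -50]$ HU times the voxel
   volume; "between −205 and −50" is read inclusively, and the window is
   configurable. Trabecular BMC integrates calibrated density over
   trabecular voxels; marrow commonly calibrates to *negative*
   bone-equivalent density, so negative regional BMC is legitimate and
   preserved.

Key tunables, all arguments with these defaults: periosteal threshold
0.15 g/cm^3^, erosion depth 3.5 mm, HU window (−205, −50), band edges
(0.1, 0.2, 0.3).

## The CT phantom generator

`generate_ct_phantom()` builds an axis-aligned cylinder with a hemispherical
distal cap: a cortical shell (default 1.2 g/cm^3^, 2.5 mm thick) around a
marrow interior (default +30 HU, red-marrow-like) salted with trabecular
struts (default 0.3 g/cm^3^, 10% of interior voxels) and an exact number of
fat voxels (default −120 HU) per region, plus calibration rods whose HU are
exact under the true line. Default geometry (150 mm bone, 15 mm radius) and
spacing (0.8 × 0.8 × 1.0 mm) sit inside the scan protocol's resolution
range (in-plane 0.652–0.977 mm, slices 0.625–1.250 mm).

Two construction choices make ground truth exact rather than approximate:

* Fat voxels are placed with a two-pixel safety margin inside the eroded
  mask, so the cortical erosion can never touch them; the true per-region
  MAT volume is exactly `count × voxel volume`.
* The truth trabecular mask is produced by the same documented mask
  definition the analysis uses (solid eroded by `round(3.5/pixel)` pixels).
  The closure test therefore verifies calibration, segmentation,
  partitioning, windowing and integration — everything except the erosion
  primitive itself, which has its own brute-force per-pixel oracle test.

What the phantom does **not** emulate: realistic anatomy, beam hardening,
scatter, partial-volume blur, or scanner noise correlation (noise, when
requested, is i.i.d. Gaussian HU). Passing the closure test shows the
pipeline's arithmetic and mask logic are exact; it does not certify
segmentation performance on clinical images.

# Count normalization and the differential screen

Raw counts $c_{ij}$ (miRNA $i$, sample $j$) are normalized by the
median-of-ratios library size parameter
$$ s_j = \operatorname{median}_i \; \frac{c_{ij}}{(\prod_{k=1}^{m} c_{ik})^{1/m}}, $$
the median over miRNAs of the ratio of each sample's count to the
geometric-mean pseudo-reference. Only miRNAs with strictly positive counts
in every sample enter (a zero anywhere annihilates the geometric mean); the
median of an even count is the mean of the central pair. A consequence of
the definition worth stating: scaling *all* samples by a common factor
leaves every $s_j$ unchanged — the pseudo-reference absorbs the scale — and
scales the normalized matrix linearly; the invariant tests assert exactly
this. The estimator agrees with the standard RNA-seq implementation of the
same statistic (checked against DESeq2's `estimateSizeFactorsForMatrix` in
the suite, to common scale).

The differential screen compares normalized counts per miRNA: two groups
get a two-sample t-test whose variance rule is chosen by a folded-F pretest
(below), three or more get one-way ANOVA; Fisher/chi-squared count policies
remain available as options for presence/absence-style screens. Raw
p-values are tiered at 0.05 and 0.01 (the study's two thresholds) with
Benjamini–Hochberg available behind the `p_adjust` flag; the log2 fold
change of normalized group means uses a pseudo-count (default 0.5) only
when a group mean is zero. The output table carries volcano coordinates
(`log2fc`, `neg_log10_p`).

The count generator draws negative-binomial counts with variance
$\mu + \mu^2\phi$ (Poisson at $\phi = 0$), per-sample library factors, and
a spiked differential set at a chosen log2 effect. Defaults mirror the
study's comparison arms (12 vs 18 samples); abundances are log-normal
(meanlog 4, sdlog 1.5 — spanning the count range a plasma miRNA library
shows), factors log-normal with sdlog 0.25, dispersion 0.1, effect 1.5,
10% differential. A t-test on NB counts at these sizes holds its nominal
type-I error to within binomial error, which the suite verifies on 1000
null miRNAs.

# Hairpin structure filtering

Novel-miRNA candidates arrive as Vienna-style records (sequence,
dot-bracket structure, predicted free energy, mature-arm coordinates);
folding itself is upstream and out of scope. The parser performs
stack-based bracket matching, requires exactly one terminal loop
(multibranch folds and multi-hairpin strings are rejected as non-hairpins),
and extracts stem pairs, the terminal loop, and every internal loop with
its per-strand unpaired run lengths.

Eleven criteria, with defaults exactly as published, gate acceptance:
stem bulge ≤ 12 nt; stem pairs ≥ 16; free energy ≤ −15 kcal/mol; hairpin
length ≥ 50; loop ≤ 20; mature-region bulge ≤ 8 nt; biased errors in one
mature bulge ≤ 4; biased bulges in the mature region ≤ 2; mature errors
≤ 7; mature pairs ≥ 12; percent of mature in stem ≥ 80. Inequalities are
inclusive exactly as printed. The verdict is the conjunction of the eleven
flags, and relaxing any single threshold can only grow the passing set (a
tested monotonicity property).

Two of the criteria have no published definition. We read "biased" as
strand asymmetry of an internal loop: for unpaired runs of $a$ and $b$
nucleotides on the two strands, the biased error count is $|a-b|$ and a
biased bulge is a loop with $a \neq b$. "Stem", for the percent-in-stem
criterion, means both arms between the outermost pair and the terminal
loop, bulge nucleotides included (so dangling ends and loop overhang reduce
the percentage, internal bulges do not). Both readings are configurable
points of interpretation, flagged here deliberately.

The generator emits valid candidates (randomized 23–35 bp stems, 4–15 nt
loops, energies −35 to −18, fully paired 22-nt mature arm) and invalid ones
cycling through eleven constructions, each engineered — and unit-tested —
to violate exactly one criterion.

# Cohort statistics from summary triplets

Clinical tables print (mean ± SD, n); the testing engine consumes exactly
that, so the published testing column is reproducible with no subject data.
The two-sample t-test picks its variance rule by a folded-F pretest at
$\alpha = 0.05$: $F = (s_{hi}/s_{lo})^2$ against $F(n_{hi}-1, n_{lo}-1)$,
doubled. Compatible variances give the pooled test (df $n_1+n_2-2$);
incompatible ones the Satterthwaite approximation with fractional df. The
pretest itself is our inference about an unstated analysis choice — it is
the rule that jointly reproduces the published p-values (the marrow
adiposity and miR-148a-5p rows match the Satterthwaite branch, the
miR-148a-3p, age and age-at-injury rows the pooled branch) — and it is
overridable (`rule = "pooled"` / `"satterthwaite"`). One-way ANOVA is
reconstructed from between/within sums of squares; Tukey–Kramer pairwise
comparisons use $q = |\bar x_i - \bar x_j| / \sqrt{\tfrac{MSE}{2}(1/n_i + 1/n_j)}$
against the studentized-range distribution with $k$ means and $N-k$ df.
Every summary-statistic test equals its raw-data counterpart on vectors
constructed to match the summaries exactly — an equivalence the suite
enforces against `t.test`, `aov` and `TukeyHSD`.

Categorical variables route by expected counts: Fisher's exact test
(two-sided by the probability-mass definition) when a 2×2 table has an
expected cell below 5, otherwise Pearson chi-squared without continuity
correction. Larger-than-2×2 tables use chi-squared regardless — consistent
with the published three-group sex comparison, whose printed p matches the
chi-squared value despite a small expected cell.

Two published numbers deserve a note. The chronic-vs-acute Tukey-adjusted
p for miR-148a-3p computes to 0.015 against a printed 0.01, and the
three-group ANOVA for miR-148a-5p computes to 0.039 against a printed 0.03;
the exact post-hoc machinery behind those two entries is ambiguous, and the
package reports its computed values. All other table p-values reproduce at
printed precision.

# Association modelling

Univariate models are ordinary least squares of diaphysis MAT on one
predictor (slope ± SE and two-sided p for continuous predictors; per-level
means ± SE with the overall F-test p for categorical ones), complete-case.
The multivariable builder applies the published inclusion rule — univariate
$p < 0.10$ — and fits a single OLS model with all passing candidates. Two
subtleties:

* A *printed* univariate p equal to the threshold is ambiguous: a table
  entry of 0.10 at two decimals covers unrounded values down to 0.095. With
  `printed = TRUE` (the default when precomputed p-values are supplied)
  such ties are included, which is what makes BMI enter the final model as
  published. On unrounded p-values the rule is strict.
* Categorical injury duration passes the rule handily yet is absent from
  the published multivariable model (plausibly because group membership is
  nearly collinear with the biomarker). The builder does not guess: an
  explicit `override` term list reproduces any published model exactly.

The published model-level quantities (coefficients, R² = 0.24) require the
deposited subject-level data and are not reproducible from the package's
inputs; the suite instead verifies the estimator (closed-form agreement,
unbiased slope recovery at n = 30 over 500 replicates, uniform null
p-values, residual orthogonality).

# Target consensus

Predicted targets are the intersection of three database lists after
filtering TargetScan records at context score ≤ −0.4 (more negative =
stronger predicted repression; the direction is configurable since the
published cutoff states only the value). Strict three-way intersection is
the default, with a two-of-three mode available. The packaged target lists
are labelled synthetic: they are constructed stand-ins carrying the six
validated bone/fat-metabolism genes (DNMT1, IGF1, MAFB, KDM6B, WNT1,
WNT10B) plus decoys, for exercising the filter; they are not database
exports.

# Orchestration

`run_pipeline()` executes the stages in dependency order from a single
config (R list or YAML), derives every stage seed from one root seed, and
writes result tables, a manifest (seed, parameters, MD5 per output) and a
plain-text report. Reruns under one config are byte-identical. The
package's interface is its functions, scripts and this document; the
pipeline layer is the single entry point a reproduction run needs.

# Numerical and engineering choices

* Connected components are labelled on foreground voxels only (via a graph
  of 26-neighbour links), so cost scales with the shell, not the volume;
  flood fills and disc erosions are vectorized shift-and-combine passes.
  The morphology is written in-package so the mask definitions above are
  exactly the implemented ones.
* Anisotropic in-plane spacing (rare in practice) falls back to the mean
  pixel size with a warning.
* Degenerate inputs have defined outcomes rather than errors where a
  convention exists: identical summaries give $p = 1$; zero-MSE Tukey
  comparisons flag degeneracy; erosion that removes the whole bone warns
  (empty trabecular mask) instead of failing.
* Rounding for printed-value comparison is half-away-from-zero, matching
  how clinical tables are typeset.
* Problem sizes in the test suite and acceptance script — 1000-miRNA null
  screens, 500-replicate slope recovery, 200-candidate hairpin batches,
  150 mm phantoms at 0.8 mm pixels — are the sizes at which the Monte-Carlo
  error bands quoted above are meaningful while a full run stays
  interactive on a laptop.

# Known limitations

* The periosteal segmentation assumes the bone is the largest
  supra-threshold component and that the cortex is closed at voxel
  resolution; pinhole perforations of a one-voxel wall leak (see above).
* The summary-statistic engine reproduces tests computable from (mean, SD,
  n) or counts; it cannot recover subject-level quantities (regression
  coefficients, R²) and does not attempt to.
* The hairpin module consumes structures; disagreement between folding
  engines upstream is invisible to it.
* Synthetic cohorts draw covariates independently within groups; real
  cohort covariance (age with injury duration, BMI with MAT) is not
  emulated, so association-model performance on generated cohorts reflects
  estimator correctness, not epidemiology.
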