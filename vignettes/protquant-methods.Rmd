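---
title: "Models and methods behind protquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind protquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protquant)
library(dplyr)
```

protquant implements the two quantitative arms of an FFPE breast-lesion
proteomics workflow: relative, label-free comparison of ductal carcinoma
*in situ* (DCIS) against invasive ductal carcinoma (IDC), and absolute,
targeted quantitation of selected peptides by parallel reaction
monitoring (PRM) with stable-isotope-labeled internal standards (SIS).
This vignette explains the statistical models, the tunable parameters,
the numerical choices, and the points where the published procedure left
a genuine design decision to the implementation.

## The label-free arm

### Preprocessing chain

The LFQ substrate is a proteins-by-samples grid of linear MS1
intensities with missing cells. Four operations are applied in a fixed
order:

1. **Detection filter** (`filter_by_detection()`). A protein is kept
   only if it has at least one protein-unique peptide
   (`min_unique_peptides = 1`) and a positive intensity in at least 60%
   of the samples of at least one study group (`min_frac = 0.6`). Zero
   intensities do not count as detections.
2. **Summed-intensity normalization** (`normalize_sum()`). Sample
   loading differences are corrected by scaling each sample so its sum
   of *observed* intensities equals the cohort median of those sums.
   The median reference makes the factors robust to a single outlier
   sample and scale-free; any common reference yields the same
   between-sample ratios, which is all downstream statistics see.
3. **Imputation** (`impute_missing()`). Each missing cell is replaced
   by 1.5 times the minimum observed intensity *of that sample*. Note
   the published rule places imputed values above the observed floor —
   unlike the conventional down-shifted imputation used for
   left-censored data (one might have expected min/1.5). The rule is
   implemented exactly as stated, with the multiplier exposed as
   `factor` for users who prefer a sub-minimum value.
4. **Log2 transform** (`log2_view()`).

Normalization deliberately precedes imputation and uses observed cells
only, so that imputed values can never influence the loading factors;
imputation then operates on normalized minima. Filtering first avoids
normalizing over proteins that are about to be discarded. Within each
sample the chain preserves the rank order of observed intensities.

Spectral counts are summarized by the normalized spectral abundance
factor, `NSAF = (count/length) / sum(count/length)` per sample
(`compute_nsaf()`), which removes both protein-length and sequencing-
depth effects; every sample column sums to one.

### Differential expression

Per protein, group means are taken on the log2 scale and compared with
a pooled-variance (Student) unpaired two-tailed t-test with
`df = n_a + n_b - 2`; the fold change is the difference of log2 group
means, matching the volcano-plot axes. Welch's correction is not the
default because the workflow mirrors the classic unpaired test; the
degenerate zero-variance cases are resolved deterministically
(equal means: t = 0, p = 1; unequal means: p = 0 with a flag).

Multiple testing uses the **two-stage adaptive linear step-up**
procedure (Benjamini–Krieger–Yekutieli). Stage one is a
Benjamini–Hochberg (BH) step-up at level $q' = \alpha/(1+\alpha)$; its
rejection count $r_1$ estimates the number of true nulls as
$\hat m_0 = m - r_1$, and stage two is a BH step-up at level
$q' m/\hat m_0$. The procedure has no closed-form adjusted p-value, so
the per-protein q-value is defined by threshold inversion: the smallest
nominal FDR level at which the protein is rejected, located by
bisection to an absolute tolerance of $10^{-6}$. Internally both stages
are step-ups over the same sorted BH-adjusted p-values, which makes a
single accept/reject evaluation logarithmic in $m$ and the whole
q-vector cheap even for thousands of proteins. Rejection flags come
from the exact decision at the nominal level, not from the bisected
q-values (the two agree to the bisection tolerance).

One property worth spelling out: the adaptive procedure always rejects
at least what plain BH rejects *at its stage-one level* $q'$, because
stage two never runs below $q'$. It does **not** always contain the BH
rejection set at the nominal level $\alpha$ itself — when $r_1$ is
small, the stage-two level $q' m/(m - r_1)$ stays below $\alpha$, and
the adaptive procedure can reject strictly fewer hypotheses. The test
suite keeps a concrete instance of this as a regression case.

A protein is called differential when `q < 0.01` **and**
`|log2 FC| > 1` (both strict). These defaults follow the analysis
methods; the stricter volcano-figure variant (p-based threshold,
`|log2 FC| > 2`) is reachable purely through the `q_threshold` /
`log2fc_threshold` arguments. For enrichment tools,
`build_ranked_list()` exports `sign(log2FC) * (-log10 p)` in descending
order with p clipped at `1e-300`; this signed score is a stated
convention of the package, chosen so that direction and significance
are encoded in a single number.

### A limitation worth knowing: composition bias

Summed-intensity normalization assumes that most of the signal is
unchanged between groups. When spiked effects are one-sided, the
spiked proteins change the per-group sums, and normalization shifts
*every* log2 fold change by $\log_2(s_A/s_B)$, where $s_g$ is the
group-level summed intensity. In the noise-free simulation with 100
proteins spiked two-fold up among 2,800 this offset is ≈ 0.1–0.2 log2
units: the spiked set is still called exactly (the offset is far from
the ±1 threshold), but fold changes are not recovered to numerical
precision through the full chain. This is a property of the published
normalization itself, not of the implementation; the acceptance script
reports the measured offset honestly as
`noise_free_max_abs_log2fc_error`. Ratio-based normalizations
(median-of-ratios) would avoid it, but are not what this workflow
specifies.

## The PRM arm

### Response curves

Each peptide's calibration series pairs a variable amount of light
(endogenous-sequence) peptide — by default a seven-point geometric
ladder from 0.41 to 250 fmol — with a constant 50 fmol SIS spike. The
observed response is the light/heavy area ratio. Note the ratio is
oriented analyte-over-standard (NAT/SIS): with the heavy amount
constant, that ratio is linear in the light amount, which is what a
linear calibration model requires; the inverse orientation would be
hyperbolic in the spiked amount. The orientation is just a convention
of the report format — `read_prm_report_csv()` computes
`light_area/heavy_area` per row.

The curve is fit by weighted least squares with $1/x^2$ weights on the
per-level mean ratios. That weighting is the standard bioanalytical
choice when the response SD grows proportionally with the level — which
is exactly how the simulator generates noise (`ratio_cv`), and which
makes the weighted fit equivalent to ordinary least squares on the
transformed model $y/x = b + a/x$ (a property the tests exploit as an
independent oracle).

### Calibration-level acceptance

A level is accepted when its replicate precision (CV, sample SD over
mean, in percent) is below 20% and its back-calculated accuracy is
between 80% and 120% of nominal. Accuracy needs a curve, and the curve
depends on which levels are included, so acceptance iterates to a
stable set (at most 10 rounds, levels may re-enter).

One subtlety is *which* fit a level's accuracy is judged against.
Under $1/x^2$ weighting the lowest level dominates the fit; if its own
observation is included, the two-parameter line absorbs the level's
bias into the intercept and its back-calculated accuracy is ~100%
regardless of how biased it is. The accuracy check is therefore
**leave-one-out**: each level is back-calculated through the curve fit
to the other currently included levels (already-excluded levels are
judged against the full included fit when considered for re-entry).
This makes a deviating anchor point detectable while leaving honest
levels untouched; for noiseless data every level back-calculates to
exactly 100% either way.

A curve is valid only if the stable accepted set contains at least
three *consecutive* levels of the original ladder. When exclusions
split the accepted set into several qualifying runs, the run containing
the highest level is kept, preserving usable dynamic range toward the
top of the ladder; the reported slope, intercept and (weighted) r² are
refit on that run.

### LOD, LOQ and quantitation

The limit of detection is computed from double-blank injections (SIS in
surrogate matrix, no light peptide): each blank ratio is back-calculated
through the curve, and LOD = blank mean + 3.3 × blank SD (sample SD,
n−1), floored at zero. The limit of quantitation is the lowest accepted
calibration level — the smallest amount at which the precision and
accuracy criteria were demonstrably met. With a noisy blank the LOD can
exceed the LOQ; the package flags this with a warning rather than
silently reordering the bands.

Endogenous amounts are back-calculated as
$\hat x = (y - b)/a$ and normalized to the digested protein input
(fmol/µg; 50 fmol SIS per 1 µg input in the reference protocol).
Censoring is reported per cell: `not_detected` (no ratio), `below_LOD`
(including negative back-calculations, reported as 0), `below_LOQ`, or
`quantified`. Peptides missing (`not_detected`) in more than 60% of
samples are excluded by `filter_prm_matrix()` — strictly more than, so
a peptide at exactly 60% is retained. For differential analysis of PRM
panels, cells censored as `not_detected`/`below_LOD` are treated as
missing and imputed by the same per-sample minimum rule as the LFQ arm
(concentrations being absolute, no loading normalization is applied),
then passed through the identical t-test/FDR machinery.

## The synthetic-data generator

No raw MS data ship with the package; every test runs on simulated
inputs with the statistical structure the analysis assumes.

**LFQ cohorts** (`simulate_lfq_dataset()`): the latent log2 intensity is
a sum of a grand mean, a per-protein offset
(`between_protein_sd`, default 2 log2 units — a wide, log-normal-like
abundance range spanning several orders of magnitude), a fixed group
effect applied to the designated differential proteins in the second
group, a per-sample loading offset (`loading_sd`, default 0.2), and
within-group noise (`within_group_sd`, default 0.5 — a typical
replicate spread for FFPE label-free data). Missingness is
intensity-dependent: a cell drops out with logistic probability rising
as latent intensity falls (`dropout_midpoint`, `dropout_steepness`).
This missing-not-at-random censoring is what motivates minimum-based
imputation; the published workflow states no missingness mechanism, so
the logistic form is the package's own stand-in. The default cohort
mirrors the reference study's arms (29 pure-DCIS vs 18 pure-IDC cases,
~2,800 quantified proteins). The generator does *not* emulate peptide-
level roll-up, FFPE chemistry artifacts, or batch structure beyond the
per-sample loading offset — so green tests certify the statistics, not
robustness to those real-data complications.

**Spectral counts** (`simulate_spectral_counts()`): Poisson draws with
expectation proportional to linear abundance × protein length, scaled
to an expected per-sample depth (`mean_depth`, default 1e5).

**PRM calibration** (`simulate_calibration_set()`): per peptide a true
slope is drawn uniformly from `slope_range` (default 0.005–0.05 per
fmol, i.e. ratios near 1 at mid-ladder for a 50 fmol SIS), intercept 0;
replicate ratios get proportional noise (`ratio_cv`, default 5%, the
level of a well-behaved scheduled PRM assay), and blanks draw an
apparent concentration from `Normal(0.2, 0.05)` fmol — a faint
cross-talk/noise floor well below the lowest calibrant. Three
replicates per level is the default: the smallest number from which a
CV can be computed, and common practice for response curves. The exact
intermediate ladder levels are not printed in the reference protocol,
so a geometric (equal log-spacing) ladder between the stated endpoints
is used.

## Calibration checks and problem sizes

The package validates itself with fixed study conditions, chosen once:

- **Null calibration**: 2,000 proteins, 15 vs 15 samples,
  `within_group_sd = 0.5`, no true effects, 20 seeds. The fraction of
  raw p < 0.05 must average 0.05 (±0.005) and two-stage rejections at
  FDR 1% must be essentially absent. These runs disable dropout and
  loading variation and feed the complete log2 intensities to the
  comparison: the point is the *test stage's* type-I calibration, which
  MNAR censoring plus floor-imputation would distort (that distortion
  is a real phenomenon, and one reason imputed
  data should be interpreted cautiously near the detection limit).
- **Spike-in recovery**: 100 of 2,000 proteins spiked at |log2 FC| = 2
  under the same noise, 10 seeds; sensitivity ≥ 0.9 at FDP ≤ 0.05.
- **Oracle agreement**: the two-stage q-values against an independent
  brute-force step-up (≤ 1e-5), and the weighted fit against
  transformed OLS (≤ 1e-8 relative), on seeded random inputs.
- **Curve recovery**: 100 simulated peptides at 5% ratio CV — median
  relative slope error ≤ 2%; noiseless series recover slopes to
  machine precision; the LOD worked example (blanks back-calculating
  to 0.9/1.0/1.1 fmol → LOD 1.33 fmol) is exact.

These sizes keep the full suite fast while leaving the Monte-Carlo
bands narrow enough to be meaningful.

## Numerical conventions

- q-value inversion bisects on (0, 1) to 1e-6; ties in p receive equal
  q; q is made monotone in rank by a running maximum.
- p-values are clipped at 1e-300 before `-log10` ranking.
- Sample SD (n−1) everywhere a SD is taken (CV, LOD).
- Zero pooled variance: t = 0/p = 1 on equal means, p = 0 plus a
  `degenerate` flag otherwise.
- All simulation randomness flows from a single integer seed per
  config; the three generators draw from seed-derived independent
  streams, so results are bit-reproducible.
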