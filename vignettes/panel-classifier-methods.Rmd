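---
title: "Methods: discovering and validating a blood protein panel classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and validating a blood protein panel classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seropanel)
```

## The problem

Symptomatic patients referred for colonoscopy — the intent-to-test (ITT)
population — carry a colorectal cancer (CRC) prevalence around 10.9%, far
above the screening population. A blood test that stratifies risk in this
group can raise colonoscopy compliance where it matters most. seropanel
implements, end to end, the statistical workflow for building such a test
from multiplexed electrochemiluminescence immunoassay measurements of 27
plasma proteins: assay quality control, grid-search classifier discovery
under repeated cross-validation, optimization of an indeterminate
(gray-zone) score range, model locking, and validation statistics.

Because no patient-level data from such studies are public, the package
carries a first-class synthetic-data module that emulates the ITT cohort
structure. Every downstream stage is exercised — and tested — against that
generator.

## The synthetic ITT cohort

`cohort_spec()` encodes the study population:

* **Diagnostic groups.** Subjects fall into eight groups (colon cancer,
  rectal cancer, colon/rectal adenoma, no comorbidity-no finding,
  comorbidity-no finding, other cancer, other finding) with default
  proportions taken from the published cohort's raw counts
  (319/193/515/174/1164/814/177/1342 over 4698). We use counts rather than
  the printed percentages because the percentages round to a 100.1% total;
  the counts sum exactly.
* **Stages.** CRC subjects receive UICC TNM stages I–IV with proportions
  101 : 163 : 139 : 108.
* **Demographics.** Age and gender are deliberately *not* balanced across
  classes, mirroring a true ITT design: controls are drawn from
  N(62.7, 12.6²) years and are 53.4% female; cases from N(69.7, 10.6²) and
  42.4% female. Ages are truncated to [18, 96] (the published min/max);
  BMI to [10, 60], a deliberately loose plausibility envelope.

`panel_spec()` models concentrations as multivariate log-normal — positive
support and a 3–4 log dynamic range, matching immunoassay reality. Each
analyte has a baseline log-mean (default: the geometric midpoint of its
quantitation range, mapped to the sample scale through the panel dilution
factor, so simulated plates land mid-curve), a log-SD (default 1), and an
additive log-scale class shift δ for CRC subjects.

### Effect-size calibration

For two equal-variance normals on the log scale separated by δ, the
univariate AUC is Φ(δ/(σ√2)); `effect_size_for_auc()` inverts this
exactly. Default targets anchor the three markers with published
univariate electrochemiluminescence AUCs — CEA 0.725 (δ ≈ +0.845),
CO9 0.742, MIF 0.493 (δ ≈ −0.025, a marker *lower* in cases) — and set all
remaining analytes to a weak 0.55. Analyte–analyte correlation defaults to
zero, with an optional +0.3 block among the acute-phase proteins (A1AG,
SAA, CRP, HPT, AACT); no joint distribution is published, so independence
is the conservative default and the block illustrates the mechanism.

What the generator does **not** emulate: comorbidity-specific concentration
signatures, clinic-of-origin effects, assay drift over plates, and any
real biological correlation structure. Tests passing on this generator
demonstrate the *procedures* are correct and unbiased — not that the
published clinical performance would be reproduced on real plasma.

## Plate simulation and assay QC

`simulate_plates()` reproduces the assay workflow geometry: 96-well plates
per panel with a standard curve (seven 4-fold standards and a blank, in
duplicate — the published LLoQ/ULoQ pairs sit almost exactly 4⁶ apart,
which is why the 4-fold series is the natural choice), pooled-plasma PQC
wells in duplicate, and 39 patient samples in duplicate. Readings pass
through a forward 4PL response `y = d + (a−d)/(1+(x/c)^b)` with
multiplicative Gaussian noise of CV `noise_cv` (default 5%, a typical
within-plate immunoassay precision).

`run_qc()` then applies the acceptance hierarchy:

1. **Standard curves** are refit per plate/analyte by weighted least
   squares with 1/y² weighting (`fit_standard_curve()`, Levenberg–
   Marquardt, initialized at a = min response, d = max response, b = 1,
   c = concentration at the half-range response). A plate passes only if
   each Hill slope lies within its analyte's limits and weighted R² ≥ 0.95.
2. **PQCs** must fall inside pre-established concentration ranges (not
   published; the default is the central 99% interval implied by the pool
   concentration and the noise CV, configurable) with duplicate CV below
   the maximum.
3. **Samples** from accepted plates are retained when their duplicate CV
   (n−1 denominator: `100·|r₁−r₂|/(√2·mean)`) is at or below the
   analyte's maximum (20% across the panel); the retained concentration is
   the mean of the duplicate back-calculations.

Out-of-quantitation values are **clamped to the violated limit and
flagged**, not dropped — whether the original workflow dropped or clamped
is unstated, and clamping preserves cohort size while the flags let any
downstream stage exclude. Responses outside the invertible response range
(below blank or above saturation) cannot be back-calculated at all; those
measures are rejected as unquantifiable, which loses a small percentage of
subjects in the extreme concentration tails at the default noise level.

## Feature engineering

`pretreat()` builds the predictor matrix: optional log2 transform (always
before standardization), optional standardization whose mean/SD are
estimated **on the training rows only** and applied to all rows — the
leakage-safe reading of "strict" cross-validation — and age plus gender
(female = 0, male = 1) appended unstandardized. Whether demographics were
ever standardized in the original grid is unstated; we default to never,
with `standardize_demographics` available. `add_ratio_features()` adds one
predictor per unordered analyte pair (p(p−1)/2 = 351 for the full panel),
computed on the original scale and then pre-treated, so on the log2 scale
a ratio is exactly the difference of two log2 features. Unordered is the
default because a reciprocal is a monotone transform adding nothing to the
explored model families; an ordered mode exists behind a flag.

## Discovery: the classifier grid

`run_grid()` evaluates every combination of data type, pre-treatment,
predictor count, feature-selection method, and classifier family with its
hyperparameters. Seven rankers are implemented: elastic-net path entry
order (mixing parameter 0.5, 100-point path, ratio 1e−4 — the method is
named in the source methodology, the settings are ours), absolute Pearson
and Spearman correlation, information gain and gain ratio (equal-frequency
10-bin discretization of continuous features — the discretization is
unstated, 10 bins is the common default), and random-forest permutation
and impurity importance (seeded; 500 trees at full scale, 100 at desk
scale). Six classifier families sit behind one scoring interface:
logistic regression (IRLS via `glm`, with an automatic flagged small-ridge
refit on complete separation), elastic-net regression (glmnet), SVM
(e1071; inverse-prevalence class weights by default — an unweighted hinge
loss on a ~10% case class concentrates on the majority class and carries
little ranking signal), gradient boosting
(xgboost), random forest (ranger, probability forests), and k-nearest
neighbours.

Each grid cell is scored by **strict stratified 10-fold cross-validation**:
per fold, ranking and any standardization are fit on the training rows
only; the pooled hold-out scores of the ten folds give one AUC per
replicate, and the cell summary is the **median across replicates**.
Stratification is our choice (the methodology says only "strict"); it
protects the ~11% case prevalence in every fold. Fold partitions and
per-fold rankings are computed once and shared across the cells they feed,
with every random substream derived deterministically from the master seed
and the cell's own coordinates — so a single-cell `cross_validate()` run
reproduces the corresponding grid cell bit for bit (this equivalence is
tested).

`select_candidate()` applies the published filtering rule: keep cells at
or above the AUC floor (default 0.84, taken from the reported selection
narrative and treated as a configurable post-hoc filter, since whether it
was pre-specified is unclear), drop cells whose features involve excluded
assays (directly or inside a ratio — the reagent-availability exclusion
use-case), and among survivors pick the fewest protein-derived predictors,
breaking ties by higher summary AUC and then lexicographic cell id. The
winner is refit on all discovery rows.

### Grid scales

The `"desk"` preset is the package's working scale: all 7 rankers × all 6
families at one hyperparameter setting each × predictor counts {3, 10, 16}
× log2-unscaled features, 10-fold CV repeated twice, 100-tree forests —
126 cells, a single-digit-minute run on one CPU at n ≈ 3100. The `"full"`
preset spans predictor counts 2–29, ratio features, three pre-treatments
and denser hyperparameter lattices (tens of thousands of cells, hours of
compute); it exists for completeness and is not the default. Desk-scale
problem sizes are also what the package's tests and acceptance script use.

### Validating the discovery engine: the planted-model study

Since the real measurements are unavailable, the discovery engine is
validated by parameter recovery on synthetic data with a *known* answer.
`plant_logistic_labels()` replaces cohort labels with Bernoulli draws from
a known logistic model. The study condition fixed in the tests: eight
proteins (A1AG, CEA, CO9, DPPIV, MIF — negative, PKM2, SAA, TFRC; DPPIV
also negative) each contributing ≈0.7 standardized log-odds units, plus
age and gender at the same standardized strength, intercept solved so the
prevalence is 10.9%. The per-predictor strength was designed so that the
full 10-predictor generating model clears the 0.84 AUC floor comfortably
while 3-predictor submodels fall below it, reproducing the
fewest-proteins selection dynamic at desk scale: 3-predictor cells are
filtered out, 16-predictor cells survive but carry more proteins, and the
10-predictor cell wins. Recovery
is scored by feature-set Jaccard overlap with truth (≥ 0.6 required) and
Pearson correlation between refit and generating coefficients (≥ 0.9).

## The indeterminate score range

Some clinical tests decline to call a gray zone of scores.
`optimize_range()` searches **every contiguous window of k = round(f·n)
consecutive order statistics** of the discovery scores, for removal
fractions f ∈ {15, 20, 25}%: subjects above the window are called
positive, below negative, inside receive no call; sensitivity and
specificity are computed over called subjects only. The window returned
maximizes specificity among windows meeting the sensitivity floor
(≥ 0.80 by default; the narrative's "above 0.80" strict reading is
available via a flag), with ties broken by higher sensitivity, narrower
width, then smaller lower bound — a deterministic, fully enumerable rule
that the tests verify against independent brute-force enumeration.
Windows are defined on order-statistic positions, so tied scores can be
split by a window boundary; ties resolve by stable sort order. This is
documented behavior rather than a guess at the original intent, which the
text leaves unknowable. With f = 0 the search degenerates to the best
single threshold. The final locked fraction defaults to 25%.

One property worth flagging: forcing the window to remove *exactly*
round(f·n) samples is a constraint, not a free lunch. When the sensitivity
floor binds, every feasible window may be less specific than the best
unconstrained single threshold — removing a band at the operating point
also deletes true positives from the sensitivity numerator. This is why
the workflow explores several fractions and picks among them, rather than
assuming a gray zone always helps; what is guaranteed (and tested) is that
relaxing the floor never lowers the optimal specificity, and that the
optimizer is exactly equivalent to brute-force enumeration.

`apply_calls()` applies a locked range with no re-optimization — on a new
sample set the realized indeterminate rate will differ from f, exactly as
a locked clinical rule behaves.

## Locking and validation

`run_pipeline()` enforces the discover → lock → validate discipline: the
refit candidate and its indeterminate range are serialized (JSON with a
content fingerprint) before the validation stage runs, and validation
consists only of scoring the held-out subjects with the locked artifact.
The discovery and validation subject sets are disjoint by construction
(default split 3099/1336).

Validation statistics (`performance_summary()`):

* confusion counts over called subjects, sensitivity and specificity;
* AUC as the Mann–Whitney statistic with midrank half-credit for ties,
  with a DeLong placement-variance confidence interval (stratified
  bootstrap available); `delong_compare()` offers the paired correlated-ROC
  test and an unpaired z-test with summed variances for
  discovery-vs-validation comparisons (independent sample sets);
* the indeterminate rate with a Clopper–Pearson exact interval (the CI
  method is not named in the source; Clopper–Pearson and Wilson agree to
  the printed decimal on the published rate, so the default is robust);
* PPV and NPV from the Bayes identities at a stated prevalence
  (default 10.9%);
* stage-stratified sensitivity (I–II vs III–IV) with a two-sided Fisher's
  exact test on group × correctness (probability-mass convention — the
  `fisher.test` convention).

## Numerical choices and degenerate inputs

* 4PL fitting: Levenberg–Marquardt, ftol/ptol 1e−10, max 200 iterations;
  non-convergence is an error, never silently absorbed. Responses outside
  (min(a,d), max(a,d)) are unquantifiable by construction.
* Logistic separation: detected via the glm warning plus coefficient
  magnitude; the fallback is ridge at λ = 1e−3, flagged on the model.
* AUC with a single class present is an error; a confusion matrix with no
  called cases reports sensitivity as NA rather than 0.
* `optimize_range()` with no feasible window returns an explicit
  infeasible result (distinct from an error) so callers can try another
  fraction.
* Zero-margin 2×2 tables return Fisher p = 1 with a degenerate flag.
* All sampling operations are deterministic given their seeds; one master
  seed fans out to named substreams (cohort, split, panel, plates, folds,
  forests) so stages can be re-run independently.

## Known limitations

* The synthetic generator's independence default understates the real
  correlation among inflammation markers; classifier AUCs on synthetic
  cohorts are therefore not forecasts of clinical performance.
* The desk grid's single hyperparameter setting per family cannot rank
  families against each other fairly — it exists to exercise the
  machinery, and the full preset is the fair comparison.
* Locked-model JSON serialization carries coefficients only for the linear
  families; forest/boosting/kNN candidates lock as in-memory objects with
  a serialized recipe and fingerprint.
* The unpaired DeLong comparison assumes independent sample sets; for
  overlapping sets use the paired test.
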