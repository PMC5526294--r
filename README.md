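# seropanel

Discovery and validation of blood protein panel classifiers for
colorectal cancer (CRC) testing in symptomatic patients.

## The problem

Patients with symptoms of colorectal neoplasia — the intent-to-test (ITT)
population — carry a CRC prevalence near 10.9%, but colonoscopy compliance
is poor. A blood test that stratifies risk in this group can direct the
highest-risk patients to colonoscopy. Building such a test from multiplexed
immunoassay measurements of plasma proteins is a statistics problem with
many coupled stages, each easy to get subtly wrong: plate-level assay QC,
leakage-free cross-validated model search over thousands of
feature-selection × classifier combinations, selection of an indeterminate
(gray-zone) score range, and honest locked-model validation.

seropanel implements that whole workflow as composable, tested R functions,
together with a synthetic ITT cohort generator so every stage can be
exercised and validated without access to clinical data.

## The statistics at the core

* **Generator calibration.** Concentrations are class-conditional
  log-normal; a marker's class shift δ is set from a target univariate AUC
  by the binormal identity AUC = Φ(δ/(σ√2)), inverted exactly by
  `effect_size_for_auc()`.
* **Assay QC.** 4PL standard curves y = d + (a−d)/(1+(x/c)^b) fit by
  weighted least squares (1/y²); plates accepted on Hill-slope limits,
  weighted R² ≥ 0.95 and process-QC checks; samples accepted on duplicate
  CV = 100·|r₁−r₂|/(√2·mean) below per-analyte maxima; concentrations
  back-calculated by analytic inversion with LLoQ/ULoQ clamping and flags.
* **Discovery.** Grid search over data types, pre-treatments, predictor
  counts, seven feature rankers and six classifier families, each cell
  scored by stratified 10-fold CV (pooled-fold AUC per replicate, median
  across replicates); candidate filtering by AUC floor, assay exclusions,
  and fewest protein predictors.
* **Indeterminate range.** Exhaustive search over every contiguous window
  of k = round(f·n) consecutive score order statistics, maximizing
  specificity subject to sensitivity ≥ 0.80 among called subjects.
* **Validation.** Mann–Whitney AUC with DeLong variance and CI, paired and
  unpaired DeLong comparisons, Clopper–Pearson exact intervals, Fisher's
  exact test, prevalence-adjusted PPV/NPV, stage-stratified sensitivity.

## Worked example

A small end-to-end run (simulation → discovery → lock → validation):

```r
library(seropanel)

config <- run_config(
  n_discovery = 360, n_validation = 160,
  panel = panel_spec(analytes = c("CEA", "CO9", "MIF", "TFRC", "A1AG"),
                     target_auc = c(CEA = 0.80, CO9 = 0.78, MIF = 0.45,
                                    TFRC = 0.72, A1AG = 0.70), seed = 5),
  grid = grid_spec(predictor_counts = c(3, 5),
                   fs_methods = "linear_correlation",
                   classifiers = list(logistic = list(list())),
                   cv_folds = 5, cv_repeats = 2, seed = 5),
  auc_floor = 0.60, sens_floor = 0.70, final_fraction = 0.25,
  simulate_plate_qc = FALSE, seed = 5
)
res <- run_pipeline(config)
res$validation_summary
#> <performance_summary>
#>   called 116 of 160 (indeterminate rate 27.5%, 95% CI 20.7-35.1%)
#>   sensitivity 1.00  specificity 0.98
#>   AUC 0.96 (0.93-0.99)
#>   PPV 87.6%  NPV 100.0% at prevalence 10.9%
#>   stage association Fisher p = 1.000
```

Reading the output: of 160 held-out subjects, 44 scored inside the locked
gray zone and received no call; among called subjects the locked model was
perfectly sensitive and 98% specific (this toy panel's markers are much
stronger than real plasma proteins), and at the stated 10.9% pre-test
prevalence a positive call implies an 87.6% post-test CRC probability.
Each piece is also available directly:

```r
tidy(res$candidate)       # locked-model coefficients
#> # A tibble: 4 × 2
#>   term        estimate
#>   <chr>          <dbl>
#> 1 (Intercept)  -47.8
#> 2 CEA            1.01
#> 3 CO9            0.811
#> 4 TFRC           0.704
res$locked$range          # the locked indeterminate window
#> <indeterminate_range> [0.06245, 0.7822] removing 90/360 (25.0%): sens 0.714 spec 0.996
autoplot(res$validation_summary$roc)  # ggplot ROC curve
predictive_values(0.80, 0.83, 0.109)  # PPV 36.5%, NPV 97.1%
```

## Package layout

* `R/cohort.R` — synthetic ITT cohorts, AUC-calibrated concentrations,
  planted-model labels
* `R/plates.R`, `R/qc.R` — plate simulation, 4PL curves, acceptance rules
* `R/features.R` — pre-treatments and ratio features
* `R/discovery.R`, `R/grid.R` — rankers, classifiers, CV engine, grid,
  candidate selection
* `R/indeterminate.R` — gray-zone window optimization and three-way calls
* `R/evaluation.R` — ROC/AUC, DeLong, exact intervals, Fisher, PPV/NPV,
  stage tables
* `R/pipeline.R` — `run_config()`, `run_pipeline()`, `write_report()`
* `vignettes/panel-classifier-methods.Rmd` — the full methods account
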