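# strabnet

Prescriptive planning for horizontal strabismus surgery: from fourteen
routine pre-operative measurements, a single multi-task neural network
jointly predicts **which** of the eight horizontal muscle–procedure options
(recession or resection of the medial or lateral rectus, per eye) should be
performed and the recession/resection **dose** in millimetres for each.
The package is aimed at clinical-prediction methodologists and
ophthalmology researchers who want a fully tested, reproducible
implementation of this planning pipeline — including a synthetic cohort
simulator calibrated to published baseline statistics of a 634-patient
surgical cohort, so every stage runs and is testable without access to
patient data.

## The model

A shared trunk (input → 109 → 35 units; batch normalisation, ReLU,
dropout 0.20; Xavier-uniform initialisation) feeds two heads:

* a **selection head** with eight sigmoid outputs, one per label in the
  fixed order `rmr_recess, rmr_resect, rlr_recess, rlr_resect, lmr_recess,
  lmr_resect, llr_recess, llr_resect`;
* a **dose head** with eight linear outputs, trained on a standardised
  dose scale and clipped to 0–10 mm at prediction.

Training minimises a class-balanced binary cross-entropy (positive class
of label *j* weighted by (n − nⱼ)/nⱼ, capped) plus λ·(dose error), with
Adam, decoupled weight decay, global gradient clipping at 1.0 and early
stopping. Internal validation is multilabel-stratified 10-fold
cross-validation whose prevalence certificate is guaranteed within ±2
percentage points for every (fold, label) cell; probabilities are
temperature-scaled then β-calibrated, per-label decision thresholds
maximise the MCC, and infeasible recess+resect combinations are resolved
in favour of the higher-probability label. Reports cover discrimination
(AUC/F1/MCC/exact-match), calibration (decile ECE, slope, reliability
table), dose accuracy (MAE/RMSE/R², Bland–Altman), tiered plan agreement,
decision-curve net benefit, subgroup fairness and permutation feature
importance, with patient-level bootstrap confidence intervals.

See `vignettes/strabnet-methods.Rmd` for the full methods account,
including what the simulator does and does not emulate.

## Worked example

```r
library(strabnet)

cohort <- simulate_cohort(generator_config(n_patients = 634, seed = 11))
cv     <- run_cv(cohort, config = model_config(), k = 10, seed = 11)
report <- evaluate_cv(cv, cohort)
report
#> <strabnet_report> 634 patients, 10 folds, 7112 model parameters
#>   selection : macro-AUC 0.991 | macro-F1 0.976 | macro-MCC 0.967 | exact match 90.4% (baseline 13.6%)
#>   calibration: ECE 0.0065 (raw 0.0082) | slope 0.59
#>   dose       : MAE 0.438 mm (operated) / 0.186 mm (all) | RMSE 0.631 | R2 0.764 | within 0.30 mm: 46.8%
#>   agreement  : tier-1 50.6% | tier-2 25.4% | acceptable 76.0%
```

Reading the output: the selection head separates operated from unoperated
muscles almost perfectly (pooled out-of-fold macro-AUC 0.991, against the
0.90 "excellent" benchmark); 90.4% of patients get their entire 8-bit plan
vector reproduced exactly, against a 13.6% majority baseline. After
calibration the predicted probabilities track observed frequencies to an
expected calibration error of 0.0065 (the 0.05 bar is the usual clinical
reliability bound). On truly operated muscles the dose head is accurate to
0.438 mm on average — under the 0.5 mm step surgeons plan in — and 76% of
whole plans are clinically acceptable (exact, or one dose off by at most
1 mm). `autoplot(report)` draws the reliability diagram,
`autoplot(report, type = "decision_curve")` the net-benefit curves, and
`tidy(report)` returns the per-label metric table.

`run_pipeline("run/", seed = 1)` performs the same end to end and writes a
reproducible run directory (config snapshots, seed manifest, cohort CSV,
fold indices, metrics JSON, markdown report). A small command-line wrapper
is installed at `inst/cli/strabnet-cli.R` with `simulate`, `run` and
`demo` subcommands.

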