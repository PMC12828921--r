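---
title: "Methods: simulating and learning horizontal strabismus surgery plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and learning horizontal strabismus surgery plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

strabnet is a prescriptive planning pipeline for horizontal strabismus
surgery. From fourteen routine pre-operative measurements it predicts
*which* of the eight horizontal muscle-procedure options (recession or
resection of the medial or lateral rectus, per eye) should be performed,
and the recession/resection *dose* in millimetres for each. This vignette
is the package's own account of the model, the synthetic cohort that stands
in for patient data, the numerical choices, and the limits of what the test
suite demonstrates.

## The prediction problem

Each patient is a record $x$ of: age; deviating eye (OD/OS); prism-cover
deviation angle (prism dioptres, signed so that exotropia is positive);
per-eye axial length (from which the mean and signed inter-ocular
difference are derived); per-eye spherical equivalent (mean and
difference); per-eye best-corrected visual acuity (logMAR); and a binary
equal-vision flag. The target is a pair $(y, d)$: an 8-bit label vector
over the fixed order `r paste(strabnet::plan_labels(), collapse = ", ")`
and an 8-vector of doses in mm, 0 for unoperated muscles. Consecutive
label pairs address the same muscle, and a muscle is never simultaneously
recessed and resected.

## The multi-task network

The model is a fully connected trunk shared by two heads:

* trunk: input $\to$ 109 $\to$ 35 units, each layer linear + batch
  normalisation + ReLU + dropout (rate 0.20), weights initialised
  Xavier-uniform, biases zero;
* classification head: 8 sigmoid outputs (per-label probability);
* regression head: 8 linear outputs on a per-output standardised dose
  scale, mapped back to mm and clipped to 0--10 at prediction time.

The loss is a class-balanced binary cross-entropy (positive class of label
$j$ weighted by $(n - n_j)/n_j$, capped at 20) plus $\lambda$ times the
dose term. By default the dose term is computed on operated slots only
(`mask_unoperated = TRUE`): regressing the five to seven unoperated slots
of every patient toward 0 mm teaches the head mostly to predict zeros and
attenuates the operated-dose signal; the masked form evaluates the head
where a dose is actually defined. Squared error is the default; a Huber
option exists for robustness experiments. $\lambda$ defaults to 40 on the
standardised scale, which balances the two heads' *progress* (the
selection task saturates long before the dose task).

Optimisation is Adam with decoupled weight decay ($10^{-4}$), global
gradient-norm clipping at 1.0, and early stopping on a held-out inner
split. Three stabilisers matter at this sample size (hundreds of
patients):

* full-batch updates (`batch_size = 512`, i.e. one batch per epoch here)
  with learning rate $10^{-2}$, up to 4000 epochs, patience 200 --- at
  mini-batch settings the dose head reliably under-converges;
* the validation loss is smoothed by a 5-epoch trailing average before
  early-stopping decisions, damping small-validation-set noise;
* the parameters that are validated and returned are an exponential
  moving average (decay 0.98) of the training trajectory.

Batch-norm inference uses frozen running statistics and dropout is
disabled, so inference is deterministic. The parameter count is reported
by `strabnet_n_params()` and in every fit summary; with the default
feature set it is `r strabnet::strabnet_n_params(strabnet::model_config())`.
`random_search()` tunes trunk widths, dropout, learning rate and batch
size by seeded random search over inner folds when a user wants to re-tune
rather than use these defaults.

## Features

The ten standardised predictors are augmented by configured expansions of
the deviation measurement: its magnitude `abs_deviation`, its direction
`is_exotropia`, and surgical-table bin indicators `dev_gt_k`
($k = 10, 15, \dots, 50$ prism dioptres). Published dosing tables are laid
out on a 5-dioptre grid, and dose-per-muscle changes slope whenever the
plan adds a muscle; a small fully connected network cannot carve those
thresholds out of a single smooth input at this sample size, while the
binned basis makes them linearly accessible. All features, including the
binary ones, are winsorised at the training fold's 1st/99th percentiles
(linear-interpolation percentile definition) and z-scored with
training-fold statistics; a constant column falls back to SD 1 with a
warning. The pipeline is complete-case: missing values raise an error
rather than being imputed.

## The synthetic cohort

No patient-level data are available, so `simulate_cohort()` generates
cohorts whose marginals match the published baseline table of a
634-patient surgical cohort:

* exotropia fraction 0.532; absolute deviation Normal(31, 11) in
  exotropes and Normal(24, 9) in esotropes, truncated to (0, 140],
  giving an overall mean of about 28 prism dioptres;
* age log-normal with median 15 y (`meanlog = log 15`, `sdlog = 0.55`,
  which reproduces the published IQR 11--23, mean 17.3 and SD 10.6 almost
  exactly), truncated to 2--65 y;
* mean axial length Normal(24.1, 1.3) / Normal(23.9, 1.1) mm by type,
  inter-ocular difference Normal(0, 0.3) mm, per-eye values kept inside
  18--32 mm; spherical equivalent Normal(-1.4, 2.3) / Normal(-1.2, 2.5) D;
* per-eye acuity `max(0, Normal(-0.03, 0.18))` logMAR (clustering at
  0.00 with upper quartile near 0.10), an amblyopic deficit
  Uniform(0.2, 0.8) added to the deviating eye with probability 0.35, and
  the equal-vision flag set when the eyes differ by at most 0.1 logMAR.

Out-of-range draws are rejected and redrawn rather than clipped, so the
bounds carry no probability spikes.

### The expert planning rule

The study's surgeons' decision rules are not published, so plans are
assigned by a deterministic rule mirroring standard practice:

* $|\mathrm{dev}| \le 15$: single-muscle recession of the primary muscle
  (lateral rectus for exotropia, medial rectus for esotropia) on the
  deviating eye;
* $15 < |\mathrm{dev}| \le 34$: two muscles --- bilateral recession when
  vision is equal, recess--resect on the deviating eye when it is not
  (operating the amblyopic eye preferentially);
* $|\mathrm{dev}| > 34$: three muscles --- bilateral recession plus
  resection of the deviating eye's antagonist.

Doses follow the classical nomogram, 1 mm per 2 prism dioptres, shared
equally across operated muscles:
$\mathrm{dose} = |\mathrm{dev}| / (2 n_\mathrm{muscles}) + \varepsilon$,
$\varepsilon \sim N(0, 0.3\ \mathrm{mm})$, clipped to 0.5--10 mm. The tier
cut points (15/34 rather than a single cut near 25) were chosen so that
the simulated recession doses cluster in the 6--7 mm histogram bin, as the
source cohort's dose distribution does, and so that all eight labels keep
prevalence well above 5%; a single higher cut produces a pile-up of
clipped 10 mm doses that no published cohort shows. One known mismatch:
because the nomogram shares the correction equally, simulated resection
doses peak in the same 6--7 mm bin rather than slightly higher, as the
source reports.

### Label noise

Expert plans are not perfectly reproducible, so each *active* label is
dropped with probability `label_flip_rate` (default 0.02), and its dose
re-zeroed -- a surgeon occasionally omitting a marginal procedure. Noise is
deactivation-only by design: switching a label *on* would either violate
the dose--label consistency invariant (an operated muscle with dose 0) or
inject full-magnitude dose noise on unpredictable slots, which would put
the operated-dose error floor above the 0.5 mm clinical acceptability
bound no matter the model. With deactivation-only noise the Bayes floor of
the operated-dose MAE is the nomogram noise,
$E|\varepsilon| \approx 0.24$ mm, leaving the stated acceptability bound
achievable by a good model and failable by a bad one. The selection task
keeps a genuine noise ceiling (a fraction of positives are missing), so
perfect discrimination remains unattainable.

### What the simulator does not emulate

Real cohorts carry measurement error in the prism-cover test, A/V
patterns, vertical components, re-operations, correlated comorbidities,
site effects, and surgeon-to-surgeon systematic differences -- none of
which are modelled. Passing the pipeline's acceptance thresholds on this
generative model demonstrates that the machinery (stratification,
leakage-free preprocessing, training, calibration, thresholding,
evaluation) works and that the architecture can learn plan structure at
this sample size; it does not predict performance on real patients.

## Internal validation

`run_cv()` performs multilabel-stratified 10-fold cross-validation. The
splitter implements iterative stratification (rarest label first, fold
capacities fixed so sizes differ by at most one), followed by a local
swap search that directly minimises the certificate --- the maximum over
all (fold, label) cells of the absolute difference between fold and
overall prevalence --- and retries with derived sub-seeds until the
certificate is within the +/-2 percentage-point tolerance. The certificate
is recomputable from the emitted fold indices alone and is stored with
every split.

Within each training fold, a 1/5 multilabel-stratified inner split is held
out; the network trains on the remaining 4/5 with early stopping on the
inner split, and the inner split's out-of-sample predictions are then used
to fit probability calibration and decision thresholds. The outer
validation fold touches nothing: preprocessing statistics, calibration
parameters and thresholds all derive from training rows only, and the
per-fold artefacts record the row provenance so the tests can verify it.
One model per fold keeps the full run under two minutes on
one CPU; a nested ensemble across inner folds was evaluated and did not
improve held-out dose error.

Calibration is temperature scaling (1-D NLL minimisation on [0.05, 20])
followed by beta calibration
$m(p) = \sigma(c + a \ln p - b \ln(1-p))$, fitted per label by logistic
regression with $a, b \ge 0$ enforced by refitting without an offending
feature; labels with fewer than 20 inner-split positives share a pooled
calibration. Both maps are monotone, so discrimination is untouched.
Decision thresholds maximise the Matthews correlation coefficient per
label over midpoints of consecutive sorted probabilities, ties broken
toward the higher threshold; infeasible recess+resect combinations are
resolved in favour of the higher-probability label (an exact tie keeps the
recession, the clinically conservative weakening procedure), and a
selected muscle whose predicted dose falls below 0.5 mm is floored there
and flagged.

Uncertainty is quantified by a patient-level percentile bootstrap
(default B = 1000), resampling whole patients to preserve the within-patient
correlation of the eight outputs.

## Evaluation conventions

* Discrimination: Mann-Whitney AUC (midrank ties), F1 and MCC from
  thresholded decisions, exact-match of the full 8-bit vector against the
  majority baseline (modal reference vector frequency).
* Calibration: equal-count decile ECE (reported before and after
  calibration) and the logistic calibration slope.
* Dose accuracy: MAE/RMSE/$R^2$/fraction-within-0.30 mm, reported both
  over all eight outputs (final plan doses, zeros included) and over
  operated muscles only (regression-head output against the reference
  dose); the operated-only view is the clinically interpretable one and
  the one the 0.5 mm acceptability bound refers to. Bland-Altman bias and
  1.96-SD limits of agreement accompany it.
* Plan agreement: tier 1 = identical decisions and all operated doses
  within the 0.5 mm planning quantum; tier 2 = identical decisions with
  exactly one dose off by more than the quantum but at most 1 mm;
  tier 1 + tier 2 is the "clinically acceptable" rate.
* Clinical utility: decision-curve net benefit
  $TP/n - (FP/n)\,p_t/(1-p_t)$ against treat-all and treat-none.
* Fairness: all metrics recomputed within exotropes and esotropes with
  the absolute gap.
* Attribution: permutation importance (macro-AUC or operated-dose MAE
  degradation), a model-agnostic substitute for SHAP-style attributions.

## Reference workload

The packaged end-to-end profile mirrors the source study's design:
n = 634 patients, 10 outer folds, bootstrap B = 1000. The test-suite and
demonstration profiles use smaller cohorts (60--400 patients, 2--5 folds,
B of tens) chosen to exercise every code path quickly; all sizes are
configurable.

## Known limitations

* The planning rule is invented (the source's surgeon decision process is
  unpublished); only marginal plausibility of the label and dose
  distributions is targeted.
* Resection doses peak one bin lower than the source reports (equal dose
  sharing; see above).
* The calibration slope is unstable when predictions are nearly separated
  (probabilities piled at 0 and 1), which routinely happens on this
  generative model; ECE is the primary calibration summary.
* Dose predictions for unoperated slots are unconstrained under the
  default masked dose loss; they are always gated to 0 by the decision
  head in emitted plans.
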