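# elmgrade

Predicting conversion from mild cognitive impairment (MCI) to Alzheimer's
disease (AD) by **kernel extreme learning machine (ELM) grading** of
multimodal biomarkers.

## The problem and the idea

Identifying which MCI patients will progress to AD within a few years
(pMCI) and which will remain stable (sMCI) is a central prognostic task in
AD research, and it is hard: the baseline differences between the two
groups are subtle. The AD-vs-normal-control (NC) contrast, by comparison,
is strong and easy to learn.

`elmgrade` exploits that asymmetry. For each biomarker modality — MRI
morphometry, FDG-PET regional metabolism, and a biological block combining
CSF proteins (Abeta42, t-tau, p-tau) with APOE ε4 carrier status — a
two-class kernel ELM is trained on the AD/NC reference subjects and then
applied to every MCI subject. With the Gaussian kernel
`K(u, v) = exp(-||u - v||² / γ)` and label matrix `Y` (+1 in the
true-class channel, −1 in the other), the ELM output is the closed form

```
f(x) = [K(x, x₁) … K(x, x_N)] (Ω + I/C)⁻¹ Y,      Ω_ij = K(x_i, x_j)
```

and the **grading score** `s = s₁ − s₂` (AD channel minus NC channel) is a
continuous AD-similarity for that modality. Each modality collapses to one
score, so the fused representation of an MCI subject is a short vector
(`K = 3` by default) in which no wide block can drown the others — the
weakness of direct feature concatenation. A final kernel ELM classifies
the fused scores into pMCI vs sMCI, evaluated by repeated stratified
10-fold cross-validation (ACC, SEN, SPE, BACC = (SEN+SPE)/2, AUC).

The high-dimensional MRI block is first screened on AD/NC with a LASSO
(`min_a 0.5‖y − Da‖² + λ‖a‖₁`, coordinate descent in compiled code);
features are z-scored using AD/NC means and SDs only. Defaults follow the
reference design: `C = 1`, `γ = 10·M` (M = current feature count),
`λ = 0.015` (per-sample scale), 36-month conversion horizon.

Because the real cohorts in this field are access-restricted, the package
includes a first-class synthetic cohort generator
(`preset_adnilike()` / `generate_cohort()`) reproducing the reference
cohort structure — 200 NC / 102 AD / 110 pMCI / 205 sMCI subjects with
313 MRI / 20 PET / 3 CSF / 1 APOE features, conversion times, late
converters and diagnostic reverters — so every stage is runnable and
testable end to end. See the methods vignette
(`vignettes/elm-grading.Rmd`) for the model, design decisions and
generator calibration.

## Worked example

```r
library(elmgrade)

cohort <- generate_cohort(preset_adnilike(seed = 1))
cohort
#> <cohort_table> 617 subjects (AD=102, NC=200, MCI=315)
#>    MRI        313 features
#>    FDG-PET    20 features
#>    CSF        3 features
#>    APOE       1 features

fit <- elm_grading(cohort)          # normalise, LASSO, grade, fuse
fit
#> <elm_grading> 315 MCI subjects (pMCI=110, sMCI=205) at horizon 36 months
#>    MRI        150 features (LASSO-selected from 313)
#>    FDG-PET    20 features
#>    Bio        4 features
#>   fused score matrix: 315 x 3 [MRI, FDG-PET, Bio]

cv_evaluate(fit, runs = 100, seed = 1)
#> <cv_summary> 100 x 10-fold CV (positive class: pMCI, seed 1)
#>   ACC   83.0 +/- 0.3 %
#>   SEN   69.6 +/- 0.6 %
#>   SPE   90.2 +/- 0.3 %
#>   BACC  79.9 +/- 0.4 %
#>   AUC   90.1 +/- 0.1 %

direct_concat_baseline(cohort, runs = 100, seed = 1)
#> <cv_summary> 100 x 10-fold CV (positive class: pMCI, seed 1)
#>   ACC   74.7 +/- 0.7 %
#>   SEN   33.1 +/- 1.9 %
#>   SPE   97.0 +/- 0.5 %
#>   BACC  65.0 +/- 1.0 %
#>   AUC   86.9 +/- 0.5 %
```

Reading the output: the grading pipeline turns 337 raw columns into 3
scores and reaches a balanced accuracy of ~80% with a sensible
sensitivity/specificity trade-off under the 110/205 class imbalance. The
direct-concatenation baseline — same normalisation, same LASSO, same CV
folds, but one wide 174-column matrix instead of grading — keeps high
specificity while its sensitivity collapses to ~33%: the informative CSF
and APOE columns are swamped by the MRI block, precisely the bias that
per-modality grading removes. Mean ± SD are over the 100 CV repetitions.

Labelling at other horizons (`assign_horizon_labels(cohort, 24)`), the
strict sMCI definition (`strict = TRUE`), extra covariates appended to the
score matrix, and single-modality evaluation
(`repeated_kfold(fit$scores[, "MRI", drop = FALSE], fit$labels)`) are all
one-liners; a thin command-line wrapper with `simulate` / `grade` /
`evaluate` subcommands is in `inst/cli/elmgrade.R`.

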