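---
title: "Multimodal kernel-ELM grading for MCI-to-AD conversion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal kernel-ELM grading for MCI-to-AD conversion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The prognostic problem

Mild cognitive impairment (MCI) is the prodromal stage of Alzheimer's
disease (AD), but only part of the MCI population converts: *progressive*
MCI (pMCI) subjects receive an AD diagnosis within some horizon (36 months
by convention here), *stable* MCI (sMCI) subjects do not. Discriminating
pMCI from sMCI at baseline is much harder than separating AD from
cognitively normal controls (NC), because the group differences are small.

`elmgrade` implements a fusion strategy for this task built on a simple
observation: the AD-vs-NC contrast is strong and easy to learn, so a
classifier trained on AD/NC can be reused as a *grader* that places each
MCI subject on a continuous AD–NC axis, one modality at a time. Four
biomarker modalities are supported out of the box:

* **MRI** — FreeSurfer-style morphometry (volumes, surface areas, cortical
  thickness; 313 columns in the reference layout), reduced by LASSO;
* **FDG-PET** — summary statistics of regional glucose metabolism
  (20 columns);
* **CSF** — Abeta42, total tau and phosphorylated tau concentrations;
* **APOE** — epsilon-4 carrier status, coded 0/1 and treated as a numeric
  feature; CSF and APOE are merged into one biological modality.

Each modality yields a single grading score per MCI subject; the
`N x 3` score matrix is the fused representation on which the final
pMCI/sMCI classifier runs. Grading each modality into one number before
fusion prevents the widest block (MRI) from dominating the representation,
which is exactly the failure mode of the direct-concatenation baseline
shipped as `direct_concat_baseline()`.

## Model

### Kernel extreme learning machine

All supervised steps use a two-class kernel extreme learning machine
(`kelm()`). With training samples `x_1 … x_N` and the `N x 2` label matrix
`Y` (`+1` in the true-class channel, `-1` in the other), the model output
for a query `x` is

    f(x) = [K(x, x_1), …, K(x, x_N)] (Omega + I/C)^{-1} Y,

where `Omega_ij = K(x_i, x_j)` and `K(u, v) = exp(-||u - v||^2 / gamma)`.
There are no random hidden weights in the kernel variant: training is one
deterministic symmetric positive-definite solve, and each output channel is
exactly kernel ridge regression with ridge parameter `1/C` on that
channel's ±1 coding (a property the test suite checks against an
independent implementation). Classification compares the two channels
(`s1 > s2`); grading uses the continuous difference

    s = s1 - s2,

which is positive when the subject resembles the positive class. For the
per-modality graders the positive class is AD, so `s` is an AD-similarity
score; for the final classifier it is pMCI.

### Feature selection for MRI

Whole-brain morphometry contains many aging-related but AD-irrelevant
features. The MRI block is therefore screened on the AD/NC reference with
an L1-penalised least-squares fit,

    min_a 0.5 ||y - D a||^2 + lambda ||a||_1,

solved by cyclic coordinate descent (compiled code, residual-update form);
features with non-zero coefficients are kept. The response coding is
AD = +1, NC = -1; features are z-scored on AD/NC beforehand, so no
intercept is fitted. The solver follows the objective exactly as written.
Because widely used solvers instead scale the quadratic term by `1/(2N)`,
`lasso_fit()` exposes `lambda_scale = "per_sample"` which multiplies the
penalty by `N`. The **pipeline** defaults to the per-sample convention with
`lambda = 0.015`: at `N ≈ 300`, the literal reading of that penalty almost
never thresholds a coefficient (the fit degenerates to a dense,
ill-conditioned least-squares solution and selection is vacuous), whereas
the per-sample reading produces the sparse, AD-focused selection the
method intends — with `~300` AD/NC subjects it retains roughly half of the
313 MRI features. Users who want the literal objective can pass
`lambda_scale = "literal"` anywhere.

### Pipeline structure and leakage

`elm_grading()` performs, in order:

1. horizon labelling of the MCI rows (`assign_horizon_labels()`);
2. per-modality z-scoring with mean/SD **fitted on AD ∪ NC only** and
   applied unchanged to the MCI rows, so MCI subjects are expressed on the
   reference scale;
3. LASSO selection on the AD/NC MRI block, with the same column subset
   applied to the MCI block;
4. one grading ELM per modality, trained on the full AD/NC reference;
5. score fusion into the `N_MCI x K` matrix.

The graders are fitted once, outside the cross-validation loop. This is
deliberate and is not leakage: the AD/NC reference subjects are disjoint
from the MCI evaluation set, and no MCI outcome label is visible to any
grading-stage computation (a structural test asserts that scrambling the
conversion times leaves every score bit-identical).

Optional extra covariates (e.g. neuropsychological test scores) can be
appended to the score matrix; they are z-scored with the MCI cohort's own
statistics, since the AD/NC distribution of such covariates is irrelevant
to the classifier's input scale. This is an interpretation — the reference
design does not state a convention.

### Evaluation

`repeated_kfold()` runs `runs` × stratified `k`-fold cross-validation of a
kernel-ELM classifier on the score matrix. Per run, out-of-fold predictions
and grading scores are pooled across the k folds; ACC, SEN (pMCI recall),
SPE (sMCI recall), BACC = (SEN+SPE)/2 and the Mann–Whitney AUC of the
pooled grading scores give one row per run, summarised as mean ± SD
(divisor `n − 1`) over runs.

Two conventions are documented decisions, since the reference design says
only "randomly":

* **Stratified folds.** With a 110/205 class imbalance, unstratified folds
  occasionally produce single-class training sets; stratification removes
  that failure mode while preserving the random-permutation spirit. If a
  training fold still lacks a class (tiny cohorts), the permutation is
  redrawn with a logged message.
* **AUC pooling.** AUC is computed per run on that run's pooled
  out-of-fold scores, then averaged over runs.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `C` | 1 | ELM regularisation; each channel is kernel ridge with ridge `1/C`. |
| `gamma` | `10 * M` | Gaussian kernel width, tied to the current feature count `M`: recomputed after LASSO for MRI, and equal to `10 * K` for the final classifier on `K` score columns. |
| `lambda` | 0.015 | LASSO penalty (per-sample scale in the pipeline; see above). |
| `horizon` | 36 months | Conversion window defining pMCI. |
| `strict` | `FALSE` | Strict sMCI definition: late converters and reverters are excluded instead of counted stable. |
| `k`, `runs` | 10, 100 | Cross-validation geometry. |
| `seed` | — | Master seed; run `r` uses a derived per-run stream. |

Numerical choices: population SD (divisor `N`) everywhere, fixed for
reproducibility; constant features are an error, not silently dropped.
Kernel systems are solved by Cholesky factorisation (never an explicit
inverse); a `1e-10` jitter is added only if factorisation fails, with a
warning. Coordinate descent stops when the largest coefficient change in a
sweep is below `1e-6` (at most 10,000 sweeps; non-convergence warns and is
flagged in the result). Coefficients with `|a| <= 1e-8` count as zero for
selection. An exact classifier tie `s1 = s2` goes to the negative
(reference) class — the reference design leaves ties undefined, so the
package fixes a convention and documents it.

## The synthetic cohort generator

Real multimodal AD cohorts are access-restricted, so `generate_cohort()`
draws fully synthetic ones that reproduce the *structure* of the reference
cohort: group sizes 200 NC / 102 AD / 110 pMCI / 205 sMCI and block widths
313 / 20 / 3 / 1 (`preset_adnilike()`). Continuous blocks are
group-conditional equicorrelated Gaussians: informative features carry a
standardised AD-vs-NC mean difference (`effect`), all features within a
block share an equicorrelation `rho` through a common per-subject factor,
so nuisance features are mutually correlated and feature selection is
stressed realistically. MCI groups sit between the poles: pMCI informative
means are `mci_mixing` times the AD mean, sMCI means `mci_mixing` times
the NC mean. APOE is Bernoulli per group (carrier rates 0.65 / 0.25 /
0.60 / 0.35 for AD / NC / pMCI / sMCI). Conversion times for the
progressive group follow a truncated exponential (mean 20 months, capped
at 36), which makes the pMCI count grow smoothly with the labelling
horizon; a small fraction of the stable group converts after 36 months
(8%) or reverts to normal (22%), supplying the subjects that the strict
sMCI definition excludes.

**Calibration of the preset.** The default effect sizes (MRI 0.5 per
informative feature, 30 of 313; FDG-PET 0.75, 8 of 20; CSF 1.1, 3 of 3;
`rho = 0.2`, `mci_mixing = 0.6`) were set so that the preset's operating
point matches the reported single-modality and fused performance levels of
the task this package targets: single-modality balanced accuracies in the
high 60s / low 70s and fused balanced accuracy around 80%, with the fused
representation clearly ahead of both every single modality and the
direct-concatenation baseline. A first-principles `d'` calculation is a
poor guide here because equicorrelated nuisance noise is partially
removable by the learned discriminant, so the calibration was done against
the pipeline itself and then frozen.

What the generator does **not** emulate: realistic neuroanatomical
covariance (beyond equicorrelation), heavy-tailed or skewed marginals,
site/batch effects, measurement error differences between modalities,
informative missingness (cohorts are complete by construction), and
longitudinal visit schedules. Tests passing on synthetic cohorts therefore
demonstrate the correctness and the qualitative behaviour of the
machinery — score fusion beating single modalities and naive
concatenation, null calibration at the class prior, signal recovery with
growing effect size — not clinical performance on real data.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run everything at the preset's
natural size (617 subjects, 315 MCI) but with reduced repetition counts
chosen as a sensible compromise for routine execution: property checks use
2–3 CV repetitions per seed across 5–10 generator seeds, while the
acceptance script uses the full 100 repetitions for the fused pipeline and
the concatenation baseline and 20 for the per-modality columns. The
statistics of interest are means over repetitions, whose simulation error
at these sizes is well inside the margins being asserted.

## Known limitations

* Two classes only; no multi-way AD/MCI/NC classification.
* APOE is carrier presence 0/1; allele dosage (0/1/2) is not modelled.
* Stable subjects with follow-up shorter than the horizon are kept as
  sMCI (their ids are flagged in an attribute) — censoring is not
  modelled, matching the reference design's non-strict labelling.
* The penalty `lambda` is fixed, not cross-validated; the package exposes
  `lambda_max()` for users who want to place it on the path themselves.
* Grading scores are reused across CV repetitions by design (see the
  leakage discussion above); consequently the CV SD reflects fold
  assignment variability only, not grader refitting variability.
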