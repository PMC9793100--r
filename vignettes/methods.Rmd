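---
title: "Joint modelling of adverse pregnancy outcomes, stress, and immune features: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of adverse pregnancy outcomes, stress, and immune features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregstress)
```

## The problem

Adverse pregnancy outcomes (APOs) — gestational diabetes, severe
preeclampsia, preeclampsia superimposed on chronic hypertension, and early
gestational age (GA) at delivery — are individually rare, clinically severe,
and strongly interrelated, both with each other and with pre-pregnancy risk
factors (RFs: chronic hypertension, diabetes, high BMI). Psychosocial and
stress-related factors (PSFs), captured cheaply by questionnaire in the
first trimester, are epidemiologically linked to these outcomes, and the
maternal immune system is a plausible mediating layer.

`pregstress` implements a three-stage modelling pipeline over these data:

1. **Model 1** — a multitask neural network jointly predicting the seven
   APORFs (five binary, two numeric: GA at delivery and pre-pregnancy BMI)
   from the PSFs, compared against architecturally identical single-task
   networks under repeated stratified 5-fold cross-validation.
2. **Model 2** — an independent ridge regression per immune feature,
   predicting 534 single-cell immune characteristics from the 79 PSFs plus a
   timepoint code, under shuffled grouped 10-fold cross-validation repeated
   50 times, with Benjamini–Hochberg (BH) control across features.
3. **Model 3** — the per-fit ridge coefficients averaged into one linear
   generator, used to impute immune features for the patients without immune
   measurements; the imputed features then feed the Model 1 architecture to
   predict the APORFs again.

Around these sit the questionnaire preprocessing chain, the APORF
correlation network, the PSF correlation-profile clustering, and a synthetic
cohort generator that reproduces the statistical structure every stage
assumes.

## The synthetic cohort generator

The real questionnaire instrument is copyrighted and the cohort is not
publicly distributable, so the generator is a first-class, tested component
— it defines the conditions under which everything else is validated.

**Outcomes.** Binary outcome labels come from a latent liability threshold
model: a 7-dimensional Gaussian with configurable correlation matrix
(`default_outcome_corr()`) supplies one liability per APORF; each binary
label is the indicator of the top-$k$ liabilities, where $k$ is the
configured case count, so per-outcome counts are exact by construction. The
defaults reproduce the study composition: 200 patients with 18 hypertension,
11 diabetes, 29 gestational diabetes, 6 superimposed preeclampsia, 13 severe
preeclampsia and 17 preterm cases. The count of *distinct* affected
patients (default 52) is then enforced by greedy minimal label swaps among
patients nearest the thresholds; swaps of the GA-derived preterm label
exchange the two patients' GA values so labels and GA stay consistent. GA at
delivery is an exact monotone piecewise-linear map of its liability (top-17
liabilities into [24, 37), the rest into [37, 42] weeks); BMI is linear in
its liability. Binary-label thresholding attenuates correlations heavily at
these prevalences, which is why the default latent correlations are high
(0.75–0.8 inside the hypertensive/metabolic cluster); the observed Spearman
network on generated data then lands near the intended "about half of edges
moderate or strong".

**Stressors.** 79 PSFs in 15 correlated blocks (one shared Gaussian factor
per block, within-block latent correlation 0.6 by default), partially
discretized in a fixed cycle — 8-point ordinal, yes/no binary, continuous
score — with 5% completely-at-random missingness to exercise the
pairwise-complete correlation paths. Outcome liabilities receive a
PSF-driven component: configurable loadings put a few blocks behind each
outcome, scaled so those outcomes draw 30% of their liability variance from
the PSFs — a moderate, realistic effect size for psychosocial predictors.
When the loadings are nonzero the *realized* latent outcome correlation is a
mixture of the configured matrix and the correlation induced by shared PSF
effects; null-calibration checks therefore use a zero effect matrix.

**GA at questionnaire.** Log-normal with median 11 weeks and log-scale sd
0.3, truncated to [5, 25] weeks. This reproduces both stated properties of
the enrollment window: the median of 11 weeks, and over 95% of
questionnaires completed before 21 weeks (the configuration gives ~98%).

**Immune panel.** A seeded subset of patients (default 14), each with 4
timepoint rows. The first `n_true_signal_features` feature columns are
linear in the cohort-standardized PSFs (sparse planted coefficients, 5
active PSFs each) plus a per-timepoint offset, with Gaussian noise; the
remaining columns are pure noise. The default offsets are linear in the
timepoint code so the planted model is exactly representable by the screen's
design (PSFs + one timepoint slope). The planted truth is returned for
recovery tests.

## Questionnaire preprocessing

The documented filter chain runs in a fixed order: patients whose
preeclampsia fields are all missing are excluded first (283 → 200 on the
packaged fixture); configured text columns are parsed to numbers (clock
times to minutes after noon on a 24-hour wrap, so "10:30 PM" → 630);
non-numeric columns are dropped; columns with at most one distinct
non-missing value are dropped; finally named age-inapplicable items are
dropped (the "life stress 41–50" question — the cohort is younger than 41).
On the packaged fixture exactly 79 predictors remain. Scaling divides each
column by its sample (n−1) standard deviation computed on fitting rows only;
columns are also mean-centered by default (`center = FALSE` restores pure
unit-variance scaling), and missing entries are imputed at the fitting-split
mean. Scaling parameters are stored and replayed on held-out rows, so no
evaluation information reaches the preprocessing.

Two choices here were genuinely open: the missing-entry policy at model time
(fitting-split mean imputation — the minimal choice compatible with
unit-variance scaling) and the yes/no encoding ({no: 0, yes: 1}, ordinal
scales kept as integers).

## Model 1: multitask vs single-task networks

Architecture: an affine feature embedding, two shared fully connected hidden
layers of 150 units, then one task-specific module of 150 units per outcome
ending in a sigmoid (binary) or identity (numeric) head; batch normalization
and ReLU at every hidden layer. The single-task variant is the same network
restricted to one task module. Training is full-batch Adam for at most 35
epochs with early stopping at patience 1, monitored on a 20%
validation slice carved from each training fold (patience 1 requires a
validation signal distinct from the test folds). Loss is the sum of binary
cross-entropies plus `mse_scale` times the numeric mean squared errors;
numeric targets are standardized per training fold, so the default
`mse_scale = 1` keeps the two loss families commensurate.

Numerical choices: batch-norm uses batch statistics in training and
exponentially averaged running statistics (momentum 0.1, eps 1e-5) for
evaluation; He initialization for ReLU layers; probabilities are clipped at
1e-7 for the cross-entropy. The learning rate is the one genuinely open
training knob: with a batch size equal to the whole training set the
gradient is noiseless and the usual minibatch default of 1e-3 cannot move
the weights appreciably in 35 epochs — it fails even the linearly separable
sanity case (training AUROC 1.0 within 35 epochs), which 1e-2 passes. The
default is therefore 1e-2, exposed in `network_config()`. The gradients of
the full architecture are verified against finite differences in the test
suite.

Evaluation: repeated stratified 5-fold cross-validation, stratified on the
composite any-positive indicator over the binary tasks (the multi-task
stratification label was an open choice; a composite binary label keeps
folds balanced for the union of rare outcomes). Held-out predictions are
pooled over the 5 folds and yield one AUROC (binary) or Spearman rho
(numeric) per task per repetition; 20 repetitions by default. Both model
classes run on identical splits, and the comparison uses the Wilcoxon
signed-rank test paired by repetition (a rank-sum variant is exposed via
`paired = FALSE`), with the conventional star thresholds at 0.05, 0.01,
0.001 and 0.0001.

## Clustering and association of stressors

Spearman correlation profiles (pairwise-complete, average ranks) are
computed between all retained PSFs. K-means (10 restarts, fixed seed,
re-seeded deterministically on an empty cluster) groups the PSFs into 15
clusters on the **raw signed** profiles; the two-dimensional t-SNE embedding
runs on the **absolute** profiles — the two transformations are easy to
conflate, so the test suite pins both (a sign-flipped duplicate of a feature
embeds next to it but must not join its cluster). Since no t-SNE
implementation ships with the available R stack, the package carries a small
exact implementation (perplexity calibration by binary search, early
exaggeration, momentum gradient descent) adequate for tens to hundreds of
points; its step size scales with the point count because large steps
overshoot the strong pairwise attractions of small point sets. Perplexity
defaults to 10, suited to ~79 points.

Stressor-outcome association uses Spearman rho with the two-sided t
approximation and an **unadjusted** p < 0.05 mask — deliberately no multiple
testing correction at this stage, matching the emulated analysis design (the BH
correction appears only in the immune screen); the type-I cost of that
choice is quantified in the calibration test (the mask fires at ~5% of cells
on signal-free cohorts). Cluster summaries use the any-member rule: an APORF
is associated with a cluster if any member PSF is significantly associated
with it; per-cluster percentages are normalized by cluster size; per-PSF
tallies split APO vs RF associations.

## Model 2: the grouped ridge screen

One ridge regression per immune feature predicts it from the scaled PSFs
plus the raw timepoint integer. The outer loop is a shuffled grouped 10-fold
split of patients — all four timepoints of a patient stay in one fold — and
the per-feature penalty is selected from the grid (1, 0.1, 0.01, 0.001,
0.0001, 0) by a grouped 5-fold grid search inside each training portion
(the inner loop is not specified in the emulated protocol; mean squared
error selection inside the training portion is the standard leakage-free
choice, and the test suite verifies by poisoning held-out rows that
selection never sees them). `alpha = 0` is the minimum-norm least-squares
solution: with 80 predictors and at most ~50 training rows the design is
underdetermined, and the implementation solves the whole grid from one SVD
of the centered design. Per repetition, Spearman rho and p are computed per
feature over all pooled held-out rows; rho and p are then **averaged over
repetitions** and BH applied to the mean p-values at level 0.05.

Averaging p-values before BH is statistically unconventional (the mean of
uniform p-values concentrates at 0.5, making the screen conservative under
the null); it is implemented as written because it is the emulated
procedure, and the contract `mean_p == mean(per-repetition p)` is asserted
in the tests. The null calibration test confirms the conservative direction:
with no planted signal the screen averages far fewer than the 0.05 × 534
budgeted discoveries.

A note on recovery checks: with the study-scale design (79 + 1 predictors,
14 patients) coefficients are only identifiable up to their projection onto
the ~50-dimensional training row space, so *no* method can recover planted
coefficients there. The recovery tests therefore run on identifiable
configurations (more panel rows than predictors, e.g. 25 patients × 4
timepoints against 20 PSFs, and zero missingness for the exactly-linear
contract); the study-scale default is used everywhere else.

## Model 3: the linear generator

All repetition × fold ridge fits are averaged element-wise — coefficients
and intercepts alike — into a single linear map ("all runs" is read
literally as every fitted slice, unweighted). The generator stores the
fold-averaged scaling parameters and applies them to new patients'
stressors, appends a timepoint code, and evaluates the exact affine map: no
noise is injected, and generation is bitwise reproducible. By default
generated features represent timepoint 1 (the first trimester, when the
questionnaire was administered); the emulated analysis design does not state which
timepoint the imputed features represent, nor whether timepoints were
concatenated, so the timepoint is an argument. The 14 immune-measured
patients are excluded before the downstream APORF prediction — their
measured data trained the generator — and passing any of them raises an
error; on the 200-patient default cohort exactly 186 patients are imputed.

Because generation is linear, averaging the ensemble and then generating
equals generating per slice and averaging the outputs; this linearity is
asserted on random ensembles.

## The end-to-end triad check

When synthetic PSFs drive both the immune panel and the outcome liabilities,
APORF prediction from *generated* immune features must beat chance; when the
chain is cut, it must not. Severing deserves care: shuffling the generator's
coefficients does **not** destroy the signal, because any full-rank linear
map of the PSFs preserves their information content and the downstream
network's input embedding can absorb the remixing. The honest null severs
the patient-level correspondence instead — outcomes generated independently
of the PSFs — and the test confirms chance-level AUROC there, with
above-chance performance (mean of per-task medians across the five binary
outcomes) when the chain is intact. The downstream network for this check
uses the gentler 1e-3 step: with 534 input features and fewer than 200
patients, slow early-stopped training is the better-regularized regime
(the 1e-2 default is calibrated to the 79-feature stressor input), and the
choice applies identically to the intact and severed arms. Under that
configuration the generated-immune route preserves essentially all of the
direct PSF signal (mean AUROC ~0.56 both ways on the default synthetic
cohort), as expected for a linear bottleneck of rank ≥ the PSF dimension.

## Problem sizes in the tests

The test suite and acceptance checks run the full study-scale configuration
wherever a printed quantity is checked (200 patients, 79 stressors, 15
clusters, 534 immune features, 14 immune patients, 186 imputed patients).
Repetition counts are scaled to the check: the screen's calibration and
count contracts use 1–3 repetitions of the outer loop (each repetition is an
independent split of the same data; the contracts do not sharpen with more),
the multitask comparison uses the 20 repetitions its median is defined over,
and the triad check uses 10 repetitions of the downstream evaluation. The
50-repetition default of `ridge_config()` matches the emulated study protocol and
remains the package default.

## Known limitations

- The generator's outcome model is a latent-liability stand-in: the study
  never states a joint generative mechanism for the outcomes, only pairwise
  correlations, so co-occurrence beyond second order is not calibrated.
- Synthetic stressors are block-exchangeable; real questionnaire items have
  heterogeneous marginals, skew, and structured (not completely-at-random)
  missingness. Passing tests show the pipeline's statistical machinery is
  correct under the assumed structure, not that the effect sizes transfer to
  real cohorts.
- The immune features are generated directly at the derived-feature level;
  raw single-cell acquisition, gating and feature curation are out of scope.
- Imputed immune features are linear functions of the stressors; any claim
  of biological validity of the imputation is outside what these models can
  establish.
- t-SNE coordinates are for visualization only; no downstream statistic
  consumes them.
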