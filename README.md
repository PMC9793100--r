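# pregstress

Joint modelling of adverse pregnancy outcomes (APOs) and pre-pregnancy risk
factors — together, *APORFs* — from questionnaire-derived psychosocial and
stress-related factors (PSFs), with a downstream link to single-cell immune
features. The package is aimed at biostatisticians and perinatal
epidemiologists who want to study rare, correlated clinical outcomes jointly
rather than one at a time, and to prototype the full
stress → immune → outcome modelling chain on data with known ground truth.

## What it implements

**Model 1 — multitask outcome prediction.** Seven APORFs (gestational
diabetes, severe preeclampsia, superimposed preeclampsia, chronic
hypertension, diabetes as binary tasks; gestational age at delivery and
pre-pregnancy BMI as numeric tasks) are predicted from 79 stressors by a
multitask neural network: an affine feature embedding, two shared hidden
layers of 150 units, a 150-unit task module per outcome, batch
normalization and ReLU throughout, trained full-batch with Adam (max 35
epochs, early stopping at patience 1) on the loss

  L = Σ_binary BCE(y_t, p_t) + λ Σ_numeric MSE(y_t, ŷ_t),

with numeric targets standardized per training fold and λ = `mse_scale` = 1.
Multitask and architecturally identical single-task networks are compared on
identical repeated stratified 5-fold splits: one AUROC (binary) or Spearman
ρ (numeric) per task per repetition from the pooled held-out predictions,
compared by Wilcoxon signed-rank with the usual star thresholds.

**Stressor structure.** Pairwise Spearman correlation of the APORFs (weak /
moderate / strong edges at |ρ| 0.3 and 0.6), K-means (k = 15) on the PSFs'
signed correlation profiles, t-SNE embedding of their absolute profiles, and
PSF × APORF association at unadjusted p < 0.05 with any-member cluster
summaries.

**Model 2 — stress → immune screen.** One ridge regression per immune
feature (534 by default) predicting it from the scaled PSFs plus a timepoint
integer (1–4), with the penalty picked per feature from
α ∈ {1, 0.1, 0.01, 0.001, 0.0001, 0} by grouped grid-search
cross-validation inside each training portion of a shuffled grouped 10-fold
outer loop (all four timepoints of a patient stay in one fold; 50
repetitions). Per-feature Spearman ρ and p over the pooled held-out samples
are averaged across repetitions and Benjamini–Hochberg-corrected at 0.05.

**Model 3 — in-silico immune features.** Every fitted ridge coefficient
vector is averaged into a single linear generator ŷ = W x + b that imputes
immune features for the patients without immune measurements (the 14
measured patients are excluded); the imputed features feed the Model 1
architecture again.

**Synthetic cohort generator.** Correlated binary outcomes via a latent
liability threshold model with exact case counts (18/11/29/6/13/17, 52
distinct affected patients out of 200), block-correlated partially
discretized stressors (79 in 15 blocks), gestational age at questionnaire
(median 11 weeks, >95% before 21 weeks), and an immune panel with planted
linear PSF signal for recovery testing.

## Worked example

```r
library(pregstress)

cohort <- generate_cohort(cohort_spec(seed = 1))
#> 200 patients; 52 with at least one APORF

net <- build_outcome_network(cohort)
table(net$edges$category)
#> moderate     weak
#>       11       10
round(net$rho["severe_preeclampsia",
              c("superimposed_preeclampsia", "hypertension")], 2)
#> superimposed_preeclampsia              hypertension
#>                      0.43                      0.34
```

Eleven of the 21 outcome pairs correlate at |ρ| ≥ 0.3 — the
interrelatedness that motivates joint modelling: severe preeclampsia tracks
superimposed preeclampsia (ρ = 0.43) and hypertension (ρ = 0.34), and lower
gestational age at delivery accompanies higher preeclampsia liability
(ρ = −0.31). Continuing down the pipeline:

```r
fm  <- filter_features(cbind(cohort["patient_id"],
                             cohort[, grep("^psf_", names(cohort))]),
                       drop_items = character())
cl  <- cluster_psfs(correlation_profiles(fm), k = 15, seed = 1)
pan <- generate_immune_panel(cohort, immune_panel_spec(seed = 2))
cv  <- grouped_repeated_cv(pan, fm, ridge_config(n_repetitions = 5, seed = 3))
gen <- average_ensemble(cv$ensemble)
held <- cohort[!cohort$patient_id %in% pan$truth$patients, ]
imm  <- generate_features(gen, filter_features(
          cbind(held["patient_id"], held[, grep("^psf_", names(held))]),
          drop_items = character()))
nrow(imm)   # 186 patients imputed
```

`evaluate_repeated_kfold()` then runs the multitask / single-task comparison
on either the stressors or the generated immune features;
`comparison_table()` reports per-task medians, the Wilcoxon p and the star
label.

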