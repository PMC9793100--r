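Package: pregstress
Title: Multitask Modelling of Adverse Pregnancy Outcomes from Psychosocial Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint modelling of adverse pregnancy outcomes (APOs) and
    pre-pregnancy risk factors from questionnaire-derived psychosocial and
    stress-related factors (PSFs). Provides a synthetic cohort generator with
    correlated latent-liability outcomes and block-correlated stressors, the
    questionnaire preprocessing chain, a Spearman outcome-interrelatedness
    network, multitask and single-task neural networks compared under repeated
    stratified K-fold cross-validation, K-means clustering of stressor
    correlation profiles with t-SNE embedding and APORF association summaries,
    a ridge-regression screen linking stressors to single-cell immune features
    under grouped repeated cross-validation with Benjamini-Hochberg false
    discovery rate control, and a linear generator that imputes immune
    features for patients without immune measurements to feed a second
    outcome predictor.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
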