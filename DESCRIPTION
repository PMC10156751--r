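Package: facefwd
Title: Facial-Orientation and Blink-Rate Attention Phenotyping from
    Per-Frame Video Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying attentional engagement of toddlers
    watching a fixed sequence of social and nonsocial movies, from
    per-frame computer-vision feature streams (head pose, gaze,
    eyes-open state, action-unit 45 intensity, tracker confidence)
    recorded at 30 frames per second. Implements the facing-forward
    mask and total-time-facing-forward (TFF) percentage, AU45-based
    blink detection and blink rate per minute of valid time, and the
    mean gaze-percent-social (MGPS) metric for spatially halved
    stimuli; a synthetic-cohort generator with group- and
    stimulus-type-dependent attention and blink processes; the group
    comparison battery (2x2 mixed ANOVA with partial eta squared,
    Wilcoxon signed-rank and Mann-Whitney U tests with rank-biserial
    effect sizes, ANCOVA with age, per-movie comparisons, clinical
    Pearson correlations, demographic tests); and a leave-one-out
    cross-validated ridge-logistic classifier with pooled ROC curves,
    AUC, and Hanley-McNeil confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
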