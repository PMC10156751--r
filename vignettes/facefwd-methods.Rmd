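---
title: "Quantifying attentional engagement from per-frame video features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying attentional engagement from per-frame video features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facefwd)
```

## The measurement problem

Differences in social attention are among the earliest observable signs of
autism, and spontaneous eye-blink rate indexes attentional engagement:
blinking is suppressed while visual information is being actively encoded,
so lower blink rates mark deeper engagement. `facefwd` quantifies both
signals for toddlers who watch a fixed ~8-minute sequence of eleven short
movies — some with social content (actors, nursery rhymes, conversation),
some nonsocial (bubbles, mechanical toys) — on a tablet whose front camera
records the child at 30 frames per second.

The package deliberately starts *downstream* of the computer vision: face
detection, landmark fitting, head-pose solving, gaze estimation and facial
action-unit scoring are upstream tools whose per-frame outputs (yaw, pitch
and roll in degrees; a gaze-on-screen flag; a normalized horizontal gaze
coordinate; an eyes-open flag; AU45 blink-intensity; tracker confidence)
are this package's *inputs*, delivered as one CSV row per frame.

## Attention endpoints

**Facing forward.** A frame counts as facing forward when four conditions
hold simultaneously: the absolute head yaw is under 25 degrees (a proxy
for orienting toward the screen, consistent with the central-bias account
of gaze), the estimated gaze is on the screen, the eyes are open, and the
head is not in rapid motion. Rapid motion is declared when the *smoothed*
absolute yaw exceeds 150% of its value at the previous frame; the yaw
series is smoothed first because the rule otherwise fires on single-frame
tracker jitter. Total time facing forward (TFF) is the percentage of a
movie's frames that pass, in [0, 100].

**Blink rate.** Blinks are detected as peaks of the smoothed AU45 series:
interior local maxima with height at least 1.0 intensity unit and at
least 3 frames apart (the higher of two close peaks wins; ties go to the
earlier frame). The count is then normalized by *valid* time — frames
that are facing forward with tracker confidence at or above 0.75 — and
expressed as blinks per minute of valid time. Normalizing by valid time
rather than movie length matters: a child who looks away for half a movie
would otherwise appear to blink at half their true rate. A blink is
attributed to its apex frame only, the simplest rule consistent with
counting blinks that happen while the child is actually watching.

**Gaze percent social.** Two movies (Spinning Top, Blowing Bubbles) show
social and nonsocial content on opposite screen halves. Among on-screen
gaze frames, the percentage landing on the social half is computed per
movie and averaged into the mean gaze percent social (MGPS). These two
"mixed" movies are excluded from the social/nonsocial TFF and blink
aggregates precisely because they are neither.

Aggregate endpoints are unweighted means of per-movie values within each
stimulus type; per-movie values are first-class results (the per-movie
comparison table), so weighting movies by duration would conflate the two
levels of analysis.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `yaw_threshold_deg` | 25 | degrees | the method's facing gate |
| `rapid_ratio` | 1.5 | — | the 150%-of-previous-frame rule |
| `confidence_threshold` | 0.75 | — | tracker's recommended floor (inclusive) |
| `yaw_smooth_window` | 5 | frames | ~167 ms; shortest window that kills single-frame jitter |
| `au45_smooth_window` | 3 | frames | ~100 ms; below the ~100–400 ms span of a blink pulse |
| `blink_min_height` | 1.0 | AU45 units | separates pulses from baseline noise |
| `blink_min_separation` | 3 | frames | two physiological blinks cannot overlap closer |
| `rapid_eps_deg` | 1.0 | degrees | floors the ratio denominator; near zero yaw a ratio test is meaningless and every sign crossing would otherwise trigger |

The first three are fixed by the method; the rest are exposed in
`extraction_config()` because the source method does not pin them down —
the smoothing kind (centered moving average, shrunken windows at the
edges so no padding values are invented) and the peak criteria are this
package's choices, and the rapid-motion rule is applied to *absolute*
smoothed yaw because a ratio of signed angles is unstable.

## The synthetic cohort generator

Recordings of the kind of screening cohort this design targets (416
neurotypical and 43 autistic toddlers) are not publicly available, so the
package ships a generator that emulates the *structure* of such data and
makes every downstream stage testable:

* **Attention** is a two-state (attend/away) semi-Markov process per
  movie with exponential bout lengths (mean bout 3 s) whose stationary
  attending fraction equals the group's facing probability for that
  movie's type. Bout-level dynamics — rather than i.i.d. frames — ensure
  the smoothing and rapid-motion logic sees realistic transitions. The
  head-pose process spans the whole session so an attending spell that
  crosses a movie boundary keeps one yaw base. Away bouts are a 50/50
  mixture of gaze-off (head still roughly frontal) and head-turn
  (|yaw| 30–60°) modes.
* **Blinks** are Poisson counts at the type-specific intensity, placed
  with a 300 ms refractory spacing and rendered as 3–7-frame triangular
  AU45 pulses with apex 2–4. The eyes-open flag stays TRUE through a
  blink: it models sustained closure or occlusion, not 100-ms transients,
  which would otherwise gate every blink apex out of the valid mask.
* **Heterogeneity.** Facing probabilities are jittered per participant
  (sd 0.04 on the probability scale), blink intensities scaled by a
  mean-one gamma multiplier (cv 0.2) shared across stimulus types, and
  the social-gaze probability jittered with sd 0.10. No within-group
  dispersions are published for cohorts of this kind, so these are free
  parameters chosen once to give realistic overlap between groups.
* **Presets** encode the qualitative group-by-stimulus pattern: NT
  facing 0.95 social / 0.85 nonsocial with 12 / 18 blinks per minute;
  AUT 0.75 / 0.85 with 22 / 22; NT social-half gaze 0.70 vs AUT 0.45.
  Published reports of this design give the direction of each contrast
  but not the cell means, so the presets claim the pattern, not the
  numbers.
* **Clinical covariates** for the autistic group are constructed from
  the same latent traits that set each participant's facing
  probabilities: ADOS social-affect/total severity loads negatively on
  the social-attention trait and the Mullen composite and
  visual-reception scores negatively on the nonsocial trait, so the
  expected correlation signs match the study's pattern while all other
  cells stay near zero.

`simulate_feature_table()` draws the aggregate endpoints directly from
the generator's marginal model without synthesizing 30-fps streams; it is
used where the object under study is the downstream statistics (the
1000-replicate calibration study, classifier seed sweeps), while the
stream-level generator is used wherever the extractor itself is under
test.

What passing tests on these data do *not* show: the generator has no
pose-estimation noise model, no correlation between tracker confidence
and head pose, no age trends in attention, no drowsiness or fussiness
dynamics, and frame-level gaze coordinates are i.i.d. within bouts. Real
recordings will violate all of these; conclusions about the pipeline's
statistical behaviour transfer, point estimates of its accuracy on real
video do not.

## Statistical battery

For each endpoint (mean TFF, mean blink rate) the analysis runs a 2×2
mixed ANOVA — between factor group, within factor stimulus type —
computed by the closed-form mixed-design decomposition: the group effect
is tested in the between-subject stratum (subject means, each carrying
weight 2), and stimulus type and the interaction in the within stratum on
the unit-norm contrast (social − nonsocial)/√2, sequentially. With two
within levels sphericity is vacuous. Partial eta squared is
SS~effect~/(SS~effect~ + SS~error~) within the stratum. An absent effect
(zero sum of squares up to rounding) reports F = 0 and p = 1 rather than
a 0/0 ratio of rounding noise.

Within-group comparisons use the Wilcoxon signed-rank test (zero
differences dropped; exact null up to 25 tie-free differences, otherwise
a tie- and continuity-corrected normal approximation), between-group
comparisons the Mann–Whitney U test (exact for combined n ≤ 12 without
ties). Effect sizes are rank-biserial: r = 1 − 2U/(n₁n₂) for
Mann–Whitney and r = (T⁺ − T⁻)/(T⁺ + T⁻) for Wilcoxon, reaching ±1
exactly under complete separation. ANCOVA adjusts the group effect for a
linear age term via the nested-model F. P-values are reported unadjusted
everywhere; no multiple-testing correction is applied, and reports should
say so.

The sensitivity subset retains participants whose mean TFF across the
nine analyzed (non-mixed) movies exceeds 80 points — the conventional
0.80 read on the fractional scale, since a floor of 0.80 *percent* would
retain everyone. Which movie set enters that screening mean is not
specified by the source; the analyzed movies are used because they are
the ones all downstream statistics run on.

## Classifier

The three features (mean social TFF, mean social blink rate, MGPS) enter
a linear logistic regression with a small fixed ridge penalty (λ = 1 on
standardized coefficients, intercept unpenalized) — an unpenalized fit
diverges under separation, and the penalty strength matches the common
default of sum-loss logistic solvers. Evaluation is leave-one-out
cross-validation with the out-of-fold scores pooled into one ROC curve
(per-fold ROCs are meaningless at fold size 1); features are z-scored
with training-fold statistics only.

Two numerical points deserve emphasis:

* **Pooled scores exclude the fold intercept.** The intercept tracks the
  training fold's class prevalence, which differs by exactly one case
  between folds that hold out a case versus a control. With weak
  features the pooled ranking would therefore encode the held-out label
  itself and drive null AUC far below 0.5 (to ~0 in the constant-feature
  limit). The reported score is the logistic transform of the
  standardized linear predictor — a ranking, not a calibrated
  probability.
* **The Hanley–McNeil CI is anti-conservative here.** Its standard error
  assumes one fixed scoring function applied to independent samples;
  pooled LOOCV scores are neither, and under null simulations the 95%
  interval covers 0.5 roughly 80% of the time rather than 95%. The
  interval is reported because it is the conventional companion to this
  design; its optimism under resampling is documented, not corrected.

AUC is computed via the Mann–Whitney identity with half-credit for ties,
which equals the trapezoid area under the tie-grouped ROC.

## Degenerate inputs and tie-breaks

Empty frame series error; movies beyond a short recording yield missing
features and drop out of unweighted means; a participant missing an
endpoint is dropped from analyses requiring it (reports carry the n
actually used). Zero valid frames make the blink rate missing rather
than infinite. Close blink peaks resolve to the higher, then earlier,
apex. Fully tied samples give p = 1 and r = 0. Confidence exactly at the
0.75 floor is valid ("at or above").

## Problem sizes

The test suite exercises the study-scale cohort (416 + 43 full 30-fps
sessions, one pass) for parameter recovery, 1000 feature-level replicates
at n = 30 + 30 for the type-I-error calibration, 20 feature-level seeds
at study scale for the classifier-combination property, and exhaustive
enumeration (all rank arrangements for combined n ≤ 8; all 2^n sign
patterns for n ≤ 8) for the exact tests. These sizes were chosen so each
property is measured with sampling error well inside its tolerance.

## A short worked example

```{r example, eval = FALSE}
cfg <- cohort_config(n_per_group = c(NT = 60, AUT = 30), seed = 11)
res <- simulate_and_extract(cfg)
report <- run_analyze(res$cohort)
vapply(report$tff$anova, function(b) b$p, numeric(1))
compare_feature_sets(res$cohort)
```

## Known limitations

The extractor trusts its upstream inputs: there is no imputation for
dropped frames, no re-identification if the tracker switches faces, and
pitch/roll are carried but never gated on. The generator's realism
limits are listed above. The classifier makes no attempt at
hyperparameter search, calibration or external validation — the AUC it
reports on synthetic data reflects the planted effect sizes, not any
claim about screening performance in the clinic.
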