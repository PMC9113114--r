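---
title: "Methods: sensorimotor scoring and cerebellar brain-behavior models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensorimotor scoring and cerebellar brain-behavior models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cerebmotor` implements, end to end, the measurement and analysis pipeline
used in studies relating cerebellar subregion volumes to sensorimotor
behavior in autism spectrum disorder and typical development: isometric
precision-grip force variability, visually guided saccade accuracy,
18-region cerebellar volumetry, and the mixed-effects association models
that link them. This vignette records the models, their assumptions, the
parameters that matter, and the design decisions taken where the underlying
procedures are conventionally underspecified.

## Grip scoring

A grip trial is a 15 s force trace sampled at 200 Hz while the participant
holds a target of 15% of their maximum voluntary contraction (MVC; the mean
of three maximal-press peaks per hand). Scoring proceeds in four steps.

1. **Filtering.** Fourth-order Butterworth low-pass, 15 Hz cutoff, applied
   forward and backward. Two passes make the filter zero-phase — important
   because a causal pass would delay the rise and bias onset detection —
   and square the magnitude response, so attenuation at the cutoff is 1/2
   (the test suite checks this against the closed form
   $|H(f)|^2 = 1/(1+(f/f_c)^{8})$). Startup transients are kept out of the
   data by odd-reflection padding at both ends rather than the zero-padding
   some implementations use, which corrupts nonzero-mean physiological
   signals.
2. **Rise offset.** The sustained phase begins when the rate of force
   increase (central-difference derivative) falls below 5% of its peak
   *and* force is within 90–110% of the sustained-phase mean. As written
   the rule is circular — the sustained mean depends on the offset — so it
   is resolved iteratively: the mean is initialized from the final 12 s
   window, the offset located, the mean recomputed from the post-offset
   window, and the offset located once more (this converges on all
   fixtures). Two further disambiguations: the sustained-mean estimate
   excludes zero-force (released) samples, and the peak-rate search is
   restricted to the epoch before force first reaches the 90–110% band, so
   a re-grip after a mid-trial release is not mistaken for the initial
   rise.
3. **Sustained extraction.** Samples in the 12 s before the stop cue, at or
   after the rise offset, minus any zero-force span (force below the
   0.0016 N transducer resolution) *strictly longer* than 1 s. The trial is
   valid with at least 8 s retained. Boundary semantics follow the stated
   rules exactly — a release of exactly 1 s is retained, exactly 8 s
   retained is valid — with a 1 ns numeric tolerance so binary
   representation of thresholds cannot flip a boundary case.
4. **Endpoint.** CoV = sample SD / mean of the retained samples (n−1
   denominator; at 2,400 samples the distinction from the population SD is
   negligible), log-transformed with the natural log for all modeling.

## Saccade scoring

A saccade trial is central fixation (1.5–2 s) followed by a target step to
±12° or ±24° for 1.5 s, sampled at 500 Hz. Positions are smoothed with a
linear-phase FIR low-pass (31 taps, 50 Hz cutoff at 500 Hz, unit DC gain,
symmetric kernel so it is zero-phase by construction); descriptions of this
smoothing step in the eye-movement literature rarely pin down a passband or
tap count, so these parameters are exposed in `saccade_config()`. Velocity is the central-difference derivative of
horizontal position.

Saccades are spans where |velocity| stays at or above 30°/s for ≥ 8 ms,
extended forward to the first sample below 30°/s, the conventional offset
criterion; the symmetric onset threshold and minimum duration are
field-standard choices. The primary saccade is the first event after
target onset covering at least 20% of the fixation-to-target distance, and
(by default, configurable) moving toward the target — a 20%-amplitude
saccade away from the target is not a response. Latency ≤ 70 ms is
anticipatory and the trial is excluded. Error is |x(offset) − target|;
per-cell variability is the sample SD of error across a cell's valid
trials. Blink handling is automated in place of manual inspection: missing
samples or |velocity| > 1000°/s, padded by 50 ms, exclude the trial when
they overlap the first 1,000 ms after target onset; fixation-period blinks
are interpolated through and the trial retained. Only the horizontal
channel is scored (the task is horizontal); the vertical channel serves
artifact detection. Corrective saccades are detected but contribute to no
endpoint.

## Volumetrics

The analysis schema is 18 ROIs: left/right lobules I–V, lobule VI, Crus I,
Crus II/lobule VIIB (one composite, following the reporting convention of
cerebellar parcellation pipelines), lobule VIII, lobule IX, lobule X; vermal
composites I–V, VI–VII, VIII–X; and cerebellar white matter.
`load_volume_table()` maps common segmentation-tool labels onto this schema
(the alias map is configurable because label-to-composite conventions vary
across template versions), converts mm³ to cm³, errors on missing ROIs by
name, warns on — never silently drops — unknown columns, and QC-flags
non-positive volumes. Volumes are analyzed raw, without intracranial-volume
normalization, matching the analysis convention this pipeline targets;
`derive_composites()` adds only the exact 18-ROI sum.

## Association models

All families are fit with `lme4`/`lmerTest`; per-term F tests use
Satterthwaite denominator degrees of freedom (hence fractional df).
Specifications without a within-participant factor — midline volume
contrasts and all clinical regressions — are ordinary least squares with
type-III F tests; singular random-intercept fits fall back to OLS with a
logged warning. Final reported fits use REML; model-comparison fits use ML.

* **Behavior vs group:** log CoV on hand (level 1) + group, sex, centered
  age (level 2), with group×hand, group×sex, group×age; saccade error and
  error-SD models use amplitude and direction as level-1 terms with
  amplitude×direction, group×amplitude, group×direction, and
  group×amplitude×direction.
* **Volume vs group:** hemisphere as the level-1 term for the 7 lateral
  pairs (group×hemisphere, group×sex, group×age — the candidate interaction set
  is a design choice, and these are the three such volume contrasts
  conventionally examine), identical models minus hemisphere for the 4
  midline ROIs.
* **Brain–behavior:** behavior on level-1 design factors + group, ROI
  volume, centered age, with sex as a covariate of no interest; three-way
  sets group×hand×volume (grip) and group×amplitude×volume,
  group×direction×volume (oculomotor) with their nested two-ways.
* **Clinical (ASD arm):** ADOS CSS or RBS-R total regressed on an ROI
  pair's left and right volumes as *separate hemispheric predictors* in one
  regression (the clinical score is participant-level, so a
  hemisphere-as-level-1 mixed model would duplicate the outcome and is
  degenerate), plus sex and sex×volume; midline ROIs get single-volume
  regressions. Age is not included.

**Interaction pruning.** Parsimony-guided removal of uninformative
interactions is operationalized as: among currently removable interactions (never main
effects; never a term contained in a retained higher-order term), test the
highest order first; drop the term whose ML likelihood-ratio test against
the model without it has the largest p, if that p ≥ 0.05; refit and repeat.
The trace of every test is kept on the fitted object. Terms whose LRT is
inestimable (rank deficiency at small n) are treated as non-improving.

**FDR control.** `bh_adjust()` implements the Benjamini–Hochberg step-up
rule directly and reports `p_crit`, the largest passing threshold
$kq/m$ — the quantity reported alongside corrected families. Confirmatory
families are: the group term across the 7 lateral (and, separately, 4
midline) volume models; the volume term across the six primary skeletomotor
ROIs for grip (left/right lobules I–V, VI, Crus I) and the oculomotor
vermis for saccade error. Which p-values pool into one corrected family is
ultimately a reporting choice, so family composition is an argument
(`rois =`, `correct =`), with these defaults. Clinical and non-primary-ROI
analyses are exploratory and flagged uncorrected.

**Simple slopes.** The slope of a focal predictor (or the contrast of a
two-level factor) at each level of a categorical moderator is a linear
combination $L\hat\beta$ with SE $\sqrt{L^\top V L}$; for mixed fits the t
test uses Satterthwaite df via `lmerTest::contest1D()`. Other covariates sit
at 0/reference, so with treatment coding slope(B) − slope(A) equals the
interaction coefficient exactly — asserted in the tests as an algebraic
identity. Continuous moderators are not supported (all moderators in these
families are categorical design factors).

## The synthetic-data generator

The generator defines the study conditions: 58 ASD (21 F) and 34 TD (18 F)
participants aged 8–30; per-group age, per-hand MVC, ADOS CSS and RBS-R
distributions; per-ROI, per-group, per-hemisphere volume means and SDs; a
60-trial, 2-block saccade session balanced over the four
amplitude×direction cells; and three 15 s grip trials per hand.

Numerical choices:

* **Bounded quantities** (age on [8, 30], MVC > 0, ADOS on [1, 10], RBS-R
  ≥ 0) are truncated normals whose *parent* mean is solved numerically so
  the truncated mean equals the configured table value — plain truncation
  would, e.g., inflate the RBS-R mean by ~2.4 points. Volumes use a lower
  bound of 0.1× baseline, where the truncation bias is below 10⁻⁸ cm³ and
  no correction is needed.
* **Hemisphere correlation.** Left/right members of a paired ROI share a
  participant-level component (correlation 0.8, marginal moments
  unchanged): real hemispheric volumes correlate strongly, and the
  hemisphere-as-level-1 models rely on a non-degenerate participant random
  intercept.
* **Force trials** rise after a 0.3 s reaction time with a 0.25 s
  smoothstep (participants press "as quickly as possible"; the rise must
  own the trace's peak derivative for the offset rule to be meaningful).
  Plateau noise is multiplicative, 0.5 pink + 0.5 white, band-limited to
  0–12 Hz so the 15 Hz scoring filter preserves it, and standardized per
  realization so the plateau's sample CoV *equals* the configured
  `latent_cov` exactly — the annotation the scoring oracle tests against.
* **Saccades** follow a symmetric smoothstep position profile with a
  main-sequence duration rule (2.2 ms/° × amplitude + 21 ms); any smooth
  profile with controllable peak velocity would do, but one must be fixed
  for oracle tests. Gain and latency are drawn per trial (defaults: gain
  0.95 ± 0.06, latency 200 ± 30 ms, truncated at 80 ms); optional
  corrective saccades, blinks (recorded as missing samples), and white
  position noise (0.05°, roughly video-oculography noise after smoothing)
  complete the trace.
* **Couplings.** Trial-level outcome generators
  (`generate_grip_outcomes()`, `generate_saccade_outcomes()`) implement
  linear models with configurable group/sex/age effects and per-group ROI
  volume slopes, plus participant and trial noise. Defaults emulate the
  qualitative published pattern: TD log-CoV around log(0.05) with a +0.35
  ASD shift and lower variability with age; saccade error near 1° (12°
  targets) and 1.8° (24°), slightly larger leftward. These generators feed
  the statistical-recovery suites directly; the trace-level generators are
  validated separately by the scoring oracles. Recovery at cohort scale
  (n ≈ 92) is power-limited for interaction effects of realistic size —
  the recovery suites therefore run at n = 400–500, and the power examples
  in the unit tests inject effects sized for adequate LRT power given the
  ~2.2 cm³ volume SDs.

What the generator does **not** emulate: MRI images or segmentation masks
(only their tabular output), smooth pursuit or vertical saccades, pupil
dynamics, drifts or microsaccades in fixation, fatigue or learning across
trials, missing-visit patterns, and any nonlinearity in brain-behavior
couplings. Passing tests demonstrate that the pipeline recovers known truth
under these idealized conditions; they do not certify performance on real
recordings, whose artifact structure is richer.

## Problem sizes and suite design

The test suites use: 100-trial fixtures for scoring oracles and offset
recovery; 200 replicates (n = 100) for the type-I calibration of the group
F test, checked against the 95% binomial interval and a Kolmogorov–Smirnov
uniformity test; n = 400–500 single draws for 2-SE parameter-recovery
checks; 10,000 fuzzed families for the Benjamini–Hochberg
brute-force equivalence; and 100,000-draw cohorts for generator-calibration
means (sized so Monte-Carlo error is well below the ±0.5% calibration
tolerance even for the highest-variance cell). Unit-level recovery
assertions on single simulated draws use 3-SE bounds; the acceptance suite
applies 2 SE at its stated sample sizes. The offset-detection example
deserves one honest caveat: under the default noise model, pink-noise
excursions occasionally hold force outside the 90–110% band for tens of
milliseconds, so the share of trials whose detected offset lands within
50 ms of the annotated truth is about 92–93%, not higher; the CoV endpoint
is insensitive to this (recovered within 2% at all tested noise levels).

## Known limitations

* The pruning rule is one reasonable operationalization of
  "parsimony-guided removal"; alternatives (AIC, backward F tests) would
  retain slightly different sets near the 0.05 boundary.
* Satterthwaite df are approximations; with small clusters the F tests are
  only asymptotically calibrated (the type-I suite checks n = 100).
* The clinical regressions assume linear volume-symptom relations within
  the ASD arm and ignore ADOS module heterogeneity.
* Trial-level saccade error is truncated at zero in the outcome generator;
  with default means (≥ 1°) the induced attenuation of volume slopes is
  ≪ 1 SE, but couplings pushing mean error toward zero would bias recovery.
* The EyeLink ASC reader covers sample lines only (no event parsing), with
  a small-angle pixel-to-degree conversion.
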