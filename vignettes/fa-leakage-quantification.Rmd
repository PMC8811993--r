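---
title: "Quantifying fluorescein-angiography leakage and predicting anti-VEGF response"
author: "faleak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescein-angiography leakage and predicting anti-VEGF response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faleak)
```

## The problem

Branch retinal vein occlusion (BRVO) causes macular edema that is treated
with repeated intravitreal anti-VEGF injections under a pro-re-nata
regimen. Eyes split into a *responsive* group needing fewer than 5
injections in the first year and a *refractory* group needing 5 or more
(or showing persistent edema after the 3 monthly loading injections,
`classify_response()`). Identifying refractory eyes before treatment would
let clinicians plan therapy and counsel patients early.

Fluorescein angiography (FA) images vascular leakage directly: dye
extravasates through injured vessel walls, so hyperfluorescence appearing
between an early (1 min) and a late (5 min) frame marks leaking vessels.
`faleak` turns that observation into a number — the mean gray value of a
binarized late-minus-early leakage map over fovea-centred windows — and
provides the statistics for evaluating it as a predictor of treatment
response.

## The imaging chain

`quantify_eye()` runs, in fixed order: rigid alignment → rolling-ball
background subtraction → 384 px fovea-centred crop → per-frame
auto-threshold and binarization → regional sub-crops → clamped subtraction
→ mean gray value. The order matters: thresholding before background
removal would fold the illumination gradient into the foreground mask, so
the operators are not exposed in reorderable form.

### Alignment

The late frame is resampled onto the early frame (the early frame is the
reference because the leakage map subtracts it). Registration is dense and
Fourier-based: both frames are Hann-windowed, translation is read off the
phase-correlation peak with parabolic sub-pixel refinement, and rotation
is found by maximising the peak height over a coarse grid at half
resolution followed by golden-section refinement at full resolution. We
chose dense correlation over keypoint matching deliberately: fundus frames
from a confocal scanning-laser ophthalmoscope share dense vascular texture
across the whole field, inter-frame motion is small and close to rigid,
and a correlation peak gives a single scalar quality measure. When the
peak falls below `min_quality` (default 0.01; identical frames score 1) an
*alignment failure* is raised, which the pipeline can convert into an
identity-transform fallback with a warning. On synthetic frames with known
motion the estimates are well inside 0.5 px and 0.25°.

### Rolling-ball background subtraction

The background is the envelope of a ball of radius 50 px (configurable)
rolled under the intensity surface — a grayscale opening with a non-flat,
ball-dome structuring element. Radii above 10 px use the classical
shrink–smooth–roll–expand approximation: 3×3 mean smoothing, block-minimum
reduction (factor 2/4/8 for radii ≤30/≤100/>100), ball rolling at reduced
scale, bilinear expansion, and a final clamp of the background into
`[0, img]` so subtraction can never brighten a pixel. The "light
background" and paraboloid variants of the classical tool are not
implemented. Against a brute-force full-resolution ball opening the
approximation stays within a few gray levels (bounded at 8 in the tests,
typical mean error ≈ 3); in the unshrunk regime the operator is a true
opening and hence idempotent up to 8-bit rounding. The approximation bias,
not the operator, is what breaks exact idempotence at large radii — a
known and accepted trade for speed.

### Thresholding and the leakage map

Each 384-crop is binarized at its own iterative-intermeans threshold
(`isodata_default_threshold()`): on the 256-bin histogram, starting from
the midpoint of the occupied range, iterate
`t ← round((mean below + mean above)/2)` to its fixed point. When an
extreme bin (0 or 255) holds more than half of all pixels it is ignored,
matching the saturated-image special case of the method's common
"default" dialect. The iteration map is monotone, so it converges without
cycling; tests check it lands on a brute-force-enumerated fixed point.

Per-frame thresholds are the default because each frame is binarized
independently in the procedure we model; a pooled per-stack threshold is
available (`shared_threshold = TRUE`) since the original description
leaves the choice open, and the choice is logged in the run's provenance
record.

The leakage map is `max(B₅ − B₁, 0)`: hyperfluorescence present late but
absent early. Vessels bright in both frames cancel; ischemic areas stay
dark in both and contribute nothing.

### Regions and the score

Windows of 120 px (parafoveal, ≈3 mm) and 240 px (perifoveal, ≈6 mm) are
cut around the crop centre with a half-open convention
(`[c − s/2, c + s/2)`), which makes nested crops compose exactly. The
perifoveal window is the full square — its pixels include the parafoveal
ones — because the procedure we model crops nested squares and reports
both; an annulus variant (`perifoveal_annulus = TRUE`) is provided for
sensitivity analysis. The nominal mm equivalences are inconsistent with a
30° / 768 px field and are therefore treated as descriptive metadata only;
all geometry is in pixels. The mean gray value of a {0, 255} map is
255 × (leaking fraction), so scores scale linearly with leak area. Scores
from two graders are averaged (`average_graders()`), which halves
measurement variance under symmetric noise.

## The statistical toolkit

* `empirical_auc()` — Mann–Whitney estimator from ranks, ties one-half.
* `delong_variance_and_ci()`, `delong_paired_test()` — DeLong structural
  components (via pROC), with degenerate cases pinned: identical
  predictors give z = 0, p = 1; a perfectly separating predictor has
  se = 0. CIs are normal-scale and clipped to [0, 1] by default; a logit
  option exists because published CIs rarely state their scale.
* `binormal_auc()` — `Φ((μ₊ − μ₋)/√(σ₋² + σ₊²))`, the closed form linking
  group moments to an implied AUC; it is the analytic check on the
  simulation-based estimates.
* `icc_agreement()` — ICC(2,1), two-way random effects, absolute
  agreement, single measure, from the two-way mean squares. Absolute
  agreement is the right flavour for graders measuring the same physical
  quantity: a constant shift between graders lowers it.
* `two_sample_t()` — Student's pooled-variance test by default (the
  convention of the legacy statistical software whose analyses we mirror);
  Welch by flag.
* `chi_square_2x2()` — Pearson without continuity correction. The
  uncorrected form reproduces the published contingency p-values
  (e.g. 0.851 for the sex distribution); the corrected form does not,
  which anchored this choice.
* `backward_stepwise_logistic()` — maximum-likelihood fit, iterative
  removal of the largest Wald p above `p_stay = 0.05`, odds ratios
  `exp(β)` with Wald 95% CIs. The stay threshold reuses the 0.05
  screening level since no separate removal criterion was stated.
  Separation is detected (non-convergence or runaway coefficients) and
  handled by a small-ridge refit that reports coefficients without
  p-values rather than pretending Wald inference works there.

## What the synthetic data do and do not show

`generate_fa_pair()` renders: a smooth radial + linear background
gradient (exercising the rolling ball), a branching random-walk vessel
tree with Gaussian cross-section (exercising thresholding and giving the
aligner texture), Gaussian leakage blobs whose amplitude grows from the
1-min to the 5-min frame, a rigid inter-frame motion, and additive
Gaussian sensor noise, all 8-bit quantized. The ground truth records the
exact leak support and transform, so tests can assert pixel-exact
properties: with zero noise and motion the set of brightened pixels *is*
the leak mask; leakage confined outside the 240-window must score near
zero (region locality); raising the 5-min blob amplitude can never lower
a regional score.

`generate_cohort()` draws per-group clinical variables from normals
truncated at 0. The published cohort summaries give only means and SDs;
normality is an assumption, flagged in the generated metadata, and
truncation enforces physical non-negativity. Injection counts follow the
grouping rule by construction (responsive uniform on 1..4; refractory
rounded 5.9 ± 1.6 floored at 5, matching the published moments
approximately), so generated labels always agree with
`classify_response()`. Grader noise defaults to sd 2.7 score units, which
puts the perifoveal ICC near 0.97 — the level reported for trained
graders; `calibrate_grader_noise()` inverts the variance-ratio relation
when a specific ICC is wanted.

What passing tests on these data show: the operators implement their
definitions, the pipeline wiring is correct, and effect sizes of the
published magnitude are recovered at the published sample size. What they
do not show: performance on real angiograms, whose vessel morphology,
media opacity, saturation behaviour and non-rigid distortions the
generator does not attempt to reproduce.

## Numerical choices and problem sizes

Tolerances and conventions are frozen in code: crops use the half-open
convention; thresholds bin pixels by integer part; binarization is
strictly greater-than; p-values print to 3 decimals with `<0.001` below,
scores to 1 decimal, AUCs to 3 — which makes runs byte-reproducible under
a fixed seed. The test suite runs image scenarios at 416 px (the smallest
size that keeps the 384-crop margins comfortable) and validates the
rolling ball against its brute-force oracle at 128 px with radii 15–20;
the simulation studies use 10,000 replicate cohorts for AUC reproduction,
500 replicates for ICC and stepwise recovery, and 50 seeded image pairs
for the end-to-end separation check. These sizes were chosen to keep
Monte-Carlo error well below the assertion tolerances.

## Known limitations

* Only the 1-/5-min pair is validated; later timepoints (10/15 min) are
  accepted as inputs but the leakage contrast there is known to be less
  specific.
* The fovea must be supplied (config, CSV, or ground truth); there is no
  automatic fovea detection, mirroring the single manual step of the
  procedure.
* Eyes failing image QC are excluded and counted (a run fails above 20%
  exclusions); no imputation is attempted.
* Image-mode runs quantify each eye once: two graders operating on
  identical files would be bit-identical, so dual-grader machinery is
  exercised through the simulated-grader path.
* The rolling-ball approximation deviates from the exact opening by a few
  gray levels at large radii, uniformly across groups; it cannot bias the
  between-group contrast but does set a floor on absolute score accuracy.
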