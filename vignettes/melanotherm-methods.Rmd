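---
title: "Quantifying melanistic pattern and physiological color change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying melanistic pattern and physiological color change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Crepuscular and nocturnal ectotherms such as the leopard gecko carry a stable
melanistic pattern (dark spots on a lighter, often yellow, base) whose role in
thermoregulation is unclear: these animals mostly absorb heat from the
substrate (thigmothermy) rather than from solar radiation. Testing whether the
*proportion* of melanistic pattern influences heating and cooling — and whether
temperature changes trigger rapid physiological color change (melanosome
movement that lightens or darkens the skin) — requires extracting the *same*
color quantities repeatedly from photographs of a freely moving animal, over a
controlled 25 °C → 15 °C → 25 °C experiment divided into five blocks
(start, cooling transition, cold plateau, heating transition, end).

melanotherm implements that measurement chain: photometric normalization,
unsupervised pattern segmentation, pattern and thermal quantification, and the
block-based statistical battery, plus a synthetic-data generator that provides
exact ground truth for every stage.

## Photometric model

Images are handled as H×W×3 arrays in [0, 1]. Two photometric quantities are
used:

* **Lightness** is the L channel of the hexcone HLS model,
  `L = (max + min)/2`, with `S = (max − min)/(1 − |2L − 1|)` and hue by
  hexagonal sector. Illumination drift acts (to first order) multiplicatively
  on L, which is why normalization happens in this space.
* **Luminance** is the weighted channel sum `w·(R, G, B)` used as the
  brightness proxy whose change over time measures physiological color change.
  The default weights are ITU-R Rec. 601 (0.299, 0.587, 0.114); they are a
  configuration knob (`lum_weights()`), so Rec. 709 is a one-line change.

### Standardization against the grayscale reference

Every frame carries an in-frame neutral gray patch. For each individual, the
patch of the *first* frame defines a baseline mean lightness; every frame is
standardized by multiplying all pixel lightness by
`g = baseline mean / current patch mean` and clipping to [0, 1] (the count of
clipped pixels is recorded). Multiplicative gain, not an additive offset, was
chosen because lighting intensity scales reflected lightness; with gain, an
L-scaled copy of a frame standardizes to exactly the same image (the package
tests this to 1e-6), and standardizing twice is a no-op.

Two guards follow from this model:

* Standardization is strictly within-individual. Comparing standardized
  luminance *across* individuals is not meaningful (each individual has its
  own baseline), and `standardize_lightness()` refuses a baseline from a
  different individual unless explicitly overridden.
* Pixels at or above lightness 0.98 in the *raw* frame are flagged saturated
  at capture: their true value is unknown (clipped by the sensor), so they are
  excluded from the animal foreground. This matters for bright frames in which
  the white arena background clips at capture and would otherwise reappear
  *below* the background-lightness threshold after standardization.

## Segmentation

Foreground (animal) pixels are those inside the user-supplied dorsal ROI whose
standardized lightness falls below the background threshold (default 0.92,
separating any plausible skin tone from the white arena) and that are not
saturation-flagged. Foreground pixels are then clustered in RGB space:

1. **k-means++ initialization** (first center uniform; each next center drawn
   with probability proportional to squared distance to the nearest chosen
   center), because plain k-means is sensitive to initialization.
2. **Lloyd's iterations** until the maximum center movement drops below `tol`
   (default 1e-4 RGB units) or `max_iter` (100). Inertia is recorded after
   every assignment and asserted non-increasing. A cluster emptied by an
   assignment step is re-seeded at the point farthest from its assigned
   center. Restarts are configurable (`n_restarts`, default 1; the best
   inertia wins).
3. **Class call**: with the default k = 2 the cluster whose center has lower
   luminance is the melanistic class. "Hierarchical" k-means is implemented as
   bisecting recursion (`max_depth`); the default depth 1 with k = 2 keeps
   the conservative melanin estimate, and deeper splits only refine
   sub-cluster structure — the melanistic/non-melanistic call is always made
   at the top split.

Two rules handle degenerate pattern honestly. If the two top-level centers
differ in luminance by less than `contrast_threshold` (default 10/255), the
image is flagged low-contrast and the melanistic proportion is 0 — essentially
patternless individuals are a real part of leopard-gecko populations and must
not be split arbitrarily (this also resolves the exact tie: a luminance
difference of zero fires the rule). And because unsupervised clustering
misassigns shadowed regions, every segmentation produces a reviewable overlay
plus an accept/reject flag file (`qc_overlay()`, `qc_set_flag()`): the
pipeline never blocks on interaction, rejected images are excluded downstream,
and the number of exclusions is recorded. No additional shadow modelling is
attempted — rejection is the mitigation.

## Quantification

* **Melanistic proportion** = melanistic pixels / all foreground (head +
  trunk + tail) pixels, per image; per individual, the mean and sample SD over
  accepted images, and the natural log of the mean (the scale the models use;
  log(0) is flagged, never silently produced).
* **Body temperature** = mean of the left and right eye surface temperatures
  (the standard internal-temperature proxy for lizards); if an eye is missing
  the snout is the documented fallback (eye and snout temperatures are nearly
  collinear), with a warning.
* **Block summaries** = per-individual means within each of the five blocks.
  A datalogger reading of exactly 0 °C is an instrument failure and is
  excluded and counted; rows from dropped low-quality IR images are excluded
  and counted.
* **Rates**: cooling = block 1 mean − block 3 mean; heating = block 5 mean −
  block 3 mean; both positive under the intended profile (the orientation is a
  package convention — the sign convention is otherwise arbitrary), and
  start-to-end change = heating − cooling by construction. Natural logs are
  attached only to positive rates.

Block membership of the 15 timepoints comes from a schedule table (default:
five consecutive blocks of three), configurable because real protocols may
allocate timepoints unevenly.

## Statistical battery

`run_analysis()` emits, from a per-timepoint thermal table, per-block class
luminances and per-individual covariates:

* Pearson correlations (body vs IR substrate, vs within-terrarium datalogger
  mean, vs atmospheric datalogger, vs humidity; datalogger mean vs IR
  substrate). `r`, `r²` and, in the models, adjusted R² are reported as three
  distinct quantities and never conflated — adjusted R² may legitimately be
  negative, `r²` may not.
* Paired block contrasts (1–3, 3–5, 1–5) for body temperature and for each
  luminance class, gated by Shapiro–Wilk on the paired differences at
  α = 0.05: normal → paired t, otherwise Wilcoxon signed-rank. The gate
  statistic and level are package choices; the gate's p-value is recorded in
  every result. Wilcoxon conventions are the standard R ones (zero differences
  dropped, mid-ranks for ties, exact two-sided p for moderate tie-free n,
  continuity-corrected normal approximation otherwise), pinned by an
  enumeration oracle in the tests.
* Linear models: log rates on mass, SVL, sex, and log proportion; log
  proportion on SVL × sex (treatment contrasts); and luminance change on
  log proportion × body-temperature change, per class and block pair. All
  tests are two-sided with no multiple-testing correction (the analysis is a
  descriptive battery, not a confirmatory family).
* Influence: Cook's distance `D_i = e_i² h_ii / (p s² (1 − h_ii)²)` per
  observation, with `D > 1` flagging an influential individual; the closed
  form is verified against leave-one-out refits to 1e-10 in the tests. At
  n = 12 a single extreme individual can carry a model, so the flags are part
  of every model result.

Note one structural caveat the battery inherits from its design: in
`Δlum ~ log p × ΔT`, the interaction regressor `log p · ΔT` is almost
collinear with the main effect `log p` (ΔT varies little around its ~10 °C
mean), so main-effect and interaction t-statistics come in near-mirrored
pairs. This is a property of the uncentered parametrization, kept
deliberately; it is also why the power analysis below works with the
interaction directly.

## The synthetic generator

`generate_image()` renders an ellipse-chain body (head, trunk, tapering tail)
in near-black spots on a yellow base over a bright background, with a gray
reference patch, smooth shadow gradient, per-frame multiplicative illumination
gain on L, and Gaussian pixel noise. Spots are dart-thrown; the last spot's
radius is tuned by bisection so realized coverage lands within ~0.005 of the
target (contract: ±0.01). Truth masks are re-rasterized per frame, so recorded
true proportions are exact. `generate_image_series()` re-poses one fixed
pattern by mild affine jitter (rotation ±6°, translation ±4 px, shear ±0.04) —
enough to exercise ROI and cropping logic without a deformable body model —
with frame 1 at nominal lighting (gain 1, the standardization baseline) and
later frames drifting in U[0.7, 1.3].

`generate_thermal_cohort()` mirrors the study shape: 12 individuals (7 male),
15 timepoints in five blocks targeting (25, 20, 15, 20, 25) °C, melanistic
proportions spanning 0.01–0.41 with nine at or below 0.11, two dropped
low-quality IR images and one zeroed datalogger reading (so the 178- and
179-point filter contracts are exercised), per-eye noise around a latent body
temperature, offset dataloggers (atmospheric lower than terrarium), and an
uncorrelated humidity process. Injection hooks add effects of log proportion
on heating rate and on heating-phase luminance change (main + interaction
with ΔT), plus an optional extreme responder for influence diagnostics.

What the generator does *not* emulate: articulated posture (affine only),
specular highlights and real shadow geometry, camera response nonlinearity,
UV/multispectral channels, and radiometric IR physics (temperatures enter as
already-extracted numbers). Passing the recovery suites therefore shows the
pipeline is correct *given* its photometric model, not that segmentation of
difficult real photographs (deep shadows, soft pattern edges) is error-free —
that is what the QC step exists for.

### Calibration of injected effects

Between-individual SD of block-mean body temperature defaults to 0.8 °C:
individuals position themselves freely relative to the heat pad and hide, so
their realized block means spread far more than the IR measurement noise
(~0.15–0.25 °C per reading). This matters statistically: the luminance-change
models use the *observed* block-mean ΔT, so the informative variation in the
interaction term must dominate its errors-in-variables noise.

The power suite's stated effect size — `effect_interaction = 0.05` with
`effect_lum_slope = −0.5`, i.e. `Δlum = 0.05 · log p · (ΔT − 10)` — was chosen
by an a-priori simulation at n = 12 under exactly these conditions to give
roughly 0.9 power for the interaction term, and frozen. The acceptance script
recomputes both the null rejection rate (~0.05) and this power on 100 freshly
seeded cohorts each run.

## Numerical choices and degenerate inputs

* HLS saturation is clamped at 1 inside `rgb_to_hls()`: the hexcone
  denominator cancels catastrophically for near-extreme lightness and can
  overshoot by ~1e-9 in floating point; mathematically S ≤ 1 always.
  `hls_to_rgb()` tolerates 1e-9 overshoot and rejects anything larger.
* The rgb↔hls round trip is tested below 1e-9 on dense random samples.
* k-means ties in assignment go to the lowest cluster index; duplicated
  centers therefore empty the higher one, which the farthest-point re-seed
  repairs.
* A zero-variance difference vector, a constant correlation input, a black
  reference patch, an empty ROI/foreground, fewer distinct pixels than k, and
  a missing block all raise errors rather than propagating NaN.
* A numerically perfect OLS fit reports all Cook's distances as 0 (deleting a
  point moves nothing); an exact-fit point with leverage 1 reports Inf.
* Seeded code paths (k-means++, generators) save and restore the caller's RNG
  state.

## Problem sizes

The shipped tests segment 160×120 px scenes (≈2 400 body pixels), run the
recovery suite on 24 images spanning coverage 0–0.45, a 15-frame illumination
series, and two 100-cohort simulation suites; the acceptance script
additionally processes a full 12 × 15-frame study. These sizes were chosen so
the whole battery completes in a few minutes on one core while every contract
(coverage ±0.01, recovery MAE ≤ 0.035, type-I ≈ 5%, power ≥ 0.8) is exercised
at the study's own n.

## Known limitations

* Luminance comparisons are within-individual by construction; the package
  refuses cross-individual luminance use rather than attempting a full color
  calibration (which would need a multi-patch target, not a single gray).
* The segmentation is binary (melanistic vs not); graded or layered pattern
  classes are out of scope.
* Whether to cluster the first frame on raw or standardized RGB is ambiguous
  in principle; the package always clusters after standardization (frame 1's
  standardization is the identity, so this is also the simplest consistent
  rule).
* The 3-per-block default schedule is an assumption; real protocols should
  supply their schedule explicitly.
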