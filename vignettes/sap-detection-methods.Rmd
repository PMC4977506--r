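---
title: "Detecting stretch-attend posture: model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stretch-attend posture: model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sapdetect)
```

## The detection model

Stretch-attend posture (SAP) has two visual signatures from above: the
body is *elongated*, and the animal is *nearly stationary* (standing or
creeping). The detector therefore reduces each frame to two scalars — the
eccentricity of the body's equivalent ellipse and the centroid speed — and
declares SAP when the first is high and the second low:

$$\text{SAP}_i \;=\; \big[e_i > e_{\mathrm{thr}}\big]\;\wedge\;
\neg\big[v_i > v_{\mathrm{thr}}\big]\;\wedge\;\text{valid}_i .$$

Both comparisons are strict, so a frame exactly at a threshold is not
elongated and not vetoed. The speed veto exists because a running mouse is
also elongated; without it, every sprint would be scored as risk
assessment.

**Assumptions.** One animal per arena; a fixed overhead camera; the animal
brighter than the floor after optional inversion; an empty-arena frame
available (stored as the last TIFF page); the video cropped to the arena
with square pixels (the loader enforces per-axis calibration agreement
within 2%). Intensities are normalized to [0, 1] whatever the source bit
depth, so the binarization threshold is dimensionless.

### Segmentation

The mask is `max(frame − background, 0) > t`. Clamping at zero reflects
the bright-animal assumption: negative residuals can only be noise or
illumination drift. The floor pattern (e.g. a painted grid) cancels in the
subtraction except where the body covers it, where the difference is
reduced but still large; `sweep_thresholds()` exists to pick `t` on the
plateau between "floor noise floods in" and "the body erodes away".

The tail is removed by morphological opening with a disk. Opening deletes
any structure thinner than the disk diameter while restoring the body's
girth: the disk radius must exceed the tail half-width and stay well below
the body half-width. The default is physical, 0.25 cm, converted to pixels
through the calibration (minimum 1 px), so the same setting works at any
resolution. A small tail stub sometimes survives; it shifts eccentricity
by well under the threshold margin (the tailed/tail-free twin scenarios in
the test suite bound the effect at 0.03).

Out-of-frame pixels count as background during the opening (the mask is
padded before erosion), so an animal touching the wall is treated the same
as one in the open.

The largest 8-connected component is kept. 8-connectivity matches blob-
tracking practice; an exact size tie (possible in principle on synthetic
input) is broken deterministically toward the component whose topmost-
then-leftmost pixel comes first, so batch output is reproducible. An empty
mask — the animal absent, e.g. reared against a matching wall — marks the
frame invalid rather than aborting: invalid frames are non-SAP, break
bout runs, and restart the speed at zero.

### Ellipse, eccentricity, speed

The ellipse comes from second central moments: the 2×2 covariance of the
pixel coordinates, with +1/12 added to both diagonal terms (the variance
of a unit square pixel about its center), eigen-decomposed; axis lengths
are $4\sqrt{\lambda}$ and $e=\sqrt{1-\lambda_2/\lambda_1}$. This is the
convention of the standard region-properties routines, and it is exact in
the limit for ellipse-shaped regions: rendered ellipses with semi-major
axis ≥ 20 px recover their analytic eccentricity within 0.02 in our
tests (typically within 0.005), independent of rotation and sub-pixel
translation.

Speed at frame $i$ is the centroid displacement from frame $i-1$ times
cm/px times fps, assigned to the **later** frame. The first valid frame,
and the first frame after an invalid gap, get speed 0 — a permissive
choice: a still animal that reappears should not be speed-vetoed for
having "teleported" across the gap.

### Bout filter and per-second scores

SAP is assumed never to last half a second or less, so maximal runs of
positive frames of length ≤ `round(fps/2)` are erased. The comparison is
"≤", so at 10 fps a 5-frame run is erased and a 6-frame run survives; at
odd frame rates the rounding makes "half of the fps" an integer. The
filter runs *after* the gating (the conjunction itself is order-free), is
idempotent, and never creates positives.

Human raters score per second, so frame flags are aggregated by the
**at-least-one-frame rule**: a second is positive iff any of its frames
is. A trailing partial second is aggregated the same way. Note the rule is
deliberately asymmetric — one positive frame among ten makes a positive
second — because that is how the reference scores are defined.

Per video we report duration (positive frames / fps — the canonical,
frame-based definition), the positive-second count (what a rater panel
produces; both are emitted since either convention is found in practice),
SAP percentage, bout count and bouts/min. Bouts are counted at frame
resolution: automated detection splits events that a human, subject to
perceptual closure, would merge, so the automated frequency runs higher
than consensus frequency even when durations agree. Keeping frame
resolution preserves that sensitivity rather than smoothing it away.

## Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| `binary_threshold` | intensity in (0,1) | none — must be set | contrast-dependent; choose with `sweep_thresholds()` |
| `morph_radius_cm` | cm | 0.25 | > tail half-width (~0.2 cm), ≪ body half-width (~1 cm) |
| `ecc_threshold` | — | 0.90 (OF), 0.89 (EPM) | adult-mouse elongation; EPM lowered because animals bend toward open arms, shortening the ellipse |
| `speed_threshold_cms` | cm/s | 12 (OF), 8 (EPM) | separates creeping from running; lower in the EPM's 5-cm arms where momentum is limited |
| `fps` | s⁻¹ | 10 | the minimum customary for spatiotemporal scoring; drives the bout filter length |

Thresholds are specific to species, strain, sex and weight. For anything
other than ~32–40 g adult mice, re-derive them: score a few videos (or
seconds) by hand, then `optimize_on_videos()` sweeps a threshold grid,
computes the MCC of each pair against the reference, and returns the
argmax. MCC is the right objective because SAP seconds are rare; accuracy
would be maximized by predicting "never SAP". Grid ties are broken toward
the higher eccentricity then higher speed threshold — the more specific
detector — and the companion ROC table (trapezoidal AUC) shows the
sensitivity/specificity trade-off around the optimum.

## Evaluation statistics

Consensus is a strict majority of raters; with an even panel an exact tie
resolves to 0 (declaring SAP requires a majority, and the tie rule is
conservative about calling the behavior). Proportion metrics get Wald
intervals $p \pm z\sqrt{p(1-p)/n}$, adequate at whole-study second counts
(n ≫ 30, p away from the boundary); the default level is 0.95, with 0.99
available — published interval tables in this area are consistent with
z = 2.576. MCC with any zero marginal is returned as 0 (undefined
correlation treated as absence of correlation). The F-score with no
predicted positives is 0 with a warning.

Inter-rater reliability is ICC(A,k): two-way model, absolute agreement,
average of the k raters' scores, computed from the balanced two-way ANOVA
mean squares
$$\mathrm{ICC}(A,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n},$$
with seconds as subjects. The binary scores are fed to this
continuous-model statistic as-is — standard practice for rater panels,
though strictly the model assumes Gaussian components. Perfect agreement
gives exactly 1 (the formula reduces to $MS_R/MS_R$); an all-constant
panel is degenerate and returns `NA` with a warning.

## What the synthetic generator does and does not emulate

`synth_scenario()` renders a bright filled ellipse (the body) with an
attached tapering, quadratically curled tail polyline, over a dark floor
with an optional painted grid, plus seedable additive Gaussian pixel
noise; the last page is the noise-free empty arena. Geometry defaults
follow a typical open-field recording: 30 cm square arena, 10 fps, 150 px
frames (0.2 cm/px), body sized for an adult mouse (~7 cm elongated). The
scenario schedules (semi-axes, heading, trajectory) are the ground truth:
per-frame eccentricity is computed analytically from the semi-axes, speed
from the trajectory, and the SAP labels by applying the gating rules to
those analytic traces — never from the rendered pixels, so a rendering
change cannot silently shift the labels.

`standard_suite()` fixes seven scenarios spanning the regimes the gate
must separate (round/still, elongated/still, elongated/fast, sub-half-
second burst, a mixed schedule, a tail-free twin, and a noisy replicate at
`noise_sd` 0.05). Detector-vs-truth per-second agreement on this suite is
the end-to-end test (thresholds ≥ 95% clean, ≥ 90% noisy; the current
implementation attains 100% on both).

What is *not* modeled, and therefore what passing these tests does not
demonstrate: non-elliptical postures (rearing, grooming, bent SAP around
corners), motion blur, shadows and reflections, illumination drift between
the background frame and the video, occlusion by maze walls, and fur
texture. Real-video performance still depends on a well-chosen
binarization threshold and an honest background frame; the synthetic suite
validates the algorithmic chain, not the robustness of segmentation to
poor imaging.

## Numerical and design choices

- **Problem sizes.** Tests render 150 px frames and 5–12 s clips (the
  suite is ~420 frames), fit ellipses on ≤ 120 px grids, and use 800
  subjects × 3 seeds for the ICC simulations — sizes at which every
  quantity under test is already in its asymptotic regime.
- **Threshold recovery** is exercised with staircase scenarios whose
  analytic labels straddle the generating pair (0.90, 12 cm/s):
  eccentricity levels {0.86, 0.895, 0.905, 0.95} at rest and speed levels
  {0, 11, 13, 20} cm/s while elongated, on a grid with steps (0.01,
  1 cm/s). Recovery is asserted within one grid step; measurement bias of
  the rendered eccentricity (≲ 0.005, tail stub included) is well inside
  that slack.
- **Monte-Carlo tolerances.** The simulated ICC(A,2) has a sampling SD of
  ≈ 0.064 at 800 subjects (dominated by drawing only 2 rater effects);
  3-seed means are compared within 3 standard errors (0.11 for k = 2,
  0.04 for k = 5).
- **Quantization.** 8-bit TIFF round-trips are compared with absolute
  tolerance 1/255; the writer truncates rather than rounds.
- **Degenerate inputs.** Empty masks signal "no animal" instead of
  erroring; a video with no valid frame at all errors; `mcc` and
  `f_score` handle empty marginals by convention as above; the ROC
  surface with an everywhere-undefined MCC errors.
- **Orientation convention.** Angles are measured from the +x image axis
  with y pointing down the rows, reported in (−π/2, π/2]. The synthetic
  renderer uses the same convention, so heading round-trips through the
  fitter.

## Known limitations

Single-animal scenes only; no protected/unprotected SAP zoning or
directional (forward) SAP — both need spatial context the gate does not
use; no native reading of container formats (convert to multi-page TIFF
first); thresholds must be re-derived per animal population; and the
per-second agreement metric inherits the rater panel's one-second
granularity, so sub-second timing disagreements are invisible to it.
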