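# sapdetect

Automated detection of **stretch-attend posture (SAP)** in overhead rodent
videos, with the statistics needed to validate the detector against human
raters.

SAP is a risk-assessment behavior — the animal lowers its back, elongates,
and stands still or creeps forward — scored in anxiety assays such as the
open field (OF) and the elevated plus maze (EPM). It is a more sensitive
readout of anxiolytic drug effects than classical spatiotemporal measures,
but scoring it by eye is slow (10–45 min per 5-min video), fatiguing and
subjective. `sapdetect` scores it automatically, deterministically, and in
seconds, for anyone with an overhead grayscale video and a frame of the
empty arena.

## Method

Videos are multi-page TIFF stacks: every page is a frame, the **last page
is an image of the empty arena** used for background subtraction. Per
frame the pipeline is

1. **Segment**: clamp-subtract the background, threshold to a binary mask
   (`max(frame − background, 0) > t`, threshold chosen with the headless
   previewer `sweep_thresholds()`);
2. **Remove the tail** by morphological opening with a disk (default
   radius 0.25 cm, converted to pixels by the arena calibration) — the
   tail otherwise distorts the fitted ellipse;
3. **Keep the largest 8-connected component** and fit its moment ellipse:
   with eigenvalues λ₁ ≥ λ₂ of the pixel-coordinate covariance (+1/12
   pixel-variance correction), axis lengths are 4√λᵢ and eccentricity is
   e = √(1 − λ₂/λ₁) — 0 for a circle, → 1 for a line;
4. **Speed**: centroid displacement between consecutive frames × cm/px ×
   fps;
5. **Gate**: a frame is SAP iff `e > e_thr` (elongated) **and not**
   `speed > v_thr` (a fast elongated animal is running, not stretching);
6. **Bout filter**: SAP cannot last ≤ 0.5 s, so runs of positive frames of
   length ≤ round(fps/2) are erased;
7. **Aggregate**: a second is SAP-positive iff at least one of its frames
   is; per video the duration (s), percentage, bout count and bouts/min
   are summarized.

Default thresholds `e_thr = 0.90`, `v_thr = 12 cm/s` suit adult mice
(~32–40 g) in an open field; `0.89` and `8 cm/s` suit the plus maze, where
animals bend toward the open arms and have less room to accelerate.
`optimize_on_videos()` re-derives thresholds for other animals by
maximizing the Matthews correlation coefficient (MCC) against reference
scores over a threshold grid, alongside ROC curves with trapezoidal AUC.

For validation against human scoring, the package builds majority-vote
consensus from rater panels, confusion-matrix metrics (accuracy,
sensitivity, specificity) with Wald binomial intervals, F-score, MCC, and
the two-way agreement average-measure intraclass correlation ICC(A,k) for
inter-rater reliability. A synthetic video generator (`synth_scenario()`,
`standard_suite()`) renders calibrated mouse-like scenes with *analytic*
ground truth, so every stage is testable offline.

## Worked example

Generate the synthetic test battery, run the batch detector over the
folder, and read the summary:

```r
library(sapdetect)
suite <- standard_suite(seed = 1)
d <- file.path(tempdir(), "demo"); write_suite(suite, d)
cfg <- batch_config(d, file.path(d, "out"), fps = 10,
                    arena_width_cm = 30, arena_height_cm = 30,
                    binary_threshold = 0.4)
summary <- run_batch(cfg)
print(summary, digits = 3)
```

```
              video video_length_s duration_s sap_percent positive_seconds
1  brief_elongation              5        0.0         0.0                0
2    fast_elongated              5        0.0         0.0                0
3             mixed             12        6.1        50.8                7
4       noisy_mixed             12        6.1        50.8                7
5       still_round              5        0.0         0.0                0
6 still_sap_no_tail              5        5.0       100.0                5
7         still_sap              5        5.0       100.0                5
  bouts freq_per_min n_invalid_frames
1     0            0                0
2     0            0                0
3     2           10                0
4     2           10                0
5     0            0                0
6     1           12                0
7     1           12                0
```

Reading the rows: the stationary round animal and the fast elongated one
are never SAP (the latter is speed-vetoed); a 0.3-s elongation burst is
erased by the bout filter; the stationary elongated animal is SAP 100% of
the time whether or not it has a tail (tail removal works); the `mixed`
schedule alternates all regimes and is scored identically with and without
pixel noise. Each video also gets `<name>_frames.csv` (per-frame
eccentricity, speed, validity, SAP flag), `<name>_seconds.csv`, and a
three-panel plot of eccentricity, speed and detection against time.

A shell front end with `detect`, `preview`, `evaluate`, `optimize` and
`synth` subcommands is installed at `inst/scripts/sapcli.R`.

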