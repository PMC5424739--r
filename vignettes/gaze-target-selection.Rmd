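---
title: "Detecting intentional gaze for target selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intentional gaze for target selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazefuzz)
```

## The problem

A gaze tracker that selects whatever the user looks at suffers from the
Midas-touch problem: every glance becomes a command. Dwell-time triggers
trade this off against speed and fatigue. `gazefuzz` implements a
multi-modal alternative for near-infrared (NIR) camera trackers: a short
(10-frame, ~333 ms at 30 fps) window is scored on three concurrent cues —
the transient pupil constriction that accompanies a cognitively intentional
fixation, the stillness of the gaze itself, and the texture content of the
screen region under the gaze — and a Mamdani-style fuzzy system fuses the
three into a selection score.

## Pipeline

### Pupil and glint segmentation

Each eye frame (8-bit grayscale, pre-cropped around the eye) passes through:

1. dark-region binarization (Otsu's histogram threshold by default, a fixed
   intensity via `binarize.threshold`),
2. morphological opening (disc, radius 2 px) and a 3×3 binary median
   (majority) filter, keeping the largest connected component,
3. a circular Hough transform (CHT) over a configurable radius range
   (default 12–30 px for the pupil) voting from boundary pixels, giving a
   rough center and radius,
4. a two-phase active-contour refinement restricted to an *adaptive mask* —
   a disc centered on the rough circle with radius 1.5× (pupil) or 2.0×
   (glint) the rough radius — minimizing the piecewise-constant energy
   `mu·Length(C) + λin·Σin (u−cin)² + λout·Σout (u−cout)²`.

The glint (corneal reflection of the NIR illuminator) follows the same
path inside an eye ROI, with bright-spot thresholding at
`max(0.9 × ROI maximum, 180)`. The absolute floor exists because on a
glint-free frame 0.9× of the maximum selects ordinary iris pixels; NIR
glints are near-saturation, so 180 of 255 is a physical bound. The glint
refinement mask has a minimum radius of 8 px so an undershooting rough
radius still leaves the contour room to grow back.

Pupil size is the pixel count inside the refined pupil boundary — not an
ellipse fit, since real pupils are not elliptical — with glint-overlap
pixels excluded. The pupil boundary is hole-filled before its centroid and
area are taken, so a glint inside the pupil does not bias the center.

**Numerical scheme.** The contour energy is minimized by checkerboard
sweeps of single-pixel label flips, each accepted only when it strictly
lowers the discrete energy (curve length = count of 4-adjacent label
discordances). This makes the energy provably non-increasing per iteration
and convergence finite — properties a PDE time-stepping discretization only
approximates. On this discrete scale the length weight acts per boundary
edge: a flip that advances a flat front trades a data gain of `(Δu)²`
(≈0.14 for the pupil–iris contrast) against ~2 edges of penalty, so the
default is `mu = 0.05` (λin = λout = 1, intensities normalized to [0,1]);
`mu = 0.25` would stall convex fronts. Iteration stops when fewer than
0.1% of mask pixels flip (cap 200 sweeps).

### Feature 1 — pupil accommodation

The pupil-size series is smoothed by a 3-tap uniform moving average
(truncated, renormalized endpoints), the 10-frame window anchored at the
fixation onset is min-max normalized to [0, 1], and its summed squared
difference (SSD) to each of three constriction templates is minimized. The
templates are length-10 "constrict then partially recover" profiles (fast,
middle, slow dip; minimum at positions 3, 5, 7; recovery to 0.6), stored in
`inst/extdata/templates_default.csv` so calibrated banks can be
substituted. A low score means the window looks like an intentional
constriction.

Two degenerate-window rules apply. A constant window normalizes to all
zeros (no accommodation evidence). Additionally, a window whose
peak-to-peak amplitude is below 5% of its mean (`features.min_amplitude_frac`)
is treated the same way: min-max normalization is amplitude-invariant, so
without this gate sub-physiological sensor noise would be rescaled into
full-range curves that occasionally match a template as well as a real
constriction. Intentional constrictions are ~20% of pupil area, an order of
magnitude above the gate.

### Feature 2 — gaze change over a short dwell

The pupil center is compensated by the glint center (vector difference),
which cancels head translation. A 4-point calibration maps compensated
positions to monitor coordinates through the bilinear form
`Gx = a·x + b·y + c·xy + d`, `Gy = e·x + f·y + g·xy + h`, solved exactly
from the four corner correspondences; two-eye systems average the two
monitor-space gaze points. Feature 2 is the sum of per-frame Euclidean gaze
changes `Δz` over the window — the Euclidean distance, so a (3, 4) px
movement counts 5, not 4.

The window anchor is the first frame of the longest run with
`Δz < 5` monitor px/frame (`features.still_threshold`). Inside the
pipeline, an event with no sufficiently long run falls back to its
lowest-total-change candidate window (flagged `fixation_found = FALSE`)
rather than being dropped, so noisy sessions degrade gracefully instead of
losing events.

### Feature 3 — monitor texture at the gaze point

A bank of `K × (P+1) = 16` real-part Gabor wavelets (4 orientations
`θ = nπ/4`, 4 amplitude scales `a^{-m}` with `a = √2`) is applied to a
101×101 px ROI centered on the gaze point, and the mean absolute response
over kernels and pixels is Feature 3. Defaults `σx = σy = 2` px and radial
frequency `W = 0.25` cycles/px span edge-like structure at the scale of
on-screen objects (the tracker's ±1° accuracy is ≈82 px at 70 cm; the ROI
is comparable). Each kernel is DC-removed so a blank region scores exactly
0; responses use reflect padding. None of these constants are critical —
the feature is only compared across regions of one screen.

## Fuzzy fusion

Raw features are min-max scaled by their training ranges, clipped to
[0, 1], and features 1 and 2 are inverted (`f ← 1 − f`) so that for all
three, larger = more selection-like. Each feature has complementary linear
Low/High membership ramps (Low: 1 on `[0, a]`, 0 after `b`; High the
mirror). The eight rule combinations map to output labels

| f1 | f2 | f3 | out |  | f1 | f2 | f3 | out |
|----|----|----|-----|--|----|----|----|-----|
| L  | L  | L  | L   |  | H  | L  | L  | L   |
| L  | L  | H  | L   |  | H  | L  | H  | M   |
| L  | H  | L  | M   |  | H  | H  | L  | H   |
| L  | H  | H  | H   |  | H  | H  | H  | H   |

with per-rule inference values (IVs) combined by MIN (default) or MAX.
Output membership functions on [0, 1] are: L descending 1→0 over [0, 0.5],
M triangular with apex (0.5, 1), H ascending 0→1 over [0.5, 1]. Per-label
aggregation takes the maximum IV (standard Mamdani max-aggregation), each
output MF is clipped at its label's height, and the union region (overlaps
counted once) is reduced by FOM, MOM, LOM, COG (default) or BOA. COG and
BOA are computed in closed form on the piecewise-linear union; tests check
them against a trapezoidal-integration oracle. All-zero IVs score 0; a
selection requires `score > threshold` (strict; default 0.3, the COG/MIN
operating point).

```{r example}
params <- example_membership_params()
infer_ivs(c(0.30, 0.50, 0.45), params, mode = "MIN")
defuzzify(infer_ivs(c(0.30, 0.50, 0.45), params, mode = "MIN"), "COG")
```

Note the rule base is deliberately two-of-three: (L,H,H) and (H,H,L) fire
H. A monotone response to any *single* feature is therefore not a property
of this system — rule (H,L,L)→L means a rising f1 can raise the Low
aggregate when f2 and f3 are low — and the package's property tests assert
the sound bound (all-Low and all-High corners bound and attain the score
range) rather than per-feature monotonicity.

### Membership calibration

Three calibrations are available via `fuzzy.membership`:

* **`"gap"` (pipeline default).** Per feature, if the labelled training
  classes separate (every non-gazing value below every gazing value by at
  least 0.01 on the normalized scale), the ramps span exactly that gap.
  Otherwise the feature falls back to `"cluster"`. The dwell feature
  legitimately overlaps across classes — an unintentional fixation is as
  still as an intentional one — and is the usual fallback case.
* **`"cluster"`.** Unsupervised: Otsu's threshold splits the feature's
  pooled distribution and the ramp spans the gap between the two clusters
  (minimum width 0.05). Low/High linguistic classes are identified with the
  feature's own modes.
* **`"entropy"`.** The literal maximum-entropy criterion: grid search of
  the ramp knees (step 0.01, histograms binned at 0.01) maximizing
  `−pL·log pL − pH·log pH`, where `pL` is the non-gazing distribution
  integrated against the Low ramp and `pH` the gazing distribution against
  the High ramp. The two terms depend on disjoint parameters, so each ramp
  is optimized independently (equivalent to the joint search; continuity
  fixes the slope/intercept pairs, so `(p, q)` are not free parameters).
  Each term's unconstrained maximum is at coverage `1/e`, which on sharply
  clustered data drives the ramps onto slivers at the class edges; this is
  why it is not the pipeline default, but it is retained as an exported,
  fully tested operation for broad, overlapping empirical distributions
  like those the method was designed on.

`example_membership_params()` is a fixed illustrative set (complementary
ramps over [0.2, 0.6], [0.1, 0.4], [0.11, 0.61]) that reproduces the
worked-example degrees above; it is a demonstration fixture, not a
calibrated system.

## Evaluation

A type I error misclassifies an intentional selection gaze as non-gazing; a
type II error selects a non-gazing episode. `compute_eer()` sweeps every
distinct score as a threshold, picks the one minimizing |type I − type II|
(ties to the lower threshold), and averages the two. `roc_curve()` reports
(100 − type II, type I) per threshold; with the strict decision rule its
attainable extremes are (0, 0) (everything selected) and (100, 100)
(nothing selected), and perfectly separable scores pass through (100, 0).

`noise_experiment()` adds zero-mean Gaussian noise to the detected pupil
sizes (area pixels — pupil size is a pixel count) and to each gaze
coordinate (monitor px), re-extracts features, re-calibrates, and reports
EER per sigma. Sigma levels share common random numbers (one standard
normal draw per replicate, scaled), a paired design that removes
between-level sampling noise from the comparison. Re-calibrating per run
reflects a tracker operated and calibrated under that noise level; pass a
frozen `fs` to evaluate a fixed calibration instead (with clipped
normalization a frozen calibration can paradoxically score *better* at high
noise, because saturation wipes a partially-misleading feature).

## The synthetic session generator

`gen_session()` is the package's ground truth. It emulates:

* eye frames: mid-gray iris (120), dark pupil disc (25, radius ~22 px in a
  160×120 frame), near-saturated glint (250, radius 4), additive Gaussian
  sensor noise (default σ = 5), optional chord-cut non-elliptical pupils;
* a monitor (1680×1050, the published setup) with nine texture patches on a
  3×3 target grid (smoothed-noise patches, ~110 px, comparable to the 82-px
  angular-accuracy scale);
* events of 16 frames: a 4-frame saccade lead-in, then for positive events
  a fixation (per-coordinate jitter 1 px) on a textured target with a
  20%-area template-shaped pupil constriction starting at fixation onset;
* negative events alternating between a fixation without constriction on a
  blank region and a wandering gaze (28 px/frame) across the textured area;
* physiological pupil-area noise (σ = 6 px) throughout;
* a rectangle-to-rectangle eye-to-monitor correspondence, so the generating
  bilinear model is exactly invertible and glint drift (slow common motion
  of pupil and glint) tests head-movement compensation end to end.

Because the rule base fires H on (L,H,H) and (H,H,L), a non-intentional
fixation *on texture* would be selected by construction; the generator's
negative classes are therefore the non-gazing behaviors that the selection
logic is designed to reject. What passing tests show is that every stage
computes what it claims and that the pipeline separates these synthetic
conditions; they do not show field performance on real eyes — real
pupillometry has hippus, blinks, and eyelid occlusion (explicitly out of
scope), and real negatives include attentive fixations on textured content
that this rule base will select.

## Problem sizes and determinism

Everything is integer-seeded (`set.seed` per frame/replicate, no
time-based state); the same seed reproduces sessions, frames and CSV
artifacts byte-identically. The shipped checks use: 100 rendered frames
(noise σ = 10) for segmentation accuracy, a 40-event session (640 frames)
for the end-to-end run, 10 replicates × 4 sigma levels for the noise
experiment, and 1000 random IV sets for the defuzzifier oracle. A 640-frame
session segments in well under a minute on one core.

## Known limitations

* Whole-face eye localization, blinks and eyelid occlusion are out of
  scope; frames must be pre-cropped around the eye.
* The min-max window normalization of Feature 1 discards amplitude; the 5%
  amplitude gate is a pragmatic guard, and very slow constrictions spread
  over more than one window are not modelled.
* Calibration is exactly 4-point bilinear; no regularization, no Z-distance
  compensation beyond glint subtraction.
* The entropy calibration is faithful to its defining formulas, including
  their degenerate behavior on well-separated data (see above).
* EER resolution is bounded by event count (2.5% steps at 40 events).
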