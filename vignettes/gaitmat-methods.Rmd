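---
title: "Processing pressure-walkway recordings with gaitmat"
author: "gaitmat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing pressure-walkway recordings with gaitmat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmat)
```

## The measurement and the processing problem

A pressure-sensing walkway is a floor-mounted grid of piezoresistive sensors
that records a movie of plantar pressure: at every frame (here 100 Hz) each
sensor reports a pressure in kPa, quantized to the instrument resolution
(10 kPa) and clipped to its sensing range (0–1510 kPa). The default
`WalkwayGeometry` models a 2 × 6 arrangement of 60 cm tiles, each a 120 × 120
sensor grid at 0.5 cm pitch: 720 × 240 = 172,800 sensors over a
1.2 m × 3.6 m active area. A walking trial is a rank-3 tensor
(frames × 720 × 240); a participant walks back and forth along the long (y)
axis, so one trial contains several *passes*, each with 4–6 consecutive
footsteps.

Everything downstream takes the geometry as an argument, so the whole pipeline
runs unchanged on reduced grids; the test suite uses quarter-resolution tiles
for speed, and the defaults reproduce the full instrument.

Coordinate conventions used throughout: frames are matrices with rows = y
(long axis) and columns = x; metadata indices are 0-based and inclusive;
tiles are numbered in reading order with Tiles 1–2 at y = 0, so
Orientation = 1 means walking toward increasing y; when walking toward +y the
walker's left side is at larger x. The last convention is arbitrary (the
instrument does not define a handedness); it only has to be used consistently
by the simulator and the side classifier.

## Footstep detection and tracking

Per frame, sensors are *active* when pressure ≥ 10 kPa (the instrument's
activation threshold; with 10 kPa quantization, `>=` keeps the smallest
nonzero reading active). The binary frame is dilated with a circular
structuring element of radius 4 and eroded with radius 2 (Euclidean discs,
dx² + dy² ≤ r²), connected components are labeled under 8-connectivity
(diagonal neighbours, i.e. pixels within two orthogonal hops), components
smaller than `minPixels` (default 5; unstated in the source protocol, needed
so single-frame noise specks cannot seed tracks) are dropped, and components
whose centroids lie within 20 px are merged transitively (union–find) — heel
and forefoot of a high-arched foot or shoe often form separate components.
Morphology uses zero-padded borders (pixels outside the grid count as
background), the convention of the standard scientific image stacks; note
that boxes are measured on the processed mask and are therefore ~2 px larger
than the raw activity, and conversely set back ~2 px from the grid edge where
the foot is cut by it.

Objects are linked over time SORT-style: a constant-velocity Kalman filter
per track over (center y, center x, box area, aspect ratio) predicts each
track's box one frame ahead; detections are associated to predictions by
intersection-over-union (greedy matching, threshold 0.3); unmatched
detections spawn tracks and tracks unmatched for more than `maxAge = 3`
frames terminate. Tracks with fewer than `minHits = 3` matched frames are
discarded. These are conventional SORT settings; the source protocol does not
state its values. Each surviving track is one candidate footstep: its
StartFrame/EndFrame are the first/last matched frames, its spatial box the
union of member boxes, and its tensor is cropped from the raw frames with
pixels outside the track's masks zeroed.

Passes are assigned by scanning footsteps in StartFrame order: the pass id
increments when no footstep is in contact for at least `gapFrames`
(default 100, i.e. 1 s — turns take about 2 s) or when the walking direction
flips between consecutive steps.

## Labels

**Orientation** compares the anteroposterior (y) center of pressure at the
beginning and end of the stance; the means over the first and last 10% of
frames are compared rather than single frames, which is robust to
touchdown/lift-off flicker. **Side** aligns the step upright and splits the
middle third of the sole length into two lateral halves; the half with fewer
activated sensors is the medial (arch) side, and medial-on-the-left of a
toe-up image means a right foot. This is one concrete instantiation of
"counting activated sensors beneath different regions of the foot"; it is
deliberately isolated behind `labelSide()` so an alternative classifier can
be swapped in. Its accuracy depends on arch asymmetry: it is exact on
simulated feet with `archDepth` ≥ 0.5 and degrades toward chance as the
midfoot becomes symmetric (`archDepth` → 0), where ties are resolved as
"Right" with a message. **Incomplete** combines a time rule (StartFrame = 0
or EndFrame = last frame of the actual recording) with an area rule for steps
near a grid boundary (within 3 px, covering the erosion set-back): flagged
when the activated-sensor count falls more than three scaled MADs below the
trial median. **Standing** (slow-to-stop trials only) fits a least-squares
slope to the AP COP of each step; walking steps progress heel-to-toe while
standing steps do not, so steps whose |slope| deviates from the trial median
by more than three scaled MADs are standing. Throughout, "scaled MAD" is
1.4826 × MAD, the normal-consistency scaling; if the MAD is zero the standing
rule falls back to an absolute tolerance of 0.01 px/frame.

Both MAD rules are per-trial robust statistics and assume anomalies are a
minority; like any median/MAD estimator they break down as the anomalous
fraction approaches half the trial.

## Quality scoring

Each footstep is reduced to three characteristics: the number of sensors
active at any time during the step (spatial), its duration in frames
(temporal), and its vertical ground-reaction-force profile resampled to 101
points (amplitude). The trial's reference is the per-feature median over
steps not already flagged standing or incomplete (element-wise median for the
GRF profile). Each step gets three robust deviations — count and duration
robust z-scores against the non-excluded pools, and the robust z-score of the
RMS distance between its GRF profile and the median profile — and

R = sqrt((z_count² + z_duration² + z_GRF²) / 3) ≥ 0,

which for approximately normal measurements reads as "standard deviations
from the trial center". Steps with R ≥ 2.0 are outliers, and
Exclude = Standing OR Incomplete OR Outlier. The exact aggregation of the
three characteristics is not recoverable from the source description; the
RMS-of-robust-deviations form above satisfies every stated property
(per-trial, median reference, three characteristics, ≈ SD units,
nonnegative) and is isolated behind `rScores()` so that, e.g., a
Mahalanobis-style variant could replace it. GRF profiles are compared after
temporal normalization so duration enters the score only once. When a pool's
MAD is zero, scores are 0 at the median and ±Inf elsewhere — a degenerate
trial, reported rather than masked.

## Normalization menu

`runPipeline()` applies an explicit ordered list of operations:

* **rotate** — principal-axis alignment. The first PC of the unweighted
  active-pixel coordinates (union over stance) defines the foot axis; every
  frame is rotated by nearest-neighbour inverse mapping so the axis is
  vertical, then the stack is rotated 180° if the walking direction implies
  the toe points down. Nearest-neighbour resampling preserves pressure values
  and their quantization. Unweighted (binary) PCA is used rather than
  pressure-weighted — it is insensitive to amplitude artifacts; a weighted
  variant sits behind a flag. The reported RotationAngle is the signed angle
  between the axis and the grid long axis, in (−90°, 90°], positive toward
  +x. Nearly isotropic pixel clouds (eigenvalue ratio < 1.05) get angle 0
  with a warning.
* **pad** — zero-pad each frame to H × W (75 × 40 for the presets) with the
  content centroid at the canvas center; exact, conserves each frame's total
  pressure.
* **resize** — rescale so the measured sole dimensions (maximum count of
  active pixels along each aligned axis) reach 70 × 25 px, nearest-neighbour.
  Because sole dimensions are counts while the canvas needs extents, the
  scale is clamped so the resized canvas fits the downstream pad target; the
  clamp never binds for plausible feet, only for degenerate fragments such as
  tiny boundary slivers.
* **interpolate** — temporal nearest-neighbour resampling to 101 frames
  (percent of stance). Output frame i copies input frame
  round(i·(T_in−1)/(T−1)) with exact halves rounding down; this tie-break
  reproduces the reference mapping (for T_in = 3: output 0–25 ← input 0,
  26–75 ← input 1, 76–100 ← input 2) and makes every output frame an exact
  copy of an input frame.
* **amplitude** — divide by the time-averaged total pressure (recorded as
  MeanPressure first), by body mass, or min–max to [0, 1].

Preset 1 is rotate → pad → interpolate (output n × 101 × 75 × 40, pressure
values untouched); preset 2 inserts measure/resize before padding and
appends mean-pressure amplitude normalization. The pad-before-or-after-resize
order is not fully specified in the source description; resizing first and
padding second is the order that makes the 75 × 40 canvas a superset of the
70 × 25 sole for every foot.

## Biomechanical features

With A the area of one sensor in m² and s its side length in cm:

GRF(t) [N] = 1000 · A · Σ p_xy(t),   COP_ML(t) [cm] = s · Σ x·p / Σ p,
COP_AP(t) [cm] = s · Σ y·p / Σ p,

computed per frame (zero-pressure frames are dropped from COP trajectories;
the centered variant removes the per-component time mean). Peak-pressure
images are per-pixel maxima over the stance. Spatiotemporal parameters come
from consecutive 3D boxes within a pass: step length |Δy|·pitch, step width
|Δx|·pitch (no drift correction — raw |Δx| is used), step time
ΔStartFrame/rate (initial contact to initial contact, the standard step-time
definition), cadence 60/step-time, speed step-length/step-time, stance time
from the step's own span, and toe-out as the side-signed principal-axis
angle (external rotation positive: −RotationAngle for right feet,
+RotationAngle for left, under the handedness convention above).

Balance recordings are preprocessed by cropping to the bounding box of every
pixel that ever reaches 10 kPa, zero-padding to 180 × 180, rotating in 90°
increments so the feet are upright (auto-detection uses the largest connected
region — one foot — to decide the vertical axis, and puts the pressure
maximum, the heel, in the lower half; a manual override is available since
the reference procedure used visual inspection), and keeping the trailing
3000 frames (recordings start a few frames early, so the crop removes the
beginning). Shorter recordings are zero-padded with a warning, or rejected,
by policy.

## The simulator and what passing tests mean

`simulateWalkingTrial()` renders parametric feet walking in alternating
passes with full ground truth (boxes, sides, orientations, standing and
incomplete flags, principal-axis angles, pass ids). The synthetic foot is a
union of a toe ellipse, a metatarsal band, a lateral midfoot strip and a heel
ellipse, with plateau pressures per region and a heel-to-toe weighting curve
over the stance; `archDepth` narrows the midfoot strip from the medial side.
Ground-truth rotation angles report the grid-frame angle of the placed
template's *principal axis* (applied rotation plus the template's intrinsic
PC offset), because the principal axis is the quantity the pipeline is
defined to measure.

Default stride-to-stride variability: footfall timing sd 1 frame, placement
sd 1.5 px, amplitude sd 4%, stance-duration sd 2 frames, and a 0.3
probability that each contact-boundary sensor fails to register on a given
footfall (all draws clamped at 2 sd). These magnitudes are of the order of
natural gait variability and keep the per-trial robust pools non-degenerate;
setting them to zero gives perfectly periodic gait whose steps all score
R = 0. Task presets: preferred 1.12 m/s, slow 0.83 m/s, fast 1.45 m/s, and a
slow-to-stop variant that ends each pass with a two-foot stop held about a
second (feet 20 cm apart — close enough to be realistic, far enough apart
that dilation cannot bridge them into one object).

By default footfalls are laid out so that every step lands fully inside the
grid (partially-on-grid footfalls are skipped; a heel-tip sliver has no
meaningful COP direction, so its labels would be arbitrary). Passing an
explicit `startOffsetPx` instead emits boundary-straddling, incomplete steps;
the boundary tests use an offset that cuts ~30% of the sole, a decisive crop
for the MAD area rule (a step cut by only a row or two is genuinely
indistinguishable from a complete one by any area criterion — that gray zone
is intrinsic to the published rule, not to this implementation).
`injectArtifacts()` adds ghosting (sensors held at their lift-off value),
dead tiles, additive noise, and premature lift-offs, annotating the truth.

The simulator emulates geometry, timing, quantization and the artifact
taxonomy — not biomechanics. Pressure magnitudes per anatomical region are
stylized plateaus, not calibrated loads; shoe outsoles, double-support load
transfer and inter-subject variability are not modeled. Tests passing on
simulated data therefore validate the *processing* (segmentation, tracking,
labeling, scoring, normalization arithmetic) under known ground truth; they
do not certify classifier accuracy on real feet.

Problem sizes used by the test-suite experiments: quarter-resolution tiles
(360 × 120 grid), 10–24 s trials for detection/label/QC checks, a
full-length narrow grid (720 × 120) for the slow-to-stop scenario, and a
2 × 2-tile grid for the 3050-frame balance check. These reproduce every
pipeline code path at a few hundred MB of working memory; the full-device,
90-second configuration runs with the same code and defaults.

## Containers and streaming

Tensors are exchanged in two dialects, both storing the array under the key
`arr_0`: an NPZ-style zip of `.npy` members (written with stored, i.e.
uncompressed, entries so that a C-order rank-3 tensor is frame-seekable;
deflated entries from other writers are read transparently) and a
MAT-style (Level 5) file (zlib-compressed element, column-major, values
stored compactly as 16-bit integers when they fit — readers receive doubles
either way, and both integer and float storage are accepted on input).
`readTrial(lazy = TRUE)` on a stored NPZ returns a file-backed trial whose
frames are read on demand, so a full 9000 × 720 × 240 recording never has to
be materialized; all pipeline consumers pull frames in chunks through
`trialFrames()`. Metadata travels as comma-separated UTF-8 CSV with a
validator that checks every field name, domain, ordering constraint and the
Exclude/Outlier identities, reporting named violations rather than coercing.

## Known limitations

* The side classifier is validated only against the simulator's arch model.
* Orientation and side labels on incomplete fragments are reported but not
  meaningful (the reference dataset corrected such labels by manual
  inspection, which is out of scope here).
* R-scores in trials whose non-excluded steps are nearly identical are 0/Inf
  (degenerate MAD); real recordings have enough variability that this arises
  only in synthetic edge cases.
* Bit-level equality with any externally released preprocessed tensors is
  not claimed: the exact PCA weighting and resampling kernels used to produce
  them are unstated, and the tie-breaks documented here are this package's
  own.
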