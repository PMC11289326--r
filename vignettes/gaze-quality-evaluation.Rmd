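---
title: "Evaluating wearable eye-tracker data quality with gazeqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating wearable eye-tracker data quality with gazeqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

Head-mounted eye-trackers report gaze as a pixel coordinate in the video
of a forward-facing *scene camera*. To ask "how far was the gaze from
what the wearer was told to look at?", two things must be known per
video frame: where the gaze landed (the device's export) and where the
target actually was in that same image (which moves whenever the head
moves). `gazeqc` solves the second half with computer vision on the
scene video itself — no motion capture, no fiducial markers — and then
reduces the per-frame angular errors to the standard data-quality
metrics: accuracy, bias, precision, target speed, and spatial heatmaps.

The evaluation protocol it targets has three dynamicity conditions:

* **seated, chinrest** — only the eyes move; targets are nine green
  20-mm dots, a center dot plus eight on a 536-mm-diameter circle viewed
  from 1 m, so the peripheral dots sit at 15° eccentricity and each dot
  spans about 1.1°;
* **seated, free head** — same wall pattern, but the wearer may turn
  their head, which re-centers the instructed dot in the scene image;
* **walking** — the wearer walks toward a 480-mm green bullseye at the
  end of a red carpet; the target oscillates in the image with the gait.

## Angular geometry

A pixel offset is converted to a visual angle through the *virtual
viewing distance* `VD`: the physical camera-to-wall distance divided by
the physical footprint of one pixel on the wall, i.e. the camera's
magnification expressed in pixels. Each image point `(x, y)` is referred
to the image center `(960, 540)` and lifted to the 3-D ray
`(x − 960, y − 540, VD)`; the angular distance between gaze `i` and
target `j` is the angle between their rays,

θ(i, j) = acos [ (uᵢ · uⱼ) / (|uᵢ| |uⱼ|) ].

Numerically the package evaluates the identical quantity as
`atan2(|uᵢ × uⱼ|, uᵢ · uⱼ)`, because the arc-cosine form loses about
1e-7 degrees near zero angle — visible in property tests that demand
closed-form agreement `θ(center, p) = atan(‖p − c‖ / VD)` to 1e-9.

`VD` is estimated from graph-paper measurements: for points at a known
pixel eccentricity `e` (400 px here) one reads off their physical
distance `d` from the center point, and with camera-to-wall distance `D`,
`VD = e · D / mean(d)`. With the measured distances for the two supported
devices this gives 1132.4 px (50-Hz device, Tobii Pro Glasses 2 profile)
and 912.8 px (100-Hz device, Tobii Pro Glasses 3 profile); the same
`atan(d/D)` conversion yields their fields of view (80.1°x50.7° and
94.4°x61.2°), matching each manufacturer's specification to within a
degree. Field-of-view numbers are computed by rounding each half-angle
to one decimal and summing, mirroring how such tables are reported; all
internal angle computation is double precision and unrounded.

The camera pitch (12° for the older device, 1° for the newer) is stored
metadata. It shifts where targets appear vertically — the simulator
applies it, and it pushes the top dot off the older device's image — but
it enters no angular computation, since gaze and target live in the same
(pitched) image.

## Preprocessing conventions

Raw gaze is filtered per axis by a **moving median with a 0.30-s
window** that *omits missing data*: each output sample is the median of
the non-missing values in its centered window, so blinks shorter than
half the window are bridged with plausible data while saccade edges are
preserved (a median, unlike a mean, does not blur steps). Choices the
window definition leaves open were fixed as: window length in samples is
`round(0.30 · rate)` (15 at 50 Hz, 30 at 100 Hz), an even length extends
one sample further to the right, the median of an even count is the mean
of the two central order statistics, and edge windows shrink rather than
pad. A window with no data yields a missing sample.

Filtered samples are then averaged per video frame (half-open binning on
`[f/25, (f+1)/25)`, two samples per frame at 50 Hz, four at 100 Hz);
a frame with no valid sample is *missing*. Missing-data percentages are
reported both before and after filtering — the difference is exactly the
blink-bridging effect. Invalid samples inside a frame are excluded from
the frame mean rather than zero-filled.

## Scene vision

Targets are localized per frame:

* **green masking** in HSV space (hue 80–160°, saturation ≥ 0.35, value
  ≥ 0.2 by default — plain config parameters, tuned on the bundled
  renderer; real recordings will need their own band);
* a **circular Hough transform** on the mask's edge pixels over a radius
  range, with accumulation restricted to the edge bounding box and
  candidate peaks refined to sub-pixel precision by an algebraic (Kasa)
  circle fit — the dot-grid and bullseye radii differ, so the radius
  range is a per-call argument derived from the physical geometry;
* **labelling** of the nine dots: the center dot minimizes the summed
  distance to all candidates, the rest are named by 45° compass sectors
  about it. This is invariant to translation, scale, and roll to ±15°
  (half a sector); two candidates in one sector are resolved toward the
  median ring radius. Candidates scoring below half the best score are
  discarded first — partially out-of-frame slivers and noise blobs score
  far below full disks. Frames with fewer than five candidates are
  marked undetected rather than discarded, and a dot out of view keeps
  its own undetected flag (this is *not* counted as missing gaze data);
* for walking frames, lines are fitted to the left and right extreme
  columns of the **red-carpet mask** per image row (rows touching the
  image border are excluded — there the border, not the carpet, is the
  extreme) and their intersection — the vanishing point — serves as the
  search prior for bullseye detection in a local window. The bullseye
  center is refined as the centroid of the masked ring pixels around the
  Hough candidate, exploiting the rings' point symmetry. Near-parallel
  edge lines (< 0.5°) raise a no-intersection error.

Detected tracks are smoothed per label and axis by a five-frame
(0.20-s) centered median that skips undetected frames, removing
single-frame detection jitter.

## Segmentation and metrics

Each seated instruction opens a window `[onset+2 s, onset+12 s)`: the
first 2 s absorb the reaction and saccade to the new dot, leaving 250
video frames of steady fixation (instructions are 12 s apart; a late
window is truncated at the next onset with a warning). The 2-s discard
applies from the very first instruction as well. Walking windows end
when the carpet leaves the camera's view — operationally, the last
visible frame before a sustained (> 2 s) invisibility, so single-frame
dropouts don't end a walk — and start 10 s earlier; at most two walks
per trial, with a fallback to the last visible frame if the carpet never
leaves view.

Per interval, with `θ_f` the per-frame gaze-target angular distance over
frames where gaze exists *and* the target is detected:

* **accuracy** = mean θ_f (always ≥ 0 — overall angular error);
* **median accuracy** = median θ_f, robust to the occasional very large
  deviations that inflate the mean;
* **bias** = the angular magnitude of the *mean displacement vector*
  (gaze − target), applied at the image center. Signed errors cancel, so
  bias ≤ accuracy in typical symmetric noise, and bias = accuracy for a
  constant offset. Using per-frame displacement vectors (not mean gaze
  vs mean target) keeps the definition meaningful when the target moves;
* **precision**, in two common variants since the literature has not
  settled on one: RMS of angular distances between successive frame gaze
  points (target-independent), and the SD of the θ_f series;
* **target speed** = mean of per-step angular distance x frame rate over
  successive detected target frames — movement of the target in the
  image is wearer movement, so this separates dynamics from device error;
* **heatmaps** bin image points into 20x20-px cells (96x54 at full HD)
  normalized to a total of 1000.

Across participants, summaries collapse intervals to per-participant
means first, then report mean/SD/median across participants (the SD is
across participants of per-participant means, not pooled across
intervals — the spec left this open and this is the reading consistent
with a per-participant results table).

## Study statistics

The inferential layer mirrors the study design: a 2x3 fully
within-participant ANOVA (device x dynamicity) from an explicit
sums-of-squares decomposition, each effect tested against its own
effect-by-participant interaction, with partial η² =
SS_effect/(SS_effect + SS_error). Sphericity corrections default off
(uncorrected df match the reported F tests); a Greenhouse–Geisser
option exists. Missing-data policy: listwise deletion for the ANOVA,
pairwise for t-tests and correlations. Workload ticks (21-point scales)
map to percentages by `(tick − 1)/20 · 100`. Overall per-participant
accuracy is the mean of per-condition z-scores (sample SD, n − 1; a
zero-variance condition is skipped with a warning), tolerant of missing
condition cells. Binary participant attributes correlate with accuracy
via Pearson r, which for 0/1 predictors equals the point-biserial
coefficient.

## The synthetic world

The simulator generates complete sessions — instruction schedule, target
track, gaze recording, and optionally rendered frames — with ground
truth for every stage. Its defaults state the world of the protocol
above; they are fixed once and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| seated protocol | 19 instructions, 12 s apart; center at positions 1, 10, 19; others twice each, shuffled | the stated protocol |
| devices | 50 Hz / VD 1132.4 px / pitch 12°; 100 Hz / VD 912.8 px / pitch 1° | calibrated device profiles |
| bias | 1° at 45° | typical wearable-tracker offset magnitude |
| noise SD | 0.5° per axis | typical sample-level RMS noise |
| blinks | Poisson 0.25 Hz; lognormal durations, median 0.15 s, sdlog 0.4 | ~15 blinks/min, physiological durations |
| reaction lag | uniform 0.3–0.5 s | safely inside the 2-s discard |
| head re-centering (free head) | 0.8 of dot eccentricity, 1-s raised-cosine ramp | heatmaps of free-head trials cluster targets near the center |
| gait | 25 px lateral at 0.9 Hz, 18 px vertical at 1.8 Hz | ~1.8 steps/s walking cadence; yields mean target speeds near the reported walking values and an order of magnitude above seated ones |
| walks | 2 x 20 s, 5-s turnaround | ~1-min walking trials on a 21.7-m carpet |
| head tremor (seated) | 3 px slow wander | chinrest-level residual head motion |

Gaze is the instructed target's position plus the bias vector
(`bias_deg` converted to pixels at the image center) plus isotropic
Gaussian noise, switching targets with a per-instruction lag. Blinks
replace samples with invalid ones. Everything derives deterministically
from the scenario seed: identical scenarios give bit-identical
recordings and frames.

Two caveats on what a green test establishes. First, the renderer is
schematic — flat colors, hard edges, no lighting, lens distortion,
motion blur, or clutter — so vision tests certify the geometry of the
detection chain, not robustness to real video. The segmentation
thresholds are config parameters precisely because real recordings will
need retuning. Second, because bias is injected as a center-referred
pixel vector, its measured angular size at a 15°-eccentric target is
slightly below nominal (projective foreshortening); recovery tests
therefore assert at the central target, where the identity is exact to
within the sub-pixel effect of the ~1° camera pitch.

## Numerical choices and degenerate inputs

* Angles are computed in double precision; rounding happens only at
  presentation (and in `fov_from_edges`, whose rounding argument exists
  to mirror tabulated per-edge values).
* Sample-to-frame assignment adds a 1e-7 guard to `floor(t · fps)`
  so that timestamps surviving a CSV round trip cannot migrate across a
  frame boundary by one ULP.
* Gaze coordinates outside the image are kept and flagged, not clipped.
* A paired t-test on differences with (numerically) zero variance, a
  correlation against a constant, an empty schedule, an all-missing
  series, or a heatmap with no in-bounds points raise errors; detection
  failures in single frames never do — they flag the frame and move on.
* The median-accuracy variant exists because per-frame θ occasionally
  takes very large values that dominate a mean; on right-skewed error
  distributions it is strictly below the mean-based accuracy.

## Known limitations

* No lens-distortion correction (the calibration procedure found the
  distortion negligible except at the image margins, and the package
  follows that choice).
* No fixation/saccade event detection and no velocity-based blink
  detection; blinks are handled implicitly by the missing-aware median.
* The free-head re-centering model is a stand-in with the right
  qualitative behavior, not a model of head-movement dynamics.
* Proprietary project folders and `.xlsx` exports are out of scope; the
  CSV column map is configurable instead. MP4 decoding is unavailable in
  this build — frame sequences are the canonical video input.
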