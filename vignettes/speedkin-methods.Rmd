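---
title: "Methods: from panning video to wall-frame kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from panning video to wall-frame kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speedkin)
```

## Problem and assumptions

A speed-climbing run is recorded by one camera on a tripod that only
rotates vertically while tracking the athlete. The wall is standardized
(15 m x 3 m lanes, 5 degree overhang, 20 hand and 11 foot holds at fixed
positions), which supplies the metric reference that a single uncalibrated
camera otherwise lacks. The package assumes:

* the only camera degree of freedom is vertical rotation — horizontal pan,
  roll and zoom are not modelled;
* the athlete and all holds lie close to the wall plane, so a per-frame
  affine mapping with a single scale `s_i` (px/m) relates image and wall
  coordinates; coordinates are measured *along* the overhung wall plane;
* pose keypoints follow the BODY_25 layout; the six keypoints for ears,
  eyes and small toes carry no kinematic information and are dropped,
  leaving 19;
* frames are 0-indexed, times are `frame / fps` seconds, and pixel y grows
  downward in every file. All kinematics are computed after flipping to the
  upward convention so that positive vertical velocity always means "up the
  wall". A camera shift `gamma > 0` means the camera panned up, which moves
  static wall features *down* in the image.

## Camera motion

Between consecutive frames, every static feature shares (to first order)
one vertical displacement. `filter_matches()` keeps pairs with
`|dx| <= tol_px` (default 3 px) and then applies a robust band
`median ± k·MAD` (k = 3) to the vertical displacements. The MAD gets a
0.5 px floor: a perfectly rigid displacement field has MAD 0 and would
otherwise degenerate the band to a single point. `estimate_shift()`
averages the surviving displacements per frame; transitions without
inliers carry the previous value forward (causal, streamable) and are
flagged. The mean — not the median — matches the averaging character of the
estimator; the robust band has already done the outlier work.

## Scale calibration

A hold pair with known map separation gives a direct sample
`s = 1/2 (|dx_px/dx_m| + |dy_px/dy_m|)`; when one map axis is zero the
other axis is used alone (logged). Per frame, the widest vertically
separated pair of identified holds is used, which minimises the relative
pixel error of the sample.

Across the run, `s_i = A cos(alpha_i)` with
`alpha_{i+1} = gamma_i / B cos(alpha_i) + alpha_i`. Only `A = c f / d`
(px/m) and `B = c f` (px) are identifiable; the model never reports focal
length, distance or the unit constant separately, and `B` is treated as an
opaque pixel-valued gain (the dimensional bookkeeping of the underlying
geometry is loose, but only the aggregate enters the recurrence).
`fit_scale_model()` minimises the squared residuals at the supporting
points with Levenberg-Marquardt (bounded: `A > 0`, `B > 0`,
`|alpha0| < pi/2`), multi-started over
`alpha0 in {-0.4, -0.2, 0, 0.2, 0.4}` rad because the loss is non-convex in
the start angle. `A` is seeded at the largest measured sample and `B` at a
gain that keeps the implied angle sweep moderate. Non-convergence from
every start raises an error. On four-frame instances the optimizer is
checked against an exhaustive grid; because `A` and `alpha0` trade off
there, the identifiable combination `A cos(alpha0)` is compared, not the
raw coordinates.

Hold tracks are built by camera-compensated nearest-neighbour linking with
a gate of 0.75 x the median box size — safely below the closest inter-hold
distance at any plausible scale. Map identification aligns the
height-ordered track sequence with every contiguous window of the
height-ordered map, fitting one free scale per window and keeping the
window with the smallest squared gap-vector residual: inter-hold distance
*ratios* are scale-free signatures of the standardized route. Fewer than
two tracks is an error ("insufficient holds for calibration").

## Center of gravity and velocity

The summation `C = sum_b m_b (j_pb + r_b x_b)` runs over 12 segments
(head, trunk, and bilateral upper arm, forearm, upper leg, lower leg,
foot), with the proximal joint as each segment's anchor. The printed form
of this summation is ambiguous about parenthesisation; the reading in
which the mass fraction multiplies the whole segment-center position is the
only one for which the unit mass sum normalises the result, and is the one
implemented. The bundled male reference fractions sum to exactly 1, so C is
a convex combination of segment centers — this is asserted, and any edit to
the table that breaks it fails validation.

Velocity adds the camera shift back before scaling,
`v_i = (C_{i+1} - C_i + gamma_i) fps / s_i` (vertical component; the
horizontal one uses the pixel difference alone since the modelled camera
motion is vertical). Whether the shift also carries a horizontal component
in a given recording is not modelled. Finite-difference samples are
stamped at frame midpoints `(i + 0.5)/fps`: this half-frame correction
matters when contact times are read off the curve.

## Filtering

Contact times are read off filtered curves, so the filter must not lag
events: all filtering is zero-phase (forward-backward Butterworth).
Two implementation facts shaped the defaults, both established on
synthetic ground truth during development:

* filtering the speed *magnitude* retains the mean of the rectified noise
  as a positive bias on the dwell plateaus; the velocity components are
  filtered first and the magnitude taken afterwards;
* a sharper (effective order 4) filter rings at the abrupt
  dwell-to-transfer transitions, planting spurious inflections and
  above-threshold humps inside contacts; the default is therefore a gentle
  effective order-2 filter at 5 Hz (both configurable via `run_config()`).

The forward-backward pass is preceded by odd-reflection padding of three
cutoff periods; without it the filter's zero initial conditions corrupt
both ends of short kinematic series. Series shorter than the warm-up are
returned unfiltered and flagged. `auto_cutoff()` implements the
spectral-energy alternative: the frequency below which 95% of the non-DC
energy lies, with a 1.5x margin, clamped to `[0.5, fps/4]` Hz.

## Contact detection

Each contiguous run of frames below `eps` (default 0.15 m/s) seeds a
candidate contact. Interior above-`eps` stretches shorter than the minimum
physiologically plausible release (`min_release_s`, default 0.15 s) are
closed first — a limb cannot release and re-touch faster than that, so such
gaps are measurement ripple. The candidate expands outward to the nearest
enclosing inflection points (sign changes of the discrete second
difference): the descending inflection before the dip is the touch, the
ascending one after it the release. The search is bounded by the last/first
crossing of `2 eps` — beyond that level the limb is clearly moving again,
and inflections farther out belong to the transfer, not the contact. If no
inflection lies in the window the dip edge itself is used; either way the
boundary is pushed at least one sample outward, because the first
sub-threshold sample is already in contact. Candidates whose separating gap
stays below `eps` or is shorter than the minimum release are merged, and
intervals running into the recording edges are censored there. The interval
is reported inflection-to-inflection; the sub-threshold span is exported as
an auxiliary column (`sub_eps_s`) since either reading of "contact
duration" is defensible.

Monotonicity of the interval count in `eps` holds over the detector's
operating range but not below the speed noise floor, where dips genuinely
fragment; the property test covers `eps in [0.10, 0.30]` m/s.

Hold association takes the nearest identified hold track (camera-adjusted
to the interval's midpoint frame) within 1.2 x the median detected box
width; wrists proxy the hands and big toes the feet.

## Sections and the parameter set

Sections are delimited by the first-touch times of boundary holds:
Start (1-5), Middle I (6-8), Middle II (6-12) and End (12-20); the End
span extrapolates the same scheme and is user-overridable. Within a
window, path is the summed metric displacement, and the section-end speed
is the mean of the last three samples (a single frame would be
noise-dominated). The run clock starts at the first frame where the
center-of-gravity speed exceeds 0.3 m/s for three consecutive frames (no
start-pad signal is available from video; both constants are
configurable) and stops at the first touch of the top hold. The
shoulder-hip ("SH") angle is **an interpretation**: the angle of the
mid-shoulder to mid-hip axis against the upward wall vertical; no precise
definition of this parameter exists in the field's common parameter lists.

`synchronize_runs()` shifts two runs so a chosen hold's first touch is
t = 0 in both and builds a piecewise-linear warp through all shared
hold-touch times (identity-slope extension outside the shared range).

## The synthetic generator

`generate_run()` emulates exactly the statistical structure the pipeline
assumes: a climber whose limbs dwell with zero velocity on route-map holds
and transfer with smooth minimum-acceleration profiles; a torso following a
monotone spline through the hand-touch events (or an exactly constant
ascent, or a frozen posture for compensation tests); a camera that keeps
the athlete vertically centered; per-frame affine projection with
`s_i = A cos(alpha_i)`; i.i.d. Gaussian keypoint noise and dropout; hold
detections for all in-view holds; and match pairs of static wall points
displaced by exactly the camera shift, plus a controllable fraction of
horizontal outliers. Defaults: 6 s at 24 fps, `A` = 400 px/m, `B` =
5000 px, `alpha0` = -0.2 rad, noise 2 px, 5% dropout, 20% outliers, 0.55 s
dwells at a 0.45 s hand cadence — values a trainer would recognise as an
elite-pace run filmed from a typical broadcast position.

Deliberate idealisations, and hence what passing tests do *not* show about
real data:

* match-pair jitter is endpoint-correlated so that the pair displacement
  equals the camera shift exactly — the estimator's behaviour under
  independent endpoint noise is covered separately by property tests with
  test-generated pairs;
* the rotating-camera mode varies the scale but writes matches displaced by
  the exact shift; a real rotation produces a displacement field that is
  only locally a translation. The exact compensation-identity check
  therefore runs in the translating-camera mode, where pure translation is
  geometrically exact;
* all limbs are already placed on their first targets at t = 0 (race-start
  posture), and the last dwell of each limb runs to the end of the
  recording;
* keypoint noise is Gaussian and i.i.d.; real pose estimators fail in
  bursts, with occlusion-correlated errors and left/right swaps;
* the renderer draws flat discs on a gray wall — it exercises the HSV
  segmenter's thresholding and morphology, not real lighting or chalk
  texture.

The bundled route map is an approximate, synthetic IFSC-style layout
(hand holds 1-20, foot holds 21-31); only inter-hold distances enter any
computation, and a user map file replaces it exactly.

## Numerical choices and degenerate inputs

* Readers are total: malformed frames or rows degrade to logged skips.
* Keypoints below `min_confidence` (default 0.1) count as missing; interior
  gaps are linearly interpolated, ends clamp to the nearest valid sample,
  and keypoints with fewer than two valid samples stay missing (logged).
* Degenerate joint angles (coincident points) return `NA` and are left to
  interpolation downstream.
* A skeleton exactly on the lane midline (single athlete, tracking camera)
  is kept regardless of image half; with two skeletons the per-half
  best-confidence rule applies, and the per-track majority vote stabilises
  the side label.
* Problem sizes in the test-suite: 6 s runs (144 frames) for recovery
  checks, a ~10 s run (232 frames) for the constant-velocity end-to-end
  check, 10 scale supporting points, 20 replicates for the noisy-fit
  median, grids of 41 x 31 x 41 for the tiny-instance oracle.

## Known limitations

* 2D only: all angles and velocities are wall-plane projections.
* One anthropometric table (male reference values); no personalisation to
  an athlete's stature or mass.
* Horizontal camera pan, roll, zoom and lens distortion are unmodelled.
* The endtime depends on a video-derived start trigger that need not
  coincide with the official starting pad, so endtimes are comparable
  within this tool but not against official race times.
* Hold identification assumes the tracked holds form a contiguous stretch
  of the route; a detector that only ever sees isolated, widely separated
  holds would defeat the ratio alignment.
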