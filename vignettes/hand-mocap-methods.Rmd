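---
title: "Methods: multi-camera hand motion capture, camera selection and kinematic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-camera hand motion capture, camera selection and kinematic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`handmocap` implements a processing chain for markerless hand motion capture
with multiple calibrated video cameras. A detector (MediaPipe-style) supplies
per-camera 2D tracks of the 21 standard hand landmarks with confidences; the
package reconstructs 3D landmark trajectories, chooses which cameras to trust,
fits an articulated hand skeleton, and computes the metrics used to compare a
markerless recording against a marker-based (optoelectronic) reference:

1. **Triangulation** (`triangulate_tracks`) — direct linear transform (DLT) on
   undistorted normalized image coordinates, per frame and landmark, using every
   camera whose detection confidence clears a threshold (default 0.5).
2. **Camera-subset selection** (`select_subset`) — every subset of ≥ 2 cameras
   is scored by a *reprojection error* and an *anatomical error*; the largest
   subset whose errors stay below 10 mm and 5 mm respectively is kept.
3. **Trajectory conditioning** (`lowpass`, `resample_track`, `fill_gaps`,
   `estimate_lag`) — zero-phase 6 Hz Butterworth filtering, rate conversion
   between the 30 Hz video chain and a 100 Hz optoelectronic reference, spline
   gap filling with provenance flags, and cross-correlation synchronization.
4. **Skeletal fit** (`scale_skeleton`, `inverse_kinematics`) — a 26-DOF hand
   model scaled per participant from a static trial, then fit frame by frame by
   weighted damped least squares.
5. **Evaluation** (`occlusion_rates`, `joint_angle_rmse`, `range_of_motion`,
   `compare_trial`) — occlusion-aware per-joint angle RMSE with a strict
   "more than 50 % occluded ⇒ excluded" rule, range of motion, and IK marker
   residuals (`ik_residual`).
6. **Synthetic trials** (`generate_motion`, `make_rig`, `render_views`) — a
   generator of ground-truth articulated motions and corrupted camera views
   that makes every stage testable without recordings.

# The reconstruction model

## Cameras and triangulation

Cameras are standard pinhole models with 5-coefficient radial/tangential
distortion (k1, k2, p1, p2, k3), world units millimetres, pixel origin at the
top-left. Calibration is *consumed* from a JSON file (`load_rig`); estimating
it is out of scope. Rotations may be given as 3×3 matrices or Rodrigues
vectors; translations declared in metres are converted.

For a landmark observed in cameras $i = 1..n$ at undistorted normalized
coordinates $(x_i, y_i)$, with $[R_i | t_i]$ the world→camera transform, the
DLT stacks the constraints

$$x_i\,(r_{3,i}^\top X + t_{3,i}) - (r_{1,i}^\top X + t_{1,i}) = 0,
  \qquad y_i\,(r_{3,i}^\top X + t_{3,i}) - (r_{2,i}^\top X + t_{2,i}) = 0$$

and solves for $X$ in least squares. **Numerical choice:** we solve the
*inhomogeneous* form (fix the homogeneous scale $w = 1$, SVD-based
least-squares solve for the three coordinates). The textbook homogeneous
form — smallest right singular vector of the stacked 2n×4 system under
$\|v\| = 1$ — is scale-biased when world units are millimetres: the algebraic
error of a candidate at distance $D$ is discounted by $1/\|X\|$, and in the
worst geometry (a point at the rig's convergence point, observed at each
camera's principal point) 2 px of noise moved the homogeneous solution by
about a metre. The inhomogeneous solve is exact on noiseless data and agrees
with a brute-force grid search minimizing the summed squared reprojection
error to better than 0.2 mm (worst of 20 random instances). Degenerate
geometry (near-parallel rays) is detected by a condition-number guard (10^12)
and reported, not silently returned. No nonlinear refinement is applied; the
hand occupies so small a depth range that the depth-weighting of the linear
solution is immaterial.

## Reprojection and anatomical errors

The *reprojection error* of a camera is the RMSE, over frames and the 21
landmarks, of the image-plane distance between the observed landmark and the
reprojected triangulated point. The selection threshold is specified in mm,
while the error lives in pixels; we convert with
$e_{mm} = e_{px} \cdot \tilde Z / \bar f$, where $\tilde Z$ is the median
depth of the triangulated landmarks in that camera and $\bar f$ the mean of
its focal lengths — i.e. the metric size of the pixel error at the hand's
distance.

The *anatomical error* exploits bone rigidity: per finger segment, the sample
standard deviation (ddof = 1) of its frame-wise length over frames where both
endpoints are visible; the score is the RMS of these 15 per-segment standard
deviations (palm rays excluded). It is zero for any rigid reconstruction and
grows with triangulation noise, making it a reference-free quality measure.

## Subset selection

All subsets of size 2..n are enumerated (size-descending, then lexicographic
— 11 subsets for four cameras). A subset passes when its **worst** per-camera
reprojection RMSE is ≤ 10 mm *and* its anatomical error is ≤ 5 mm; among
passing subsets the largest wins, ties broken by lower anatomical error, then
lower pooled reprojection error. If nothing passes, the subset minimizing the
threshold-normalized sum of both errors is returned, labelled
`none_pass_best_effort`. Worst-camera (rather than mean) gating is the
conservative reading of a per-camera criterion and is what makes a single
corrupted camera detectable; it is configurable. Selection is per trial —
per-window dynamic selection is deliberately out of scope.

# The hand model

## Skeleton

21 landmarks, 20 rigid segments (5 palm rays WRIST→digit base + 15
phalanges), 15 named joints (`1cmc, 1mp, 1ip` for the thumb; `Nmcp, Npm, Nmd`
for digits 2–5). The rest pose is a flat hand with digits radiating from the
wrist in a plane; each digit's phalanges are collinear with its palm ray, so
0° means a straight chain for every joint. Default segment lengths are
published-average adult values; a left hand is the mirror image.

26 DOFs: 6 global (translation mm, XYZ Euler orientation) plus, per digit,
base flexion, base abduction, middle flexion and distal flexion. Joint limits
(base flexion −30..110°, abduction ±25°, middle −10..115°, distal −10..90°)
are physiological ranges whose main job is to exclude mirror-image IK
solutions. Reported angles are the 15 flexion DOFs, in degrees; abduction is
estimated but not reported, matching the one-angle-per-joint convention of
optoelectronic hand protocols.

## Scaling

`scale_skeleton` averages landmark positions over the first 5 s of a static
trial (visible frames only; an error is raised if less than half the window
is usable). Each digit gets a single longitudinal scale — observed chain
length over template chain length — applied to its phalanges, and each palm
ray is scaled from the observed wrist-to-base distance. Joints are never
moved off the bone axes. The procedure is exactly scale-equivariant and
recovers constructed per-finger scales to 1e-6.

## Inverse kinematics

Per frame we minimize $\sum_i w_i \lVert m_i(q) - \hat m_i \rVert^2$ over the
26-DOF pose, dropping invisible landmarks. Default weights are 1.0 for the
four landmarks of each finger chain and the three proximal thumb landmarks,
and 0.1 for the wrist and thumb tip — high weight where detectors are
reliable and anatomy is consistent, low weight near the palm.

The optimizer is Levenberg–Marquardt with an **analytic Jacobian**: every
angular DOF is a revolute axis recorded during forward kinematics, so its
column is $a \times (p - c)$ for axis $a$ and joint center $c$. Steps are
accepted only when the cost decreases (so the per-frame cost trace is
provably non-increasing), joint limits are enforced by projection, and
convergence is declared when the improvement falls below 1e-6 mm² (at most 50
iterations). Frames are warm-started from the previous solution; the first
frame takes its global pose from a rigid (Kabsch) fit of the palm landmarks
and its flexions from `direct_joint_angles`, the model-free oracle that
measures the signed angle between adjacent bone vectors. Frames with fewer
than 4 visible landmarks, or that fail to converge, are flagged invalid and
excluded downstream. On noiseless forward-kinematics data the IK recovers
all DOFs to < 1e-4 degrees; sequential warm-starting keeps the whole fit
deterministic.

# Signal conditioning

Filtering is a zero-phase (forward–backward) 4th-order Butterworth at 6 Hz —
the biomechanics convention for hand kinematics; the family and order are the
package's choice since only the cutoff is conventionally reported. The
implementation pads each visible run by odd extension and seeds the filter
with steady-state initial conditions, so a constant signal passes through to
machine precision. Two properties follow: the DC gain is exactly 1, and the
first/last samples of a record are preserved exactly (a known property of
odd-extension zero-phase filtering — stopband attenuation therefore holds in
the interior, not at the endpoints). Runs shorter than $3 f_s / f_c$ samples
pass through unfiltered. Filtering happens after triangulation, matching the
processing order of the video chain.

Gap filling uses cubic splines across gaps up to a configurable duration, but
filled samples are *provenance-flagged* and still count as occluded in the
evaluation: interpolated reference data would bias the error estimate in
either direction, so it is never treated as observed. Synchronization between
devices is the argmax of the normalized cross-correlation of the mean finger
MCP flexion (ties toward zero lag, search bounded at ±2 s).

# Evaluation rules

Per joint, the angle RMSE between reference and test series is computed over
frames valid in both, after resampling both to the lower rate (the 100 Hz
reference is downsampled to 30 Hz rather than inventing reference samples)
and lag alignment. A joint whose central landmark is occluded for **more**
than 50 % of the trial is excluded entirely (exactly 50 % is still included);
the trial mean covers included joints only. Joint-to-landmark gating is
one-to-one (e.g. `2pm` is gated by the index PIP landmark). Angle differences
are plain arithmetic — hand joints never approach ±180°, so no circular
statistics are needed. Range of motion is max − min over valid frames.

# The synthetic generator

The generator emulates the five-task experimental protocol (static, piano,
flexion, extension, ball; 10 repetitions per trial, 30 Hz video, 2–4 cameras
around the hand, 100 Hz reference): DOF trajectories are raised-cosine pulses
— C¹-smooth and essentially band-limited below the 6 Hz cutoff at the default
repetition period of 2 s. Piano is strictly sequential pinky→thumb (at most
one finger flexed at a time); flexion drives all digits simultaneously (MCP
80°, PIP 100°, DIP 70° by default); extension relaxes to +15° then
hyperextends (−20° base, clamped at −10° for middle/distal to respect the
joint limits); ball holds a grasp posture while the hand shuttles 120 mm
sinusoidally. The initial posture is always palm-down with fingers extended.

Virtual rigs place webcam-like cameras (70° FOV, 1280×720) on a 600 mm arc,
including one view from below the hand. Rendering projects every landmark,
adds isotropic Gaussian pixel noise, per-camera extra noise and bias for
"bad" cameras, and seeded contiguous occlusion dropouts (alternating
geometric-length runs whose long-run occluded fraction matches the requested
rate). Reference-track dropout supports a wrist-bias multiplier reproducing
the empirical concentration of optoelectronic occlusions near the wrist; the
16.6 % flexion-regime occlusion rate is available as a preset. The ball
task's external occlusion is approximated statistically — three-fold dropout
of palm-side landmarks in the below-hand camera — rather than by rendering a
sphere.

What the generator does *not* emulate: detector-specific bias fields
(MediaPipe's depth coordinate errors are structured, not isotropic),
soft-tissue artefact, correlated confidence/error, or photorealistic
appearance. Passing round-trip tests therefore validate the geometry,
selection logic and kinematics of the pipeline, not detector behaviour on
real video.

# Validation summary and problem sizes

The test suite validates each stage against independent oracles: brute-force
grid-search triangulation, hand-computed anatomical errors, analytic filter
responses, constructed lags/scales/offsets, and FK↔IK round trips. End-to-end
checks run at desk scale, chosen to keep the full suite in a few minutes:
piano round trips with 10 repetitions (600 frames), Monte-Carlo batches of
10–20 seeds with 2-repetition trials (120 frames) for the noise-response,
bad-camera and IK-recovery properties. `scripts/acceptance.R` recomputes the
same quantities from scratch at a given seed.

Known limitations: one camera subset per trial; the wrist is rigid (no
forearm DOFs); abduction is fit but not reported; C3D support covers the
Intel/float and integer point formats that dominate in practice; confidence
values are used only as a gate, not as triangulation weights.
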