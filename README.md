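# handmocap

Markerless hand motion capture turns ordinary multi-camera video of a hand
into 3D landmark trajectories and joint angles — but its accuracy hinges on
*which* cameras you trust, and validating it requires comparing against a
marker-based (optoelectronic) reference whose markers are frequently
occluded. `handmocap` implements that full processing and evaluation chain
for biomechanists and human-movement researchers working with 21-landmark
hand keypoint detectors (MediaPipe-style) and 2–4 calibrated webcams:

- **DLT triangulation** of per-camera 2D landmark tracks (confidence-gated,
  with explicit handling of degenerate geometry),
- **optimal camera-subset selection**: every subset of ≥ 2 cameras is scored
  by its worst per-camera *reprojection error* (RMSE between observed and
  reprojected landmarks, converted to mm at the hand's distance,
  `e_mm = e_px · Z̃/f̄`) and its *anatomical error* (RMS over the 15 finger
  segments of the temporal standard deviation of segment length — a
  reference-free rigidity measure). The largest subset with reprojection
  ≤ 10 mm and anatomical error ≤ 5 mm wins,
- a **26-DOF articulated hand skeleton** (6 global DOFs + base
  flexion/abduction and middle/distal flexion per digit), scaled per
  participant along each finger from a static trial, and fit per frame by
  **weighted inverse kinematics** (damped least squares, analytic Jacobian,
  marker weights 1 for the finger chains / 0.1 for wrist and thumb tip),
- **occlusion-aware evaluation**: per-joint angle RMSE over jointly valid
  frames with joints excluded outright when their landmark is occluded for
  more than 50 % of the trial, range of motion (max − min), occlusion rates,
  and IK marker residuals,
- **signal conditioning**: zero-phase 4th-order 6 Hz Butterworth filtering
  (exact DC gain), 100 ↔ 30 Hz resampling, provenance-flagged spline gap
  filling, cross-correlation synchronization,
- a **synthetic trial generator** (five task presets — static, piano,
  flexion, extension, ball — plus virtual camera rigs, pixel noise, bad
  cameras and seeded occlusion dropout) so every stage is testable without
  recordings, and
- **I/O** for C3D, TRC, calibration JSON, 2D-track CSV and joint-angle CSV.

## Worked example

Simulate a flexion trial (3 repetitions, 30 Hz, 2 px detector noise) seen by
four cameras, one of which is badly corrupted; select cameras; triangulate,
filter, and compare against the 100 Hz reference:

```r
library(handmocap)

sk  <- build_default_skeleton()
rig <- make_rig(4)
cfg <- synthetic_task_config("flexion", n_reps = 3, noise_px = 2, seed = 1,
                             bad_cameras = list(cam2 = list(sigma_px = 23)))
sim <- simulate_trial(cfg, rig, sk, ref_fs = 100)

sel <- select_subset(sim$views, rig, sk)
sel$chosen
#> <subset_score> {cam1,cam3,cam4}: reproj 1.42 mm (worst cam), anat 1.38 mm [pass]
sel$reason
#> [1] "fallback_smaller"

t3  <- lowpass(triangulate_tracks(sim$views, rig, sel$chosen$subset))
cmp <- compare_trial(sim$reference, t3, sk, config = list(scale = FALSE))
cmp
#> <trial_comparison> mean joint-angle RMSE 2.00 deg over 15/15 joints; mean occlusion 0.0%; lag 0 frames
head(summary(cmp), 4)
#>   joint rmse_deg included   status n_frames rom_ref_deg rom_test_deg occlusion
#> 1  1cmc 1.011640     TRUE included      180          80     82.18884         0
#> 2   1mp 2.007438     TRUE included      180         100    104.83020         0
#> 3   1ip 2.909682     TRUE included      180          70     80.95361         0
#> 4  2mcp 1.057046     TRUE included      180          80     83.65544         0
```

The selector dropped the corrupted `cam2` (its reprojection error exceeds
the 10 mm threshold) and kept the three clean views; the remaining 2°-level
RMSE is the footprint of the injected 2 px detector noise after
triangulation, filtering and IK. `run_pipeline(config)` executes the same
chain from files on disk (calibration JSON + per-camera CSVs, optional
reference and static C3Ds) and writes C3D/TRC/CSV/JSON reports.

## Vignette

`vignettes/hand-mocap-methods.Rmd` documents the models and the numerical
choices: the inhomogeneous DLT formulation, the pixel→mm conversion, the
skeleton's DOF layout and joint limits, IK initialization and convergence,
the zero-phase filter construction, the occlusion-gating rules, and what the
synthetic generator does and does not emulate.
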