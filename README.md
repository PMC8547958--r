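# mousegaze

Reconstructs the visual experience of freely moving mice during prey
pursuit. Laboratory mice chase crickets without smooth-pursuit eye
movements: their eyes counter-rotate against head rotation (the
vestibulo-ocular reflex, VOR) to stabilize the visual field, and the
animal steers its *body* so the prey image stays in a stable "functional
focus" of each eye's view. Quantifying this requires rebuilding, frame by
frame, what each cornea saw — from tracked head landmarks, eye rotation
angles, the prey position, and a mesh model of the arena — and an optical
model of the mouse eye to relate corneal directions to retinal locations.

`mousegaze` implements that pipeline end to end:

- **Geometry** — head-frame construction from anatomical landmarks
  (eyes–nose plane tilted 40°), eye-rotation composition
  `R = R_φ R_θ R_ψ` on the reference gaze `(0,0,−1)`, swing–twist
  geodesic interpolation between 60 Hz eye and 200 Hz head tracks, rigid
  fiducial registration, horizon alignment, chordal-mean differential
  rotations.
- **Ocular torsion** — per-frame torsion ψ from a tracked corneal spot by
  minimizing predicted-vs-marked pixel distance, with calibration of the
  spot's anatomical parameters (r, α) and session normalization to the
  median head posture.
- **Schematic eye** — measured mouse biometry with a gradient-index
  (GRIN) lens: constant-index and Poisson-gradient lens models optimized
  so 10,000 rays from 10 cm focus on the retina, blended on a 45° off-axis
  bundle; Monte-Carlo retina→cornea back-projection; projection of
  retinal ganglion-cell isodensity contours; geometry sensitivity scan.
- **Corneal views** — per-pixel ray-cast renderings of the environment on
  an azimuthal-equidistant 180° chart (object ID, depth, 3D intersection),
  with the cricket as a 2 cm disk.
- **Optic flow** — tangent-plane flow fields from consecutive views, the
  analytic `(v/r)·sin θ` field of the idealized spherical surround, flow
  poles with Gaussian density, solid-angle-weighted regional statistics.
- **Binocular** — inter-ocular alignment on the zero-baseline sphere,
  overlap probability maps, digital freezing of torsion/vertical/
  horizontal eye rotations, head→eye compensation gains.
- **Behavior** — detect/track/capture epoch classification (20 cm/s
  velocity criterion, 90° bearing, 6 cm contact, ≥5 cm escapes, 500 ms
  look-back, >20 cm inclusion), trajectory straightness, prey-image
  density maps with highest-density-region contours, per-trial medians.
- **Synthetic data** — seeded generators for arena meshes, scripted
  pursuits with ground-truth epochs, head/eye series with programmable
  VOR gains, and corneal-spot observations, so the whole pipeline is
  testable without the deposited recordings.

## Worked example

Simulate a scripted pursuit with one cricket escape, classify its epochs,
and measure the pitch-axis VOR gain with and without torsional eye
rotations:

```r
library(mousegaze)

sim <- simulate_pursuit(simulation_config(seed = 42), with_escape = TRUE)
seg <- classify_epochs(sim$trajectory, sim$manual_capture_end)
seg$epochs
#>     kind t_start t_end excluded
#>   detect   0.805 1.305    FALSE
#>    track   0.940 2.250    FALSE
#>  capture   2.810 3.210    FALSE
seg$escapes
#>  t_contact t_escape peak_dist_m
#>       2.25    2.575   0.1398848

vor <- simulate_vor_head_eye(simulation_config(seed = 42, duration_s = 8))
eye <- resample_rotation_series(vor$left, vor$head$timestamps)
fit <- compensation_gain(vor$head, eye, axis = "X")
frz <- compensation_gain(vor$head, freeze_eye_rotations(eye, "torsion"),
                         axis = "X")
sprintf("pitch-axis gain: %.3f (torsion frozen: %.3f)", fit$slope, frz$slope)
#> "pitch-axis gain: -0.450 (torsion frozen: -0.158)"
```

The detect epoch ends at the last frame before the mouse's smoothed
velocity toward the cricket reaches 20 cm/s with the bearing below 90° and
the distance falling; tracking runs from the sub-90° turn to the 6 cm
contact; the 2.5 s contact is followed by a 14 cm rebound (an escape,
since it exceeds 5 cm), so capture starts with the final approach. The
simulated eye compensates −0.45 of head pitch; freezing torsion removes
most of that compensation, because for a lateral eye the head's pitch axis
is close to the eye's gaze axis.

Building and querying the schematic eye:

```r
eye_model <- optimize_lens(schematic_eye(), n_rays = 10000, seed = 1)
eye_model$report$index_range        # lens index extrema after optimization
retina_to_cornea_mc(eye_model, 30)$mean_direction  # visual direction of a
                                                   # 30 deg-eccentric point
```

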