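---
title: "Models and methods in mousegaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mousegaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousegaze)
```

mousegaze reconstructs what a freely moving mouse sees while it pursues
prey. The inputs are tracked 3D positions of head landmarks and of the
cricket, per-frame eye rotation angles (or raw corneal-spot pixels), a
triangle mesh of the environment, and optionally retinal cell-density
contours. From these the package computes corneal-view maps, optic-flow
fields, binocular overlap and alignment, vestibulo-ocular compensation
gains, pursuit-epoch labels, and — through a schematic eye with a
gradient-index lens — the corneal locations of retinal landmarks.
This vignette explains the models, their assumptions and the numerical
choices; the README shows a worked example.

## Coordinate frames and rotation handling

All rotations are 3x3 orthonormal matrices mapping body coordinates to
world coordinates; angles are degrees at every API boundary and radians
internally. The head frame is built from the medial canthi and the
nostrils: forward runs from the eye midpoint to the nose, the left axis is
orthogonal to forward and the inter-canthus axis, and forward is elevated
by a tilt angle (default 40 degrees, a parameter because other species
differ) so that the frame matches the skull's bregma--lambda plane
convention. Head yaw--pitch--roll is intrinsic about up--left--forward;
positive pitch is nose-up and positive roll is roll-right. This convention
is chosen once and used by every function; nothing downstream depends on
the choice as long as it is consistent.

Eye rotations compose as `R_phi %*% R_theta %*% R_psi` (vertical,
horizontal, torsional) acting on the reference gaze `(0, 0, -1)`. The
per-eye sign convention is therefore the same for both eyes; mirroring for
display is left to the caller.

**Interpolation.** Eye cameras run at 60 Hz against 200 Hz head tracking,
so eye poses must be resampled. The requirement is twofold: the gaze
vector must travel along the great circle between the bracketing gaze
directions with an angle proportional to the interpolation fraction, and a
vector perpendicular to the gaze must rotate uniformly. The rotation-group
geodesic (constant angular velocity about a single axis) does *not*
satisfy the first requirement in general: it carries the gaze along a
small circle whenever the relative rotation axis is oblique to the gaze.
`interpolate_rotation()` therefore uses a swing--twist factorization — a
uniform great-circle swing of the gaze composed with a uniform torsion
about the gaze — which satisfies both conditions exactly and reduces to
the group geodesic when the twist vanishes. Exactly antipodal gazes have
no unique great circle and raise an error rather than picking a plane.

Rigid registration of fiducial points (tracking system against the scanned
mesh) is the closed-form Kabsch/Procrustes solution; the test suite checks
it against a brute-force optimizer on small instances. The chordal L2 mean
(the rotation minimizing summed squared Frobenius distance) underlies
`differential_rotations()`; it is computed by projecting the elementwise
mean matrix onto SO(3).

## Torsion from a corneal spot

The torsion tracker models a mark on the eyeball surface at radial
distance `r > 1` (in units of the pupil rotation radius) and fixed angle
`alpha` from the gaze axis. Given per-frame vertical/horizontal angles
from pupil tracking, the predicted pixel position of the mark is linear in
`cos(psi)` and `sin(psi)`; per-frame torsion is the bounded 1-D minimizer
of the squared pixel error. The search is restricted to (-90, 90) degrees:
freely moving rodents stay far inside this range, and the bound excludes
the mirror solution. Calibration of `(r, alpha)` runs a derivative-free
Nelder--Mead simplex over the two parameters with the per-frame torsion
re-estimated inside the objective (a nested bounded search, vectorized
over frames as a coarse 1-degree grid plus 40 golden-section refinements,
resolving psi far below 0.001 degrees).

Initialization exploits the geometry: back-projecting each frame's pixel
onto the sphere of candidate radius `r` yields a per-frame `alpha`
estimate, and the true `r` makes these agree, so `r` starts at the
minimizer of their variance (the in-plane component is clamped so the
square root stays real for marks near the limbus). Missing spot frames
propagate as missing torsion; nothing is imputed.

Session normalization subtracts the mean torsion over the reference frames
closest to the median head pitch *and* roll. Closeness is Chebyshev
distance (the maximum of the two absolute deviations); the reference
fraction defaults to 1e-4 of frames and at least one frame is always used,
since the nominal fraction selects less than one frame at typical session
lengths. Normalization is per-session.

## The schematic eye and its GRIN lens

The model eye is built on experimentally measured mouse biometry: surface radii of
curvature (anterior/posterior cornea, anterior/posterior lens, retina),
component thicknesses (cornea 92, anterior chamber 278, lens 2004,
vitreous 609 um), indices (cornea 1.402, aqueous 1.334, vitreous 1.333)
and a 594 um pupil radius (mean of the constricted and dilated mouse
pupil). Axial surface positions follow from cumulative thicknesses along
the optical axis. The table's radius signs are interpreted through the
physical orientation of each surface — cornea and anterior lens convex
toward the incoming light, posterior lens and retina concave toward it —
with the magnitudes setting the curvature; the iris aperture sits in the
anterior lens vertex plane.

The lens refractive index is unknown and is constructed in three stages,
each judged by the least-squares focal point of a bundle of rays emitted
from an object 10 cm away (10,000 rays by default, aimed at a seeded
uniform sample of an entrance disk 15% wider than the pupil so the stop
itself trims the bundle):

1. a **constant index** `n_c` optimized so the on-axis bundle focuses on
   the retinal sphere;
2. a **gradient model** `n_g = 1.333 + c * u`, where `u` solves a Poisson
   equation (unit source, zero Dirichlet boundary) on the 40x40x40 lattice
   nodes inside the lens body, giving a smooth core-peaked profile that
   meets the vitreous index at the capsule; the gradient strength `c` is
   optimized for the same on-axis criterion. The sign of the source term is chosen so
   the index peaks inside the lens — the focusing direction; with the
   opposite sign a positive source strength would push the core index
   below its boundary value;
3. the final lens `alpha * n_c + (1 - alpha) * n_g`, with the blend weight
   optimized on a bundle from 10 cm away and 45 degrees off axis.

Scalar optimizations use bounded Brent search (`stats::optimize`) with
tolerances of 1e-6 on `n_c` and the blend weight and 1e-4 (relative) on
the gradient strength; the gradient strength is capped so the lattice
never exceeds an index of 1.60. The Poisson system is solved once per
geometry by sparse Cholesky factorization of the 7-point Laplacian
(roughly 22,000 interior nodes).

Ray tracing applies Snell's law analytically at every surface and an
explicit step-wise update inside the lens: the position advances along the
unit direction, the direction is incremented by the trilinearly
interpolated gradient of `log n` (central differences on the lattice) and
renormalized each step. The step defaults to 5 um; halving it moves exit
directions by under 0.01 degrees on average (the scheme is first order, so
pupil-margin rays through the steepest gradient can reach a few hundredths
of a degree). The speed-of-light factor that a physical ray parameterization would
carry cancels in the geometry and is normalized out. Boundary crossing
is located by bisection on the lens-body membership test.

**Retina-to-cornea projection** back-traces rays Monte-Carlo-style from a
retinal point: emission polar angles are cosine-weighted (Lambertian,
`pdf(theta) ∝ cos(theta) sin(theta)`; a plain-cosine switch is provided
since an intensity-proportional-to-cosine rule admits either reading), rays hitting the iris,
the lens equator or the sclera are discarded, and rays exiting the
anterior cornea contribute their direction. The visual direction of the
point is the normalized mean exit direction; the angular spread and the
acceptance fraction are reported. Retinal flat-mount contours are placed
on the retinal sphere by azimuthal-equidistant unfolding about the
optic-disc center (arc length preserved along radii from the disc), with
the disc at the optical-axis intersection; rotational symmetry of the
model makes further alignment unnecessary. The unfolding distortion of a
real flat-mount is not modeled; vertices whose back-trace accepts no rays
are flagged and interpolated across runs of at most two.

**Sensitivity scan.** Each curvature radius and each thickness is
perturbed (positively) by 10, 50 and 100 um; the lens is re-optimized for
every perturbed geometry (3,000-ray bundles keep the 28 optimizations
tractable; the optimization is deterministic given the seed, so baseline
and perturbed models share identical ray sampling); and a deterministic
meridional fan of 45 rays from the 45-degree off-axis object is traced.
The scan reports, per parameter and delta, both the maximum per-ray change
in radial retinal elevation (polar angle of the retinal hit about the
optical axis, seen from the retinal sphere center) and the change of the
bundle centroid, so either convention for summarizing the bundle can be
compared. The headline number is the maximum
per-ray deviation across parameters. Deviations are not linear in the
perturbation for every parameter (lens thickness in particular is
super-linear between 50 and 100 um in this implementation), which matters
when comparing against summaries that assumed linearity.

## Corneal views and optic flow

Each eye sees a 180-degree hemisphere around its optical axis. The
corneal map is an azimuthal-equidistant chart: the center pixel is the
optical axis and radial pixel distance is proportional to the angle off
axis (1024x1024 by default; analyses here run at 64--256). The chart is
not equal-area, so every statistic over the map carries solid-angle
weights proportional to `sin(gamma)/gamma`. Rendering is per-pixel CPU
ray casting (nearest triangle intersection, Moller--Trumbore), which the
test suite checks against a cube-map-then-resample oracle — the same
projection the original GPU pipeline used — at one spherical pixel of
quantization slack. Crickets are closed disks, 2 cm diameter and 1 cm
thick, axis parallel to gravity, tessellated with 64 rim segments.

Optic flow at a pixel is the central difference of the world-frame 3D
intersection points one frame before and after, divided by `2 dt` and by
the eye-to-surface distance, then projected orthogonally onto the local
tangent plane spanned by the polar and azimuthal basis vectors of the
chart; only these two components enter the speed, the third being radial
motion. The normalization makes the field independent of frame rate and
resolution, which the tests verify directly. The idealized surround — a
fixed sphere of radius 50 cm around the head with the animal translating
at 1 cm/s — has the closed form `(v/r) sin(theta)` and doubles as the
accuracy benchmark (rendered flow matches within 2% RMS at 256^2).

Flow poles (directions of zero translational flow) are the normalized
central-difference translation directions of the eye trajectory over a
4-frame window, expressed per frame in eye coordinates; zero-velocity
frames are excluded. Their density uses a Gaussian kernel over chordal
distances with `sigma = 2 * pi / 180` radians, divided by the number of
contributing frames. Per-frame flow minima are taken from these poles
rather than from an argmin over noisy per-pixel speeds; an argmin channel
over total flow remains available for comparison.

## Binocular analyses

Alignment and overlap use the idealized environment: a unit sphere with
zero inter-eye baseline, which is the stated limit of an infinitely
distant surround. A direction in one eye projects into the other as
`t(L) %*% R %*% u`; misalignment is the mean of `2 * asin(chord / 2)`
deviations from the normalized mean direction. The overlapping field of a
frame is the set of directions within 90 degrees of both optical axes; the
probability map averages this indicator over frames on the reference eye's
chart. For two static axes separated by `delta` the overlap is a spherical
lune occupying `(pi - delta) / pi` of one field, the analytic check used
in the tests.

"Freezing" an eye axis decomposes each eye-in-head rotation relative to
the mean pose into vertical/horizontal/torsional angles, replaces the
selected components by their series means, and recomposes. Compensation
gains compare rotations about common head axes: differential rotations
(frame relative to chordal mean) for head and eye, the signed angle about
the axis extracted by projecting the axis-angle vector onto it (the pitch
axis is the negative left axis so positive angles are nose-up), and the
gain fit by ordinary least squares over frames with a binned mean/SD curve
(2-degree bins by default; bin width is configurable). Gains are reported per series; aggregation across
animals happens outside.

## Pursuit epochs and behavioral summaries

Velocity toward the cricket (head-point velocity projected on the
mouse-to-cricket direction), absolute target bearing and inter-animal
distance are smoothed with a 50 ms sliding Gaussian window (kernel SD a
quarter of the window, edge-renormalized) before any rule applies. The
detect end point is the last frame before the conjunction of: velocity
toward the cricket at least 20 cm/s, bearing below 90 degrees, and
distance continuously decreasing — operationalized as a negative smoothed
derivative on every frame from the candidate through the approach end.
Detect starts
500 ms earlier. Tracking runs to the first 6 cm contact; if the bearing
exceeded 90 degrees before the turn, tracking starts at the first frame
below 90. Contacts followed by a rebound of at least 5 cm are escapes;
the capture period starts with the first approach after which every
escape stays within 5 cm of the 6 cm contact zone (11 cm), and ends at the
manually identified capture end, which is a required input: the
final catch is identified by manual inspection of the video, not by a
distance rule. Tracking
periods starting at 20 cm or less are flagged excluded rather than
deleted, and frames within 3 cm of the cricket carry a whisker-zone mask,
so both rules can be toggled downstream.

Straightness metrics rotate the path so the start-to-end chord is the
abscissa and report the absolute lateral deviation 20 cm (chord distance)
from the end, the maximum absolute deviation, and the unsigned area
between path and chord. Prey-image density maps are solid-angle-corrected
histograms normalized to unit mass; maps from several sequences are
averaged with equal weight per sequence regardless of length. Highest-
density regions rank pixels by density per steradian and accumulate mass
greedily; polygon outlines come from `grDevices::contourLines` at the
resulting threshold, and regions may be disconnected. Per-trial medians
collapse each temporal trace to one number before any across-trial
statistic, because within-trial samples are strongly autocorrelated.

## The synthetic-data generators

The generators produce inputs with the structure the pipeline assumes —
they make every module testable without the deposited recordings, and they
define the conditions under which the acceptance checks run. Head angle
traces are band-limited sums of eight random sinusoids (0.2--1.5 Hz) with
SDs of 8/8/6 degrees for yaw/pitch/roll, moderate values for a mouse
engaged in pursuit; eyes counter-rotate about the head pitch and roll axes
with programmable gains (defaults -0.45 and -0.51) on 60 Hz timestamps
offset from the 200 Hz head grid so analyses must interpolate. Eye
anatomical frames sit at 60 degrees azimuth and 22 degrees elevation with
a -90 degree twist about the gaze, which makes head pitch load mainly on
ocular torsion and head roll on vertical eye rotation — the coupling
reported for lateral-eyed rodents.

Scripted pursuits are built from piecewise segments (idle, bearing turn,
quadratic speed ramp through 20 cm/s, linear approach, parabolic dip to
5 cm, optional escape to 14 cm and final approach) whose rule-relevant
crossings sit on smooth or mid-linear stretches, far enough from segment
corners that the classifier's 50 ms smoothing does not move them; the
generator records ground-truth boundary times analytically. Script
parameters (initial distance 32--45 cm, initial bearing 105--150 degrees,
approach speed 24--30 cm/s) are drawn per seed within ranges that respect
the rule margins. Each generator draws from a named substream of the
master seed, so adding a generator does not shift the others, and equal
seeds reproduce identical bytes.

What the generators do *not* emulate: biomechanics of locomotion, cricket
evasion, saccade-and-fixate gaze patterns, tracking dropouts in position
data, or the spectral detail of real head movement. Passing the synthetic
acceptance checks therefore shows that the algorithms implement their
definitions correctly under controlled conditions, not that real
recordings would yield the session statistics reported from real recordings; the
`scripts/integrate_dryad.R` entry point recomputes those statistics when
the deposited data are supplied.

## Problem sizes and runtimes

The test and acceptance runs use: 10,000-ray bundles for the headline lens
optimization and 3,000-ray bundles inside the 28 re-optimizations of the
sensitivity scan; 256^2 pixels for the flow benchmark and 64--128^2 for
rendering unit tests; 20 seeds for the classifier, torsion-noise and
alignment-freezing checks; 8-second series at 200/60 Hz for gain
recovery. These sizes were chosen so each check resolves its tolerance
comfortably on a single CPU.

## Known limitations

- The GRIN stepping scheme is first-order; accuracy at the default 5 um
  step is adequate for the model's tolerances but marginal rays carry the
  largest error.
- The schematic eye is rotationally symmetric and unaccommodated; no
  chromatic effects, astigmatism, or fitting to individual biometry.
- Sensitivity deviations are not linear in the perturbation for every
  parameter, so summaries that interpolate between perturbation sizes
  will disagree with recomputed mid-size values; the scan reports both
  per-ray and centroid deviations so either convention can be compared.
- Flat-mount contour unfolding assumes azimuthal-equidistant flattening.
- The classifier requires the manual capture-end timestamp, as in the
  tracking protocol; fully automatic capture detection is out of scope.
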