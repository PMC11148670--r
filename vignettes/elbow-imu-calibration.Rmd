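---
title: "Methods: sensor-to-segment calibration and 3-DOF elbow kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-to-segment calibration and 3-DOF elbow kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elbowcal)
```

This vignette is the package's own account of its model, conventions,
numerical choices and limitations. Nothing stated here as an empirical
result goes beyond what the test suite and `scripts/acceptance.R` compute.

## Conventions

Everything downstream depends on a handful of conventions that the
literature often leaves implicit, so they are fixed once, here:

* **Quaternions** are Hamilton, scalar-first `(w, x, y, z)`, and *passive*:
  a quaternion maps local coordinates into global coordinates
  (global ← local). Composition matches the matrix product of the
  corresponding rotation matrices, and all public functions keep results
  unit-norm to 1e-9.
* **Angles** are degrees at every public boundary; radians appear only
  inside trigonometric kernels.
* **Global frame**: X forward, Y left, Z up; gravity is −Z with magnitude
  9.81 m/s².
* **Segment frames** (trunk, upper arm, forearm): X forward, Y cranial
  (longitudinal, pointing proximally), Z lateral — the flexion axis of a
  right elbow. In the neutral standing pose a segment frame is the global
  frame rotated +90° about global X.
* **Elbow decomposition**: the relative rotation humerus ← forearm,
  `inverse(q_upper) ⊗ q_lower`, is factored with the intrinsic Z–X′–Y″
  sequence into flexion (Z), carrying angle (floating X) and pronation
  (Y). This is the elbow sequence implied by the ISB joint coordinate
  system; the signs are fixed so that flexion and pronation are positive
  for their anatomical motions, verified against the simulator's ground
  truth.
* **Sensor mounting convention** (the manual-alignment assumption):
  segment forward = −sensor y, cranial = +sensor x, lateral = +sensor z.

The middle (carrying) angle of a ZXY factorization is confined to
[−90°, 90°] and the factorization degenerates at ±90°. Elbow data should
never approach that band, so samples within 0.5° of it are *flagged*
per-sample rather than raising an error; flexion and pronation are
phase-unwrapped with a 180° jump threshold.

## Calibration methods

Each method produces a constant quaternion `q0` (segment → sensor) per arm
segment; runtime orientations are then composed as
`q_GS(t) = q_GI(t) ⊗ q0`.

**N-pose.** The thorax anatomical frame is built from the global vertical
(cranial role) and the thorax sensor's nominal forward direction
(−sensor y) orthogonalized against it; both arm segment frames are set
equal to this thorax frame at the calibration instant, and
`q0 = inverse(mean sensor orientation) ⊗ frame`. Two design points are
worth making explicit. First, the vertical reference is the global
vertical of the fused orientation estimates, not the raw accelerometer;
the accelerometer, when present, is used as a consistency *diagnostic*
(warning beyond 10° of disagreement) because a held pose cannot guarantee
an acceleration-free accelerometer but the fused vertical is exactly what
the runtime orientations are expressed in. Second, only the middle 50% of
the static window is used (edges often contain settling motion), the
orientation spread over that window must stay below 2°, and a stillness
failure is an error, not a warning — a moved N-pose silently corrupts
everything downstream.

**Functional calibration.** The flexion axis is estimated from the
lower-arm gyroscope during the flexion/extension movement as the first
right-singular vector of the raw n×3 sample matrix. The matrix is *not*
mean-centered: hinge angular velocity reverses sign across cycles, so its
raw second moment already points along the hinge, and centering would only
matter for a biased gyro. The fraction of gyroscope energy off-axis
(`1 − σ₁²/Σσ²`) is reported as a residual ratio; fits with more than 50%
off-axis energy are rejected as not single-plane. A singular vector has an
arbitrary sign, which here encodes which direction is *positive* flexion;
the sign is chosen so that the first movement lobe projects positively,
which matches protocols that begin with flexion (respectively pronation).
Movements shallower than 0.3 rad/s peak angular speed are rejected as
insufficient motion. The axis is translated into the upper-arm sensor
frame through the window-mean orientations of both sensors (for a hinge
movement the axis is the same at every instant of the sweep, so the window
mean is exact in the noise-free limit); the upper-arm accelerometer mean
during the same movement — the upper arm is held still — provides the
cranial direction, and the frame follows by cross products with the axis
kept exact and the accelerometer direction orthogonalized. For the lower
arm, the pronation axis (longitudinal role) comes from the pronation
movement, and the secondary direction is the global vertical mapped into
the lower-arm sensor frame at the window-mean orientation: with the elbow
flexed at 90° the vertical lies along the segment's forward (X) axis, and
because the carrying-angle rotation is about that same axis, this
construction is exact for a noise-free subject regardless of the carrying
angle. A full-cycle, symmetric pronation sweep makes the window-mean
orientation coincide with the neutral posture.

**Manual alignment.** `q0` is the fixed permutation quaternion of the
mounting convention, `(√2/2, 0, 0, −√2/2)` up to global sign — identical
for both segments and independent of any recording.

## Agreement metrics and segmentation

Metrics are computed per repetition and axis: ROM error (difference of
peak-to-peak ranges), RMSE of the two within-repetition demeaned series
(so constant offsets do not contribute), and offset (difference of means,
reference minus test). Repetition boundaries are the consecutive local
minima of the dominant-axis signal after a 0.25 s moving average, with
minima restricted to the lower 45% of the signal range, clustered minima
collapsed to the deepest, and windows shorter than half the median cycle
discarded; the smoothing constant and the minima rule are this package's
choices, tuned for five-cycle protocols and oracle-tested on constructed
waveforms. When aggregating to cohort summaries the package averages
repetitions within each subject × calibration × task × axis cell first and
then averages cells — subjects, not repetitions, are the unit of analysis;
other weightings would change cohort means by fractions of a degree.

Time alignment between a real optical reference and IMU streams
(resampling plus lag correction) is deliberately out of the desk-scale
path: the simulator produces synchronized series, and the on-disk adapter
validates timestamps instead.

## Repeated-measures statistics

The three-way fully-within-subject ANOVA (calibration × axis × task) is
delegated to `car::Anova` on a multivariate linear model: univariate F
tests, Mauchly sphericity tests and Greenhouse–Geisser epsilons are
standard machinery and reimplementing them would only invite error. The
Greenhouse–Geisser correction is applied per effect when its Mauchly test
is significant at 0.05, mirroring the usual "correct when violated"
practice. Generalized eta squared *is* implemented in-house, because its
defining choice — which strata enter the denominator — must be the
Bakeman pooling: the effect sum of squares over itself plus *every* error
stratum of the design, including the between-subject one. The routine
reports the sums of squares it pooled so the effect size can be audited
against the closed form. Conventional benchmarks for η²G read 0.02 as
small, 0.13 as medium and 0.26 as large. A degenerate input with no
variance at all (the error-free closed loop) reports F = 0, p = 1,
η²G = 0 rather than 0/0.

## The virtual subject

The simulator emulates exactly the recordings the calibration protocols
need: a 3 s static N-pose; a 15–50° flexion/extension calibration
movement; a full-range pronation movement at 90° flexion; and five tasks —
full-range flexion (10–130°), pronation (±80° at 90° flexion), and three
multi-joint tasks (drinking, box-off-shelf, circles) mixing both axes with
gentle trunk motion. Waveforms are raised-cosine cycles (sinusoids for the
symmetric sweeps), C¹ by construction; the stated ranges, not the exact
shapes, are the contract. Defaults are 60 Hz sampling, 15 s task trials
and five repetitions — protocol-plausible values for consumer IMUs, and
also the problem sizes the test suite and acceptance script run at.

The carrying angle is a deterministic function of flexion: a subject
baseline at full extension decreasing by the subject's span (≤ 15°) at
130° flexion, with a linear or half-sinusoid shape. The forearm
orientation is the upper arm composed with the ZXY rotation of the
ground-truth angles, so `elbow_angles()` of the truth orientations
reproduces the truth angles to machine precision — the simulator's
internal consistency invariant.

Corruption maps truth to virtual IMU streams: a per-sensor mounting
rotation (the nominal convention composed with a random-axis misalignment
of configured magnitude), a heading random walk about the vertical at the
configured drift rate (heading is the component fused orientation
estimates actually lose without magnetometers), finite-difference body
rates plus Gaussian noise for the gyroscope, and gravity resolved in the
corrupted sensor frame plus Gaussian noise for the accelerometer. Default
population ranges (carrying angle 8–16° baseline, 5–12° span, 2–8°
mounting error, 2–8° N-pose posture error, gyro 0.01 rad/s, accel
0.05 m/s², drift 0.05 °/s) describe a healthy cohort wearing carefully
taped consumer sensors.

What the simulator does *not* model: flexion-correlated soft-tissue wobble
(the heading walk is the only placement non-stationarity), linear
acceleration in the accelerometer (static gravity only), magnetometer
disturbances, marker-level optical noise in the reference, and anatomical
axis non-orthogonality beyond the carrying-angle model. Consequently,
passing the synthetic closed loop shows the *pipeline* is correct and
shows each calibration's failure mechanism qualitatively (N-pose degrades
with posture error; a tilted flexion axis leaks flexion into the carrying
angle monotonically with the tilt); it does not certify the absolute
accuracy any method reaches on real skin-mounted data.

## Numerical choices

* Frames keep the primary axis exact and orthogonalize the secondary
  (Gram–Schmidt via two cross products); primary/secondary pairs closer
  than 1° are a degenerate-frame error that reports the angle.
* Window-mean orientations use the sign-aligned chordal quaternion mean —
  adequate for the tight orientation clusters of calibration windows, and
  exact for symmetric single-axis sweeps; it is not a general rotation
  average.
* Rotation distances use an asin-based chordal formula, well-conditioned
  near zero where acos of a dot product loses half the available digits.
* Gyroscope synthesis uses central differences of the corrupted
  quaternion series (one-sided at the ends); for a constant-rate rotation
  this recovers the exact angular velocity.
* The zero-corruption configuration nulls *every* deviation — including
  the anatomical carrying-angle baseline, because a subject standing in
  N-pose with a nonzero carrying angle genuinely biases the N-pose
  calibration; the closed loop must isolate pipeline error from modelled
  anatomy.

## Known limitations

The three-way ANOVA requires a complete crossed design and at least three
subjects; incomplete designs are reported cell-by-cell, not imputed. The
highest-order interaction (calibration × axis × task, 16 df) cannot be
sphericity-tested at 13 subjects; it is not among the reported effects.
The on-disk adapter reads only the package's native trial layout and
refuses anything else explicitly — mapping a specific laboratory deposit's
format belongs in a thin conversion script, not guessed at here. Gimbal
flags are advisory; downstream metrics do not exclude flagged samples.
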