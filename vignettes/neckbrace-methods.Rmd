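---
title: "Measuring head-neck range of motion with a serial-chain brace: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring head-neck range of motion with a serial-chain brace: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neckbrace)
```

## The measurement problem

Patients who undergo neck dissection often lose cervical mobility when the
spinal accessory nerve innervating the sternocleidomastoid (SCM) and
trapezius (TR) is manipulated. Quantifying that loss in a routine clinical
visit needs something lighter than a camera laboratory and more stable than
an IMU. The device modelled here is a passive serial chain of six revolute
joints worn between a C7-mounted base and a head cap: each joint carries a
potentiometer, and forward kinematics turns the six voltages into the three
anatomical head angles (flexion/extension, lateral bending, axial
rotation). This package implements the computational stack around that
device: the kinematic model, the design-phase workspace analysis used to
size it, the voltage-to-angle calibration against motion capture, the
angle/EMG signal processing, movement-cycle analysis with pre/post
statistics, and a ground-truthed synthetic digital twin that stands in for
clinical recordings.

## Kinematic model

The chain uses the standard (distal) Denavit-Hartenberg convention: joint
$i$ contributes $\mathrm{Rot}_z(\theta_{0,i}+q_i)\,\mathrm{Trans}_z(d_i)\,
\mathrm{Trans}_x(a_i)\,\mathrm{Rot}_x(\alpha_i)$. The structure encodes the
biomechanics it emulates:

* **J1 ∥ J2** (twist 0 between them): an elbow-like pair whose axes are
  mediolateral, supplying the sagittal translation that the lower cervical
  column contributes during flexion/extension;
* **J3, J4 ⊥ J1/J2**: lateral-bending freedom during flexion/extension;
* **J4, J5, J6 concurrent at a point C**: a spherical wrist standing in
  for the atlanto-axial "ball joint"; J6's axis is vertical at neutral,
  aligned with the cervical axis, so axial rotation is resolved distally.

`validate_chain()` checks all of this numerically (parallelism and
perpendicularity to 1e-9 rad, pairwise common-perpendicular distances of
the wrist axes to 1e-6 mm). The published device's numeric link table is
not recoverable from the source material, so `default_chain()` ships a
parameter set designed to satisfy the constraints and reach the synthetic
workspace: 62 mm proximal links with a bent-elbow neutral
($\theta_{0,1} = 35°$, $\theta_{0,2} = -70°$, so the rotation center is
not at the edge of reach), a 25 mm offset link into the wrist, and a 60 mm
end-effector offset placing the head-top point P directly above C.

```{r chain}
default_chain()
```

Inverse kinematics is damped least squares (Levenberg-Marquardt) on a
6-vector pose error: position in mm stacked with the axis-angle orientation
error scaled by a 100 mm characteristic length, joint limits enforced by
projection, with adaptive damping and a small set of deterministic restart
seeds. IK is a *local* method: on trajectories every solve is warm-started
from the previous solution (`ik_trajectory()`), which is also how the
physical device behaves - it tracks continuously from the neutral donning
pose. Non-convergence is data, not an error: unreachable targets return
the best solution with `converged = FALSE` and the residual (which for far
targets is essentially the distance to the reachable boundary).

### Head angles

Anatomical angles use the intrinsic vertical → anteroposterior →
mediolateral sequence on the rotation relative to the neutral posture, in
an anatomical frame with x anterior, y left, z up; signs follow clinical
convention (+extension, +right bending, +right rotation). Two frames
matter:

* marker-built head frames are anatomically aligned at neutral, so
  `head_angles_from_pose()` decomposes $R_\text{neutral}^\top R$ directly;
* the brace end-effector frame is *not* anatomically aligned, so
  `head_angles_relative()` first conjugates the relative rotation into the
  anatomical axes given by the mounting matrix (`default_mounting()`:
  base x = up, base y = anterior, base z = left). `apply_calibration()`
  uses this route.

Near gimbal lock (|lateral bending| within 0.5° of 90°) results are
flagged degenerate; the composition is still exact, but the axial/sagittal
split is ill-conditioned. Cervical bending never approaches 90° in
practice.

## Design-phase workspace analysis

Eight markers form two rigid bodies (trunk: C7, chest, both acromions;
head: C1, head top, both sides). `build_reference_frame()` constructs both
frames from the static neutral trial by Gram-Schmidt on the marker
differences; `to_trunk_frame()` re-expresses dynamic marker paths in the
per-sample trunk frame (C7 at the origin), removing trunk motion. The
head-top cloud approximates a spherical cap about the atlanto-axial
center; `fit_sphere()` runs an algebraic least-squares solve refined by
orthogonal-distance Gauss-Newton and reports center, radius and RMS
residual.

`search_dh_parameters()` is the sizing loop: a finite grid over chosen
link parameters (by default the two proximal link lengths, ±30 mm in 5 mm
steps - the twists stay fixed because they encode the axis structure), a
farthest-point subsample of the workspace (200 points, reordered into a
nearest-neighbour tour so warm-started position-only IK always moves
between nearby targets), feasibility = every point reached within 2 mm
with joints in limits, ranking by total link length as a weight proxy.
Candidates that break the structural constraints are simply infeasible.

`check_clearance()` implements the head/linkage interference test: the
plane through the C1 marker and the two acromions splits space into a head
region and a neck region, and the J4 origin must stay on the neck side.
One honest caveat: in the shipped chain topology the J4 origin coincides
with C itself (the wrist has zero intermediate offsets), which sits almost
directly below the head-top marker - no such plane separates them for the
default anthropometry, so the CLI applies the clearance filter only on
request. The published device evidently offsets J4 physically; those
dimensions are part of the unrecoverable link table. The operation itself
is fully implemented and tested on geometry where a separating plane
exists.

`derive_joint_limits()` turns IK joint trajectories from the recorded
motions into operating ranges, padded by a 5° margin per side.

## Calibration

Real devices differ from their nominal model, so the map from
potentiometer voltage to joint angle is fitted, not assumed. The reference
comes from motion capture: head poses from the markers, joint angles by
warm-started IK, interpolated onto the 100 Hz brace timeline. Stage 1 fits
each joint's polynomial (degree 3 by default, configurable 1-5)
independently by least squares in a centered and scaled voltage variable
(raw-volt Vandermonde matrices are numerically singular). Stage 2, on by
default, refines all coefficients jointly by BFGS on the summed squared
*head-angle* error between the forward-kinematics reconstruction and the
mocap reference - head angles are what the device reports, so that is the
error that matters. Monotonicity of each fitted map over its observed
voltage range is checked numerically and warned about; neutral voltages
are averaged over the initial neutral rest. Reconstruction flags (rather
than drops) samples outside the calibrated range plus a 5% extrapolation
guard, because polynomials diverge outside their support.

Validation compares brace-reconstructed and mocap head angles on the
primary angle of each single-plane trial (both zero-phase low-pass
filtered at 6 Hz), reporting per-trial maximum and RMS differences, the
group maximum, and the mean RMS over trials - the device's headline
accuracy numbers.

## Signal processing

No DSP package is available in this stack, so Butterworth design (analog
prototype, prewarping, bilinear transform) and zero-phase filtering (odd
edge extension with steady-state initial conditions, forward and backward
passes) are implemented in the package and pinned by tests to the analytic
Butterworth magnitude response; a constant series passes through to
machine precision. Angle streams get the zero-lag 4th-order 6 Hz low-pass.

The EMG linear envelope follows the six-step recipe exactly and in order:
optional cardiac-artifact suppression (off by default - the 60-200 Hz
band-pass already removes most ECG energy; an ensemble template-subtraction
stage is available since the original used closed vendor software), mean
subtraction, 4th-order zero-phase band-pass 60-200 Hz, full-wave
rectification, centered 300-sample (0.2 s) moving average with
shrink-at-edges, and normalization of each channel by its largest envelope
value across all of the participant's recordings in that visit (so each
channel's visit-wide maximum is exactly 1, and the operation is
idempotent). The tests distinguish rectify-then-filter from
filter-then-rectify explicitly; the order is load-bearing.

The two acquisition systems are aligned by a shared digital trigger:
first rising edges define a common t = 0, EMG is linearly interpolated
onto the 100 Hz brace timeline, and streams are cropped to their overlap.
All filters being zero-phase keeps envelope peaks aligned with motion.

## Movement cycles and outcomes

A trial is five continuous cycles of neutral → one extreme → opposite
extreme → neutral. Segmentation runs on the filtered primary angle with
hysteresis (departure beyond 20% of the trial's peak magnitude, return
inside 10%), requiring one excursion of each sign per cycle; detected
boundaries are then anchored at the |angle| minima of the neutral dwells,
so on clean data they coincide with the true neutral-to-neutral limits.
Trailing partial excursions are discarded. Cycles are resampled to 101
points (0-100%), phase-aligned by the sign of the first extremum (patients
chose their first direction; averaging opposite-phase cycles would
cancel), and averaged pointwise. Outcomes per cycle: completion time,
signed peak angles, range of motion (max - min), and each muscle's
envelope-peak timing in percent cycle with ties resolved to the earliest
sample. Peak timings are computed both on the averaged cycle and per
cycle.

Pre/post comparison is the paired t test with 95% confidence intervals,
two-sided, significance at p < .05, implemented in closed form
($t = \bar d / (s_d/\sqrt{n})$, CI $= \bar d \pm t_{0.975,n-1}
s_d/\sqrt n$) and tested to 1e-10 against `stats::t.test`. Zero-variance
differences are handled explicitly (t = ±Inf, p = 0 for nonzero mean;
degenerate flag, p = 1 for all-zero). No multiple-comparison correction is
applied, mirroring the original analysis; with ~30 outcome variables some
nominally significant rows are expected by chance.

## The synthetic digital twin

Because no recordings are deposited, every test runs against a generator
whose defaults *are* the stated world:

| quantity | default | basis |
|---|---|---|
| cycles per trial | 5 | protocol |
| cycle period | 3.41 / 4.00 / 3.89 s (axial / bending / flex-ext) | group means, pre-op |
| amplitudes | 70/70, 40/40, 60 ext / 50 flex (deg) | healthy full-range values |
| secondary-plane coupling | 10% of primary | free parameter, unquantified coupling |
| marker noise | 1 mm isotropic Gaussian | typical optical mocap |
| voltage noise | 0.5% of 3.3 V full scale | inexpensive potentiometer + ADC |
| sensor map | per-joint monotone cubic, distinct shapes | exercises degree-3 calibration, out-of-class for degree 1 |
| EMG | 60-200 Hz Gaussian carrier, burst-modulated per the rope schedule; bursts at 20% / 70% cycle, width 30% | muscles peak near their motion phase |
| cardiac artifact | 1.2 Hz biphasic spikes, ~2x baseline | exercises the optional suppression stage |
| trigger | 0.3 s pulse; EMG clock offset 0.5 s | exercises synchronization |

Head-angle profiles are C1-smooth biphasic raised cosines (extremes at 25%
and 75% of the cycle). The rotation center C translates 0.3 mm/deg
anteriorly with flexion and toward the bend side with bending - small,
anatomically motivated couplings that also guarantee every joint
(including J3) is excited, which per-joint calibration needs. Joint
trajectories come from IK on the exact pose targets, voltages from the
closed-form inverse of the true sensor map (Cardano), markers from rigid
motion about C in an arbitrarily rotated lab frame, EMG as described.
Everything is seeded and bitwise reproducible; ground truth (angles,
joints, cycle boundaries, burst centers) travels with each trial.

What the twin deliberately does **not** model: soft-tissue marker
artifact, trunk motion during trials (subjects are seated; trunk
compensation is still exercised through the per-sample trunk frames),
marker occlusion, EMG motor-unit structure, inter-trial amplitude drift,
and any systematic mismatch between the brace model and a physical
device beyond the nonlinear sensor map. A green validation bound here
therefore establishes that the *pipeline* is correct and that the method
meets the stated accuracy under the stated noise - not that a physical
prototype would.

The cohort generator draws per-subject amplitudes (between-subject SD 3°)
and injects the pre→post deficit exactly (default: 8° off the
dissected-side bending extreme), so recovery tests compare the pipeline's
estimate against a known truth. One calibration model is shared across the
cohort, as the device is calibrated once, not per patient.

## Numerical choices

* IK: damping starts at 1e-3, /10 on success (floor 1e-12), x10 on
  rejection; stop when the error norm is below 1e-10 or stalled; a
  small-angle `asin` path replaces `acos` in the orientation error below
  1e-3 (acos loses half the significant digits near identity, which
  capped round-trip accuracy at ~1e-6 deg).
* Polynomial calibration is fitted in `u = (V - center)/halfspan`.
* Zero-phase filtering uses odd extension of length 3x the filter length
  plus steady-state initial conditions, matching standard practice.
* The moving average uses a centered window spanning [-150, +149] samples
  (even window) and shrinks at the edges.
* Sphere fitting declares degeneracy below a reciprocal condition number
  of 1e-10 (coplanar clouds).
* Segmentation thresholds are fractions of the trial's own peak, so the
  same rule serves 40° bends and 70° rotations.

## Limitations

Serial chains accumulate error distally - a few degrees of error against
motion capture is the realistic operating point, acceptable against
100°-scale motions. The default chain is a plausible stand-in, not the
published device's geometry; absolute joint trajectories are therefore
synthetic-world quantities, while head angles (the reported output) are
device-independent. The clearance criterion is topology-limited for the
shipped chain as discussed above. EMG peak timing inherits the variance of
envelope maxima on stochastic carriers; per-cycle spreads are retained for
that reason.
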