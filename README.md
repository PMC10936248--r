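# neckbrace

Computational toolkit for a six-revolute-joint serial-chain wearable neck
brace that measures head-neck range of motion (RoM), developed to document
cervical mobility changes in patients undergoing neck dissection. The
device is passive: a potentiometer on each joint, a base at C7, an
end-effector on the head. Everything downstream of the sensors lives
here:

* **Kinematics** - standard Denavit-Hartenberg forward kinematics of the
  6R chain (J1 ∥ J2; J3, J4 ⊥ J1; J4-J6 concurrent at the atlanto-axial
  stand-in point C), damped least-squares inverse kinematics with joint
  limits and warm starts, and anatomical head-angle extraction
  (intrinsic vertical → anteroposterior → mediolateral sequence).
* **Design phase** - trunk/head frames from an 8-marker set, workspace
  point clouds in the trunk frame (C7 origin), sphere fitting
  (algebraic + orthogonal-distance refinement), exhaustive link-parameter
  search with reachability screening, head/C1 clearance-plane check,
  joint operating ranges.
* **Calibration** - per-joint polynomial voltage-to-angle maps fitted
  against motion-capture inverse kinematics, with optional joint
  refinement minimizing head-angle error; validation metrics (per-trial
  max and RMS error on the primary angle).
* **Signals** - zero-lag 4th-order Butterworth angle filtering at 6 Hz;
  the six-step surface-EMG linear envelope (cardiac handling, mean
  removal, 60-200 Hz band-pass, rectification, 300-sample / 0.2 s moving
  average, visit-wide normalization); trigger-based synchronization of
  the 100 Hz brace and 1.5 kHz EMG streams.
* **Analysis** - movement-cycle segmentation with hysteresis, 101-point
  time normalization and averaging, outcome variables (completion time,
  peak angles, RoM, EMG peak timing in % cycle), paired t tests with 95%
  CIs: `CI = mean(d) ± t_{0.975, n-1} · sd(d)/√n`.
* **Synthetic digital twin** - seeded generator of complete sessions
  (markers at 200 Hz, voltages at 100 Hz through a true nonlinear sensor
  map, EMG at 1.5 kHz modulated by the rope-model muscle schedule, shared
  trigger) with full ground truth, plus pre/post cohorts with injected
  RoM deficits for recovery studies.

See `vignettes/neckbrace-methods.Rmd` for the models, conventions,
parameter choices and limitations.

## Worked example

Calibrate the device on one synthetic session and validate on a held-out
one:

```r
library(neckbrace)

cal <- generate_session(seed = 11)           # static + 3 single-plane trials
model <- calibrate_session(cal, refine = FALSE)
val <- generate_session(seed = 22)           # independent session
validate_session(model, val)
```

```
<validation_report>
 trial            motion max_abs_error_deg rms_error_deg
     1    axial_rotation             1.714        0.6626
     2   lateral_bending             2.126        0.6724
     3 flexion_extension             3.763        1.2778
group max error 3.763 deg; mean RMS 0.871 deg
```

Reading: with 1 mm marker noise and 0.5% full-scale voltage noise, the
brace-reconstructed primary head angles track the motion-capture reference
to under 1° RMS and at worst ~3.8° - inside the device's engineering bounds
(RMS < 5°, max < 6°) with margin.

A pre/post cohort with a known injected deficit:

```r
coh <- generate_cohort(n_subjects = 5, seed = 42, delta_deg = 8)
res <- cohort_peak_angle_change(coh, model)
res$stats
```

```
paired t: n=5, mean diff -8.039 (95% CI -9.448 to -6.629), t=-15.84, df=4, p=9.29e-05 *
```

The pipeline recovers the injected 8° lateral-bending peak-angle loss as
-8.04° (post - pre) with a confidence interval excluding zero.

There is also a command-line front end
(`Rscript -e 'neckbrace::brace_cli()' <subcommand> ...`) with subcommands
`simulate`, `design-search`, `calibrate`, `validate`, `process`,
`analyze`, `report`, reading/writing the CSV/JSON/YAML session formats
described in the function documentation.

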