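---
title: "Estimating overstriding from wearable IMUs: methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating overstriding from wearable IMUs: methods and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: why
overstriding can be predicted from segment angles, how sagittal angles are
recovered from IMU orientation quaternions without succumbing to heading
drift, how unsynchronized sensor streams are aligned, how gait events and
braking force are extracted, how the stride records are modelled, and why the
synthetic study generator is calibrated the way it is.

## 1. Overstriding as a kinematic identity

Work in a lab frame with $x$ forward, $y$ left, $z$ up. Define the sagittal
thigh and shank angles $\theta_t, \theta_s$ against the vertical, positive
when the distal end is ahead of the proximal end, and the foot angle against
the horizontal, positive toe-up. Overstriding (OS) is the horizontal distance
from the hip to the ankle at foot contact (FC). Because hip, knee and ankle
form a two-link chain of lengths $L_t$ (thigh) and $L_s$ (shank),

$$
\mathrm{OS} \;=\; L_t \sin\theta_{t,\mathrm{FC}} + L_s \sin\theta_{s,\mathrm{FC}}
$$

holds exactly, whatever the gait. This identity does three jobs in the
package. First, it is the marker-based reference: `overstriding_from_markers()`
computes hip-to-ankle horizontal distance directly from marker positions, and
the identity is the strongest possible unit test for the kinematics code
(agreement to numerical precision on noiseless data). Second, it motivates
the statistical question: if OS is a smooth function of two segment angles,
then IMUs that measure those angles (plus the foot angle, a landing-style
covariate) should predict OS well — the empirical question is how much the
IMU error chain (mounting, drift, noise, asynchrony) erodes that. Third, it
fixes the normalization: OS is reported normalized by leg length
(`overstriding_norm`), since the identity scales linearly with segment
lengths.

Peak braking force (PBF) is the extremum of the posteriorly directed
ground-reaction force during stance, in body weights. It is mechanically
linked to landing geometry — a foot planted further ahead of the hip brakes
harder — so the same angle predictors are used for PBF models.

## 2. Sagittal angles from IMU quaternions

Each IMU reports its orientation $R(t)$ (body→world quaternion). Two
problems separate $R(t)$ from a usable segment angle:

1. **Mounting**: the sensor is strapped on with an unknown constant rotation
   relative to the segment — tilt, spin about the strap, possibly flipped
   axes. Only one piece of metadata is assumed: which *local sensor axis* is
   (approximately) the medio-lateral joint axis. Its *sign* is not assumed
   known, because a wearer cannot reliably distinguish "points left" from
   "points right" after strapping; the pipeline resolves the sign
   functionally (Section 3).
2. **Heading drift**: gyro integration and magnetometer-free fusion leave a
   slowly growing error that is almost purely a rotation about gravity,
   $R_\mathrm{drift}(t) = R_z(\gamma(t))$, composed on the world side:
   $\tilde R(t) = R_z(\gamma(t))\,R(t)$.

### Static-pose calibration

The simple scheme (`method = "static_pose"`): average the quaternion over a
standing window, then express every sample relative to that mean,
$q_\mathrm{rel}(t) = q(t)\,\bar q_\mathrm{static}^{-1}$, and read the rotation
angle about the joint axis. This removes the mounting rotation exactly, but
the drift accumulated *since the standing window* leaks straight into the
angle: if $\gamma$ grows by 30° over a trial, the late-trial angle error is
of the same order. It remains the method of choice for short, stationary
protocols — in this package, treadmill trials, where each trial has its own
fresh standing calibration and drift accrual is small.

### Per-frame reference redefinition

The drift-robust scheme (`method = "per_frame"`) rebuilds the reference frame
at every sample from two directions that drift cannot corrupt:

* gravity $\hat z$ — a left-composed $R_z(\gamma)$ fixes $\hat z$ by
  construction;
* the current world-frame joint axis $a(t) = \tilde R(t)\, a_\mathrm{local}$,
  projected onto the horizontal plane to give $y'(t)$, with
  $x'(t) = y'(t) \times \hat z$ completing a right-handed horizontal-forward
  axis.

The segment direction $v(t)$ (the globalized completion of the local axis
pair) is then measured in this instantaneous frame:
$\theta(t) = \mathrm{atan2}(-v\cdot x',\; v\cdot\hat z)$.

Why drift is *annihilated*, not merely reduced: replace $\tilde R$ by
$R_z(\gamma)\tilde R$. Every world-frame vector in the construction —
$a$, $y'$, $x'$, $v$ — is premultiplied by the same rotation about $\hat z$,
and $\hat z$ itself is unchanged. The two dot products defining $\theta$ are
invariant under a common rotation of both arguments, so $\theta$ is exactly
independent of $\gamma(t)$, for any drift magnitude and any time course.
The cost is a degeneracy when the joint axis approaches vertical (the
horizontal projection vanishes); `sagittal_angle_imu()` raises an error
inside a 5° cone rather than returning garbage. For sagittal running motion
the axis stays near horizontal and the method is used for the long
overground trials, where drift accrual is largest.

One subtlety: with a spun or flipped mounting, the raw extracted angle can
sit near the ±180° branch cut of `atan2`, so the series is unwrapped
(`unwrap_deg`, removing ±360° jumps) *before* subtracting the standing-window
mean. The subtraction then anchors the unwrapped series so that standing
reads 0° regardless of mounting.

## 3. Synchronization and sign resolution

Each IMU starts recording 90–180 ms after motion capture, on its own clock,
so every sensor stream carries its own unknown delay. Alignment is by
cross-correlation of the IMU angle series against the marker-derived angle of
the *same segment*, both resampled to a common analysis rate
(`analysis_rate`, 200 Hz), with the lag search bounded by `sync_max_lag`
(0.25 s, comfortably above the physical delay range).

The correlation window (`sync_window`, default 12 s) is chosen on two
grounds. The protocol begins with a standing period and a brief, deliberately
non-periodic calibration maneuver (a step plus a leg swing); the maneuver is
the unique anchor that makes the lag identifiable at all — periodic running
alone would admit whole-period aliases. But the maneuver is slow, and with
realistic sensor noise and soft-tissue wobble its correlation peak is broad;
extending the window into the first running strides adds sharp, high-slope
features that tighten the peak to sub-sample precision. Including periodic
content is safe here because the stride period (≥ 0.6 s) exceeds twice the
maximum searched lag, so no alias falls inside the search range.

The unknown joint-axis *sign* falls out of the same computation: if the
metadata axis points the wrong way, the IMU angle series is negated, the
correlation peak is large and *negative*, and the pipeline flips the sign and
re-anchors. This is the functional sign resolution promised in Section 2.

## 4. Gait events, strides, and braking force

Foot contact and toe-off are threshold crossings of the low-pass-filtered
vertical GRF (4th-order zero-phase Butterworth, 50 Hz cutoff; 20 N
threshold), with linear interpolation between the bracketing samples for
sub-sample timing, and debouncing windows (`min_stance`, `min_flight`) to
reject chatter. A leading above-threshold segment with no onset (e.g. the
tail of quiet standing on the plate) is dropped. Stride frequency and duty
cycle come from consecutive FCs of the instrumented side; overground gaps
longer than a maximum stride time are excluded rather than spliced. PBF is
the most negative value of the anterior–posterior force projected onto the
direction of progression during stance, divided by body weight. Marker data
are filtered at 10 Hz; the direction of progression is the horizontal
displacement of the sacrum over the stride (overground) or the belt axis
(treadmill).

Stride selection mirrors common practice: the last `tm_keep_last` strides of
each treadmill trial (steady state), and overground strides within
±`og_speed_band` (5%) of the participant's median stride speed.

## 5. Statistical models

Strides are repeated within participants, so every model is a
random-intercept linear mixed model fitted by REML (`fit_stride_lmm()`,
backed by `lme4`), with predictors and response z-scored within the pooled
condition class so that coefficients are standardized effects. The menu
(`run_model_menu()`) crosses {OS, PBF} × {treadmill, overground} ×
{mocap angles, IMU angles}; comparing the mocap and IMU columns of the menu
*is* the validation: measurement noise in a predictor attenuates its
standardized coefficient and the model's marginal R².

Reported inference is Wald (normal) — appropriate at the study's stride
counts — plus the variance decomposition: with $\sigma_f^2$ the variance of
the fixed-effect predictions, $\sigma_b^2$ the random-intercept variance and
$\sigma_e^2$ the residual,

$$
\mathrm{ICC} = \frac{\sigma_b^2}{\sigma_b^2 + \sigma_e^2},\qquad
R^2_\mathrm{marginal} = \frac{\sigma_f^2}{\sigma_f^2+\sigma_b^2+\sigma_e^2},\qquad
R^2_\mathrm{conditional} = \frac{\sigma_f^2+\sigma_b^2}{\sigma_f^2+\sigma_b^2+\sigma_e^2}.
$$

Degenerate inputs are handled explicitly: a single participant reduces to
OLS with a warning (ICC 0), a boundary fit ($\hat\sigma_b^2 = 0$) warns, and
unfittable menu entries are skipped with a warning rather than failing the
run. The REML machinery is cross-checked in the test suite against an
independent EM-algorithm REML implementation on a printed fixture, and, at
study scale, against Monte-Carlo parameter recovery with closed-form targets
for ICC and both R² values.

## 6. The synthetic study generator

Real validation data for this pipeline would require synchronized optical
capture, force plates and multiple IMUs. The generator
(`simulate_study()`) instead produces all three streams from a single planar
forward-kinematic ground truth, so that every downstream quantity — angles
at FC, OS, PBF, event times, sensor delays — has a known true value. Its
defaults encode the intended study design, and they are fixed design choices,
not tuning knobs: a 10-participant protocol of five metronome-paced treadmill
trials at 75–95 strides/min (25 strides each) plus a one-minute
comfortable-speed overground trial with intermittent force-plate coverage
(~13 recorded strides per participant).

Design decisions worth spelling out:

* **Consistency by construction.** Marker positions are forward kinematics of
  the simulated segment angles; the vertical GRF is an analytic stance bump
  whose 20 N crossings land exactly on the scheduled FC/TO times; the braking
  pulse peaks at the scheduled PBF. Markers, forces and IMUs are therefore
  mutually consistent before any corruption is added, which is what makes the
  noiseless geometric-identity and event-recovery tests exact rather than
  approximate.
* **Angle model.** Each segment angle is a mean path through the per-stride
  FC targets plus first- and second-harmonic swing terms, so FC-time values
  are controlled exactly while the intra-stride waveform stays
  running-shaped. FC targets follow a linear stride-frequency trend with
  participant-level random offsets and correlated stride-to-stride noise —
  the covariance structure the mixed models are built for.
* **Calibration of magnitudes.** Segment-angle means and their
  stride-frequency slopes were set so that the implied OS (via the identity
  in Section 1) and its within-participant range across the treadmill
  conditions land at physiologically sensible running values (condition-mean
  OS ~18–23 cm; per-participant OS range across cadences ~5 cm), and the PBF
  model (participant intercepts plus angle-linked stride effects around
  0.2–0.3 BW) produces a cadence response of ~0.1 BW. These were derived
  analytically from the identity and the trend slopes, not fitted to
  pipeline output.
* **Sensor corruption.** IMU quaternions are built as
  $q_\mathrm{drift}\otimes q_\mathrm{seg}\otimes q_\mathrm{pert}\otimes q_\mathrm{mount}$:
  world-side heading drift (0.1 °/s), a true segment rotation, soft-tissue
  wobble plus orientation noise (2° RMS), and a mounting rotation composed of
  a signed axis permutation, a tilt, and a spin about the strap. Streams
  start at a uniform 90–180 ms delay on their own clock and carry random
  quaternion sign flips ($q$ and $-q$ encode the same rotation — the pipeline
  must not care). Markers get 0.5 mm noise, forces 1 N.
* **Stress content.** Overground strides include per-stride speed variation
  with occasional ±9% outliers (exercising the 5% speed filter), and plate
  coverage comes in stride pairs with gaps (exercising the gap-exclusion
  logic).

With the default 2° RMS orientation noise and wobble, the pipeline's pooled
FC-angle RMSE against mocap comes out in the 2–5° range reported across the
IMU gait literature — i.e. the generator's noise model is calibrated to make
the synthetic validation about as hard as the real one.

## 7. Limitations

The generator is planar: it cannot probe out-of-sagittal cross-talk,
magnetometer disturbance structure, or foot-strike-type asymmetries. Drift is
modelled as pure heading rotation — the component the per-frame method
provably removes; real fusion error has a (smaller) tilt component that it
does not. The mixed models use random intercepts only; random slopes would be
the natural next step for larger cohorts. And the identity in Section 1 makes
mocap-based OS models nearly tautological — their value here is as the
ceiling against which the IMU models are judged.
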