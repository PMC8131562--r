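---
title: "Assessing motion-induced field exposure near MRI magnets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing motion-induced field exposure near MRI magnets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mriexposure)
```

## The physical model

A person moving through the static stray field of an MRI magnet carries
free charges across **B**; the Lorentz force per unit charge is the
electromotive field **v** × **B**. Inside tissue a reaction electrostatic
field builds up and partially opposes it, but computing that reaction field
would require a full electrical body model; neglecting it leaves |**v** ×
**B**| as a tractable and *precautionary* (over-)estimate of the internal
field that Directive 2013/35/EU limits. This is the package's exposure
metric. Physiological internal motion (blood flow, etc.) is outside scope,
as is tissue-level dosimetry.

The guideline alternative, `icnirp_estimate()`, computes E_i = C·d|B|/dt
with a lumped "conversion factor" C. It discards the vector geometry of the
motion and is kept only for comparison; no calibrated value of C exists for
this configuration, so its default (0.2 m) is a placeholder magnitude and
results are labelled as comparison output.

### The stray field as a point dipole

Outside the bore, the field of a closed full-body scanner is represented by
a single point dipole

$$\mathbf B(\mathbf r) = \frac{\mu_0}{4\pi}\,
  \frac{3(\mathbf m\cdot\hat{\mathbf r})\hat{\mathbf r}-\mathbf m}{r^3},$$

with moment magnitude m, direction along the bore axis, positioned at the
magnet isocenter height. The magnet's internal architecture is unknown to
the surveyor, which is exactly why a parsimonious source model plus a
measured grid is attractive: the model has two free parameters once the
preliminaries are fixed.

`fit_dipole()` conforms the model to a survey of |B| over 70 planar
stations × 3 heights (0.72, 1.19, 1.56 m) = 210 measures, adjusting only
the planar offsets (Δx, Δy) of the dipole position by Levenberg–Marquardt
least squares (via `minpack.lm`), starting at (0, 0) with tolerance 1e-12
on the objective. The moment magnitude and height stay at their preliminary
estimates — for the 3.0 T reference machine, 1.06 MA·m² and 1.00 m. An
opt-in `refine_moment` mode adds m as a third parameter; it exists for
parameter-recovery studies, not for routine fitting. Model adherence is
summarised by the Pearson correlation of predicted vs measured |B|.

Two degeneracies are guarded: evaluation at the dipole position raises a
singularity error, and (nearly) collinear measurement positions — which
leave the transverse offset undetermined — raise a rank-deficiency
warning.

The exact planar arrangement of the 70 stations is configurable (YAML
layout files, `read_grid_layout()`); the shipped default mixes the 0.20 m
short step in the rows nearest the bore with the 0.40 m long step
elsewhere, preserving the published counts and spacings.

## Kinematics

Recordings are labelled marker trajectories at 100 Hz, in metres, room
frame (z up, origin at the map corner nearest Door A, 0-based frames).
`read_recording()` accepts the package CSV dialect and TRC (mm, converted
on read). C3D is a binary vendor format with no reader in the supported
stack; trials should be exported to TRC or CSV.

Processing follows the laboratory chain:

1. **Gap filling** — linear interpolation across occlusions of at most 10
   frames (0.1 s); longer gaps are an error rather than a guess.
2. **Smoothing** — zero-phase low-pass Butterworth (order 4, cutoff 6 Hz,
   forward–backward). Gait content lives below ~3 Hz, so a 6 Hz cutoff
   passes signal essentially untouched (< 1% attenuation at 1 Hz) while
   removing marker jitter. Plain forward–backward filtering has large edge
   transients, so the series is first detrended by the line through its
   endpoints and padded by odd reflection; constants and linear ramps are
   therefore preserved exactly. The classical generalised cross-validated
   smoothing spline is available as `method = "spline"` for trials with
   unknown frequency content.
3. **Centroids** — each tracked segment carries a cluster of ≥ 3 skin
   markers; the segment's representative point is the per-frame arithmetic
   mean. Centroids average out individual skin-motion artifact, which is
   why they anchor the exposure points.
4. **Differentiation** — central differences at interior frames, one-sided
   at the ends. Trial endpoints are door frames far from the magnet, so the
   lower-order endpoints are immaterial for exposure.

The 23 exposure points are 11 segment centroids (head, trunk, pelvis, both
thighs, tibias, feet, hands) and 12 individual markers (four head markers,
T2, the inter-scapular midpoint, the jugular notch, the xiphoid process,
and the four iliac spines). The head subset — head centroid plus the four
head markers — feeds the sensory-effects assessment. The head "centroid" is
defined as the mean of the four head markers, which form the head cluster.
No joint-center regression is performed: the six anatomical-calibration
markers appear only in the static trial and are excluded from dynamic
processing.

## Exposure and compliance

`assess_task()` evaluates E[t, i] = |v_i(t) × B(p_i(t))| with **B** taken
from the dipole model *at the point's instantaneous position* — the model
is continuous in space, so no static room-map lookup or interpolation is
involved. Per-frame maxima over the 23 points (whole-body) and over the
5-point head subset, and the task peak, summarise each trial.

Compliance is strict ("did not exceed"): the whole-body task peak must stay
below the health ELV of 1.1 V/m, and the head task peak below the
sensory ELV 0.7/f V/m. Margins are reported signed so that a failure shows
how far over the limit the trial went.

### The motion-related frequency

The sensory ELV needs f. The estimator is the spectral centroid of the raw
periodogram: mean removal, no taper, the full task as a single window
(resolution 1/T_task), centroid over positive frequencies up to Nyquist.
The analysed signal is the head peak-exposure series of the task — the
induced pulse the ELV is compared against — configurable to any per-point
series. Among the defensible choices (tapering, Welch averaging,
per-point speed signals) this is the simplest fully reproducible one; a
single tone is recovered to well within the periodogram resolution, and an
additive offset does not move the estimate.

## The synthetic generator

Because no deposited motion-capture or magnetometer data exist, the
package ships a seeded generator for both inputs.

**Field maps** (`make_field_map()`): |B| of a known dipole at every grid
position times (1 + ε), ε ~ N(0, σ²) with σ = 2% by default —
multiplicative because Hall-probe error scales with the reading — clipped
to keep readings positive.

**Task trajectories** (`make_task_recording()`): twelve scripts mirror the
study tasks (N1–N6 routine, E1–E4 emergency, C1–C2 cleaning) in a 4 × 6 m
room with doors A/B/C and the magnet at (2, 5) m, bore along +y, couch
toward the room. The pelvis follows script waypoints with a speed envelope
that is high at the doors and falls to 0.35 m/s within 1.2 m of the magnet
(the U-shaped profile), slowing additionally in turns (lateral-acceleration
limit 1.5 m/s²). Limbs oscillate about the pelvis with stride frequency
min(0.9·v + 0.6, 2.2) Hz and amplitudes tied to walking speed, capped at
95%/93% of the 5 m/s foot and 3.5 m/s hand limits to leave reserve for
smoothing overshoot and noise; trunk and head ride a small vertical bob.
Near-magnet actions are modelled kinematically: bends lower the upper body
until the head reaches a scripted height (0.90 m for object recovery) at
≤ 1.5 m/s, patient checks extend the hands 0.25 m, couch extraction
oscillates the hands longitudinally — deliberately *along* the bore axis,
where **v** ∥ **B** keeps the induced field low, as a real extraction
would. Anthropometry scales all marker offsets from the operator's
stature; every coordinate carries 2 mm Gaussian noise. Walking speed is
1.8 m/s × stature/1.72 × script pace, additionally limited to the
profile's head-speed cap / 1.2 (2.2 m/s for the tall radiographer, 2.0 for
the small one, 1.0 for the cleaner) — which reproduces the observed
regimes: the small radiographer's head never reaches 2 m/s, the tall one's
occasionally may, the cleaner's stays below 1 m/s.

What the generator does *not* emulate: validated human gait dynamics
(double support, joint kinematics), ground reaction, marker occlusion
patterns beyond short gaps, or skin-motion artifact. Passing tests
therefore demonstrate that the *pipeline* — smoothing, differentiation,
field evaluation, peak logic, thresholds — is correct under realistic
magnitudes and geometry, not that real operators behave exactly like the
fixture. The waypoint geometry is parameterised rather than surveyed, and
a minimum 0.7 m standoff of all body points from the dipole position is
validated at generation time.

## Numerical choices and problem sizes

* Fit: LM with numeric Jacobian, ftol = ptol = 1e-12, bounds ±5 m on the
  offsets; noiseless self-fits recover offsets to < 1e-6 m with Pearson
  r = 1 − 1e-9.
* Smoothing pad length: max(12, 3·rate/cutoff) samples, odd reflection.
* Periodogram: `stats::fft`, no zero-padding; centroid excludes the DC
  bin.
* Degenerate inputs error early and by name: too-short series, missing
  labels (naming the point), zero-variance correlations, non-positive
  frequencies, infeasible speed envelopes, waypoints outside the room or
  inside the standoff.
* Test and demonstration sizes: trials of 9–13 s (900–1300 frames × 41
  markers), 210-record maps, 20-seed recovery studies, 10-seed compliance
  sweeps across all twelve scripts — sizes at which the full suite runs in
  well under a minute while exercising every stage at study scale.

## Limitations

The dipole is a single-source model: multi-coil leakage, shielding and
soft iron are not represented (a fitted Pearson r near 1 on a measured map
is the empirical justification for using it). The exposure metric excludes
the tissue reaction field, so results are conservative by construction.
The sensory rule is implemented exactly as the two printed limits
(1.1 V/m; 0.7/f V/m); the Directive's full frequency-banded tables are not
reproduced. Simulated trajectories are fixtures with enforced envelopes,
not biomechanical predictions.
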