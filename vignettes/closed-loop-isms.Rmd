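---
title: "Closed-loop ISMS bladder voiding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop ISMS bladder voiding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ismsloop)
```

This vignette documents the models, parameter choices and numerical
conventions behind `ismsloop`: the stimulation scheduler, the closed-loop
controller, the synthetic bladder–urethra plant, and the cystometry
metrics. It is the place where every genuinely open design choice is
recorded, together with the reasoning.

## Stimulation scheduling

Stimuli are charge-balanced, cathodic-first, symmetric biphasic
current-controlled pulses. Defaults follow common ISMS practice: 80 µs per
phase, 100 µs interphase delay, amplitudes 40–150 µA. Charge per phase is
amplitude × phase width (3.2–12 nC over that range); charge density divides
by the electrode contact area. The area of a ~3 µm conical microelectrode
tip is not well defined geometrically, so the package treats it as a config
constant, defaulting to 3.306 × 10⁻⁵ cm² — the value at which the maximum
12 nC/phase corresponds to ≈363 µC/cm², the upper end of the range usually
quoted as safe for microstimulation. Override it in
`charge_density(contact_area_cm2 =)` if your electrode differs.

Epochs are ON/OFF cycles; the two supported presets are 2 s ON / 4 s OFF
(33 % duty) and 2 s ON / 2 s OFF (50 %). Two-channel stimulation is either
synchronous (interleave 0) or asynchronous, with channel 2 delayed by 3 s
(33 %) or 2 s (50 %) so that ON windows cannot overlap. All time windows
are half-open `[on, off)`, so the boundary-touching windows of the 50 %
asynchronous preset count as disjoint; this half-open convention is used
everywhere in the package. Pulse onsets sit at regular 1/f intervals from
the window start, and a pulse is only counted if both phases and the
interphase delay complete inside the window — with 80 µs/100 µs pulses this
yields the expected 40 pulses at 20 Hz and 60 at 30 Hz in a 2-s window.

## The closed-loop controller

A trial fills the bladder to `fill_fraction` (0.9) of the distension
threshold volume V_th at 20 mL/h, rests 2 s, then iterates epochs. After
each epoch the residual volume is read at the end of the OFF period —
post-stimulus voiding happens during OFF, so sampling earlier would
misattribute it — and the controller updates:

* residual ≤ tolerance → terminate (`residual_zero`);
* otherwise amplitude += 10 µA until I_max = 150 µA;
* (hybrid only) amplitude exhausted → frequency += 10 Hz up to
  f_max = 30 Hz, amplitude restarts at I_th;
* amplitude and frequency both exhausted → terminate (`f_max_exhausted`).

PAM modulation has no frequency channel and holds at I_max; constant
modulation never changes either parameter. Those two modes therefore have
no exhaustion branch of their own, and a hard guard (`max_epochs`, default
200) bounds every trial.

Three open choices and how they were settled:

* **Zero-residual tolerance.** Exact zero is unreachable in any noisy or
  asymptotic system, so "residual reaches zero" means residual ≤ 1 % of
  the pre-first-epoch volume. This keeps VE ≥ 99 % at a `residual_zero`
  termination.
* **Behaviour at f_max.** Whether the loop should stimulate *at* f_max or
  stop upon reaching it is ambiguous in a flowchart that both increments
  the frequency and tests it. The default runs one full amplitude ramp at
  f_max before giving up — terminating immediately would make f_max
  stimulation unreachable, which would defeat raising the frequency in the
  first place. `terminate_at_f_max = TRUE` selects the other reading.
* **I_th.** The initial amplitude for the raised frequency is a free
  constant; the default re-uses I_start (40 µA) and is config-overridable.

With the defaults the hybrid controller can run at most
`n_max_epochs()` = 12 + 12 = 24 epochs (144 s of stimulation at 33 %
duty), which the never-voiding plant preset realises exactly.

**I_start calibration.** The amplitude ramp protocol (10 µA start, +10 µA
per epoch) selects the lowest amplitude whose voided-volume change from the
previous step is "significant". With a deterministic plant the replicate
standard deviation can be exactly zero, so significance is a surrogate:
the mean increment across R = 5 replicates must exceed
max(2 × replicate sd, 2 % of the fill volume). The multiplier, replicate
count and floor are arguments; the floor decides in the noise-free limit.

## The synthetic plant

The plant is the part with no published ground truth: it exists so the
loop closes, and it is deliberately the *minimal* structure that supports
the qualitative findings the controller is designed around. States:
bladder volume V (mL), detrusor activation a ∈ [0, 1], fast sphincter tone
s, a slow sphincter "after-contraction" c, fatigue F, and a transient
distension drive. Per 20-ms step (explicit Euler, matching the control
update period):

* **Drive.** Each channel contributes amplitude recruitment (rectified
  sigmoid, midpoint 80 µA, slope 22 µA, plus a small linear term
  0.0035/µA so recruitment keeps growing past the shoulder) times a
  log-normal-shaped frequency gain with unit mode at 30 Hz (σ = 0.55 in
  log-Hz, giving gain(20) > gain(10) and gain(40), gain(50) < 1). The S2
  ventral-horn channel excites the detrusor; the S1 dorsal-gray-commissure
  (DGC) channel contributes a fraction 0.6 of its drive to the detrusor
  and *inhibits* the sphincter (gain 0.25). Total drive passes through a
  soft saturation u/(1 + 0.3u), bounding the benefit of two simultaneous
  fields.
* **Fatigue.** F accumulates at 0.04/s per unit drive toward a cap of
  0.3 and recovers with τ = 20 s. This produces the decline of peak
  pressure after the second epoch under constant-amplitude stimulation,
  and — because recovery happens during OFF — penalises the 50 % duty
  cycle relative to 33 %.
* **Pressure.** P = basal (8 cmH₂O) + V/C (C = 0.3 mL/cmH₂O) +
  G·a·V/(V + V_half), with G = 60 cmH₂O and V_half = 0.15 mL. The last
  factor is a length–tension term: an emptying bladder generates less
  active pressure, which is what lets different protocols stall at
  different graded residual volumes instead of voiding all-or-nothing, and
  which reproduces the observation that a higher-amplitude epoch can show
  higher pressure yet void less because the volume is already low.
* **Sphincter and flow.** Fast tone s tracks 1 + 0.7·(S2 recruitment) −
  0.25·(DGC recruitment) with rise τ 0.2 s and relax τ 2.6 s; the slow
  component c (rise 1 s, relax 10 s, gain 0.35) is recruited only while
  both channels are ON simultaneously — the synchronous-mode field
  summation activating pudendal motoneurons. Flow is
  max(0, P − P_open·(s + c))/R_u with P_open = 21.5 cmH₂O and R_u =
  90 cmH₂O/(mL/s). Because s relaxes faster than the detrusor
  (τ 2.6 s vs 6 s), voiding happens in spurts ~2.5–3 s into each OFF
  period — inside a 4-s OFF window but largely beyond a 2-s one, which is
  the mechanism behind the 33 % > 50 % duty-cycle ordering.
* **Distension.** Crossing V_th (1.0 mL) fires a transient detrusor drive
  (0.8, τ 3 s). The closed-loop protocol fills to 90 % of V_th and never
  triggers it; it matters only for V_th-determination simulations.
* **Noise.** Recorded pressure carries additive Gaussian observation noise
  (sd 0.5 cmH₂O); the process itself is deterministic, so volumes and
  trajectories are bit-reproducible at a fixed seed and metric code still
  sees realistic jitter. Noise is additive, not multiplicative, because
  its scale is specified in cmH₂O.

**Calibration.** The `"rat-default"` parameter set was calibrated once so
that the demonstration protocols land in plausible bands (two-electrode
asynchronous hybrid VE within 77–100 %, single-electrode PAM near 60 %)
and every qualitative ordering holds: amplitude monotonicity of peak
pressure, the 30-Hz frequency optimum, constant-amplitude fatigue,
asynchronous > synchronous > single electrode, 33 % > 50 % duty, hybrid ≥
PAM ≥ constant. It is a demonstration calibration. Passing tests show that
the *controller and metrics* behave correctly on a plant with this
structure — they say nothing quantitative about rats. Features of real
cystometry the plant does not emulate: abdominal-pressure artefacts,
spontaneous (non-distension) detrusor contractions, inter-individual
recruitment geometry, electrode migration, and any volume sensor error
(the controller reads residual volume exactly).

**Replicate variability.** With observation-only noise, replicate trials
on one plant are identical in volume terms. The experiment runners
therefore draw a small per-replicate lognormal jitter (cv = 0.05 on
detrusor gain, urethral resistance and recruitment midpoint) emulating
inter-trial/inter-animal variability; each replicate remains deterministic
given its seed. Fixture presets (`never-voids`, `voids-at-10uA`,
`threshold-at-40uA`) are labelled synthetic test plants.

## Cystometry metrics

* The **epoch window** for peak pressure and ΔP is the ON period plus the
  following OFF period by default: voided volume demonstrably accrues
  during OFF (post-stimulus spurts), so excluding the tail would miss the
  pressure that drives it. `window = "on_only"` restricts to the ON span
  for comparison with conventions that stop at stimulus offset.
* The **baseline** is the mean pressure over the 1 s before the epoch
  onset; the first epoch uses the final second of the fill/rest phase.
  Note one consequence: at the hybrid frequency switch the amplitude drops
  from I_max to I_th while the baseline window still carries the previous
  epoch's decaying pressure, so ΔP of that epoch can legitimately be
  negative. Within a monotone amplitude ramp ΔP stays non-negative.
* **Residual percent** is referenced to the mean volume over the 1 s
  before the *first* epoch.
* Summaries report mean, sample sd (n − 1) and n; no hypothesis tests are
  computed anywhere in the package.
* External records must be on a uniform time grid;
  `resample_trial_record()` linearly interpolates non-uniform recordings
  and logs that it did so.

## Numerical conventions

Times are seconds (floats), amplitudes µA, frequencies Hz, charges nC
(µC/cm² for densities), volumes mL, pressures cmH₂O. Integration is
explicit Euler at dt = 20 ms — the control-update period; the dynamics'
shortest time constant (0.2 s) is ten steps, for which Euler is accurate
to well under the observation noise. Flow is clamped so a step never
removes more volume than the bladder holds, making mass conservation exact
to floating-point rounding. Non-finite pressure or volume aborts the
simulation with a diagnostic rather than propagating NaNs. CSV output uses
15 significant digits so write/read round trips are lossless.

## Problem sizes

Simulated trials span 150–1300 s at 20-ms resolution (7 500–65 000 steps);
protocol-comparison experiments default to 6 replicates per arm, and the
test suite uses 2–3 replicates per arm with the same seeds throughout. The
acceptance script (`scripts/acceptance.R`) runs the full set — 6 replicates
across all PAM and hybrid arms plus the ramp, pattern, sweep and
calibration protocols — in about a minute on one CPU.

## Known limitations

* The plant is phenomenological; none of its constants are fitted to
  animal data, and absolute VE values are properties of the calibration.
* PAM and constant modulation have no natural exhaustion criterion, so
  their trials run to the residual-zero tolerance or the epoch guard;
  reported stimulation times for those arms reflect the guard, not a
  physiological endpoint.
* Pulse-level electric-field effects (charge interactions between
  interleaved channels at millisecond scale) are not modelled; channel
  interaction enters only through epoch-level gating.
* The controller reads residual volume without sensor error; closing the
  loop over an estimated volume would need an observer model on top.
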