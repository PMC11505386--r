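---
title: "Modelling closed-loop sweep-gas control for ECCO2R"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling closed-loop sweep-gas control for ECCO2R}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecco2rsim)
```

## The system being simulated

Extracorporeal CO₂ removal (ECCO₂R) clears CO₂ from blood flowing through a
membrane lung. The removal rate is a strong function of the sweep-gas flow
through the lung's gas side, which makes the sweep flow a natural actuator
for feedback: measure the CO₂ partial pressure of the exhaust gas (EGCO₂ —
the only CO₂ signal available without a blood-contacting sensor), compare
it to a prescribed target (tEGCO₂), and adjust the sweep. `ecco2rsim`
models that loop together with the benchtop water circuit used to exercise
it: a 5-gallon reservoir, a pump, a *conditioning lung* that dissolves CO₂
into the circulating fluid to emulate patient metabolism, the artificial
lung (AL) under control, and the blower/exhaust hardware around it.

This vignette records the model, its assumptions, and the choices made
where the physical system's parameters are not reported.

## Plant model

### Carrier chemistry

Water follows Henry's law, `content = α·pCO2` with `α = 0.03 mmol/(L·mmHg)`
(the correct order of magnitude for CO₂ in water near 37 °C). Blood uses an
empirical power-law dissociation curve `content = k1·pCO2^k2` with defaults
`k1 = 2.2`, `k2 = 0.40` (mmol/L with pCO₂ in mmHg), a standard two-constant
summary of the dissolved + bicarbonate pool that is strictly increasing,
invertible, and carries several-fold more CO₂ than water at physiological
pressures. All three constants are configuration, not physics claims: the
source experiments specify none of them.

### Gas exchange in the AL

No transfer equations for the lung are available; the simulator adopts the
simplest model that reproduces the qualitative behaviour reported for the
device — a single-transfer-unit gas-side equilibration:

    EGCO2 = pL · (1 − exp(−β / Q_sweep))

where `pL` is the liquid pCO₂ entering the AL and `β` (L/min) lumps
membrane permeability and fibre-bundle geometry. As `Q_sweep → 0` the
exhaust equilibrates to the liquid (`EGCO2 → pL`); as sweep rises the
gas–liquid gap widens while total removal still increases (since
`Q·(1 − e^{−β/Q})` is increasing); and EGCO₂ can never exceed `pL` — the
device removes CO₂, never adds it. Exhaust CO₂ carriage is converted to a
molar removal rate by ideal-gas arithmetic at 310 K and 760 mmHg, and the
liquid leaving the AL is debited accordingly, floored at the gas-side
outlet partial pressure (a stream cannot be stripped below the gas it
equilibrates with). At water's low solubility that floor is usually the
binding constraint, so removal is liquid-limited; the realised (capped)
removal is what enters the reservoir balance, keeping mass conservation
exact. `fit_beta()` calibrates `β` to a measured `(sweep, EGCO2)` pair.

### Conditioning lung, mixing volume, reservoir

The conditioning lung closes a configurable fraction
(`efficiency_conditioning`) of the gap between the liquid pCO₂ and the
gas-side inlet pCO₂ (the mole fraction of the CO₂/air mix times ambient
pressure) per pass. A small mixing volume (`mixing_volume_l`, default
0.05 L of tubing/housings between the conditioning lung and the AL) gives
the pre-AL pCO₂ a first-order lag `τ = 60·V/Q_L` (3 s at 1 L/min): without
it a metabolic step would reach the AL as a mathematical discontinuity,
which no liquid circuit produces. The reservoir is a single well-mixed
compartment (default 18.93 L = 5 US gallons) advanced by an explicit
convective update; the circuit order is reservoir → pump → conditioning
lung → AL → reservoir.

### Calibrating the two free exchange parameters

`β` and `efficiency_conditioning` are jointly constrained only by the
reported operating envelope, so they are calibrated, not measured. The
defaults `β = 1.2 L/min`, `efficiency = 0.22` are the pair under which the
full reference protocol behaves like the characterised device:

* tEGCO₂ = 20 mmHg is reachable at *all four* metabolic steps within the
  0.25–7 L/min sweep range (the largest step needs ≈ 3.2 L/min);
* tEGCO₂ = 30 mmHg is unreachable only at the lowest step, and 40 mmHg at
  the lowest two — at those steps the command pins at the floor clamp with
  EGCO₂ below target;
* EGCO₂ stays below the liquid inlet pCO₂ everywhere.

Materially larger efficiencies (e.g. closing most of the gap per pass)
push the sweep needed at the 0.8 L/min step beyond the 7 L/min hardware
maximum and move the floor-pinning to the wrong targets, so they are
inconsistent with the reported behaviour.

## Hardware models

**Blowers.** A duty-proportional constant-pressure source into the lung's
gas-side resistance, with first-order flow dynamics (τ = 0.2 s). Defaults
(`max_pressure = 42 mmHg`, `gas_resistance = 6 mmHg/(L/min)` tall,
3 short, zero internal resistance) are set by two calibration points: the
7 L/min maximum through the tall lung and the doubling to ~14 L/min when
the gas-side resistance halves. The resistance value is additionally
chosen so that the lung inlet pressure at full flow (42 mmHg above
ambient) stays under the 50 mmHg embolism-guard limit — a physically
plausible combination under which the guard trips only on genuine
overpressure. The true pressure–flow curve of the blowers is not reported;
two observed flow points cannot separate source pressure from resistance,
so only their ratio is meaningful.

**Flow sensor.** White Gaussian noise, raw SD 0.25 L/min, sampled at
100 Hz; a 10 s moving average then has SD `0.25/√1000 ≈ 0.0079 L/min`,
matching the amortised-accuracy arithmetic. The sample rate itself is
unstated; 100 Hz makes a 10 s window hold exactly 1000 samples.

**CO₂ sensor.** The exhaust CO₂ is read as a molar fraction and
renormalised by the sensing-chamber pressure. The default error model is a
multiplicative gain error (up to ±5%), a small offset (±0.2 mmHg) and
Gaussian noise (SD 0.3 mmHg); with defaults the gain/offset errors are off
and only noise remains. A one-point calibration at 20 mmHg corrects a pure
gain exactly (and keeps the residual under 1 mmHg up to 50 mmHg under the
worst-case default error model); a two-point helper removes gain and
offset together. The measurement is delayed by a plug-flow buffer through
the gas-path dead volume (0.05 L, i.e. 12 s at the 0.25 L/min floor and
1.5 s at 2 L/min) plus a fixed 1 s side-stream sampling latency, and
updates at 1 Hz.

## Controller

The outer loop is a velocity-form PI update at 1 Hz:

    u_k = clamp(u_{k−1} + kp·(e_k − e_{k−1}) + ki·T·e_k,  0.25, 7)

with `e = EGCO2_measured − tEGCO2`. Applying the increment to the
already-clamped previous command makes saturation self-limiting (no
integral windup), which is exactly the behaviour wanted at the floor: with
an unachievable target the command sits at 250 mL/min and recovers
instantly when the error changes sign. The device's controller is described as PI (in one
place PID); the derivative term exists only as a
configuration stub and is not used.

The gains are not reported for the device. The defaults `kp = 0.03 (L/min)/mmHg`,
`ki = 0.02 (L/min)/(mmHg·s)` are calibrated against the design
requirement — target attained within 2 min and held within ±5 mmHg — with
the settling and band margins verified across seeds by the test suite. At
materially higher `kp` the loop rings against the measurement delay and
the post-settling band exceeds ±5 mmHg; at much lower gains settling
stretches toward the 1-minute envelope.

The inner loop converts a flow command to blower duty as feedforward
(`duty = command / 7` nominal) plus a PI trim (kp = 0.02, ki = 0.05 in
duty units) on the EMA-filtered flow reading (τ = 0.8 s). The trim
integrates only while the flow error is inside 0.15 L/min (integrator
separation) and uses back-calculation at the duty clamps. This structure
is what meets all three reported inner-loop characteristics at once —
a 0.25 → 4 L/min step held within ±0.1 L/min in under 2 s, transient
spikes well under 0.5 L/min, and held-flow SD a few hundredths of
L/min despite the noisy raw readings; a bare PI on the filtered signal
either winds up during setpoint steps or chases the noise.

## Supervisor

The blower module treats the exhaust module's command as a *suggestion*
and watches for: a frozen suggestion (< 0.01 L/min variation over 30 s —
unless it sits exactly on a clamp, where a saturated controller is
legitimately constant), a frozen EGCO₂ (< 0.1 mmHg over 60 s),
out-of-range EGCO₂ (outside 1–100 mmHg), a patient-operated switch, and
lung inlet overpressure (> 50 mmHg above ambient, which also caps the
command at `limit / gas_resistance`). Any fault latches a fallback to the
pre-specified default fixed sweep (1 L/min) until a manual re-arm —
latching is the safer reading of an unspecified recovery policy. The
detection windows exceed the worst-case transport delay at the flow floor
(12 s) so a slow but healthy loop is never mistaken for a frozen one.
Both freeze heuristics presume measurement noise; in noise-free
configurations the supervisor should be disabled (`supervisor$enabled`),
as the test suite does for its deterministic invariants.

## Protocol and metrics conventions

`reference_scenarios()` reproduces the benchtop protocol: 4-minute
conditioning steps at 0.1/0.2/0.4/0.8 L/min CO₂ in 2 L/min air, water flow
1.0 L/min with targets 10/20/30/40 mmHg, fixed-sweep arms at 1 and
2 L/min, water flows 0.5–2.0 L/min at target 20 with the 0.8 step omitted,
and a blood run with steps 0.1/0.2/0.4. Schedules run up *and back down*
so both overshoot (after increases) and undershoot (after decreases) are
exercised; whether the physical protocol stepped monotonically or
up-and-down is not stated, and the schedule is configurable. Each run
starts with a 5-minute warm-up at the first level from a 20 mmHg reservoir
(initial condition unstated in the source; 20 mmHg is the most common
target) so start-up transients stay out of the transition metrics.

Settling time follows the benchtop definition: from EGCO₂ diverging more
than 5 mmHg from target after a change until it is back within 5 mmHg *for
3 s*. The 3 s sustain is treated as a qualification of the band entry, not
part of the duration (`include_sustain` flips this, as the wording is
ambiguous); a transition that never leaves the band scores 0, and one that
never re-settles is reported as `NA` rather than a large number. Overshoot
windows run from the change to the settling instant (or the segment end if
unsettled). Steady-state segment statistics discard the first 120 s after
each change; whole-run statistics include everything, transitions and
floor-pinned periods alike.

## Numerical choices

Fixed-step explicit integration at `dt = 0.1 s`; the test suite guards the
trajectory against a 100×-finer oracle (≤ 0.5% on the integrated fluxes,
≤ 0.1% on reservoir content over a minute) and the flux bookkeeping is
exact at the step level by construction. Traces are decimated to 1 Hz by
default (settling metrics are stable within one coarse tick against a
10 Hz decimation of the same run). The plug-flow delay line advances a
tail pointer over cumulative-volume coordinates, so it is O(1) per tick
and exact to one tick at constant sweep. All noise flows from a single
per-scenario seed; runs are bit-reproducible and the caller's RNG state is
restored. Problem sizes throughout (a ~33-minute reference run at 0.1 s
steps, 20 000 Monte-Carlo windows for the amortised flow accuracy, 1000
random traces for the settling-oracle property) were chosen to hold
estimator error near or below 1%.

## What the scenarios do and do not emulate

The generator emulates the *in vitro* characterisation circuit: step
metabolic challenges, water or blood as carrier, sensor noise and delays,
hardware limits, and injected faults (frozen/out-of-range signals, patient
switch, single-blower loss). It does not model oxygenation, humidity and
condensation in the sensor path (the water trap and heater are assumed to
work — the sensed gas is dry), liquid-side boundary layers or pressure
drop, hemolysis or thrombosis, patient physiology beyond a programmable
CO₂ source, or the electrical/battery subsystem. Passing tests therefore
demonstrate control-architecture behaviour under the modelled plant, not
clinical performance: in particular, the EGCO₂–blood pCO₂ gap at high
sweep means a constant EGCO₂ does not imply constant blood pCO₂ (the
simulator reproduces this: post-AL liquid pCO₂ rises above EGCO₂ as sweep
grows).

## Known limitations

* The two-parameter exchange calibration reproduces the reported operating
  envelope but is not unique; any (β, efficiency) pair satisfying the same
  envelope constraints is equally defensible. Both are config-exposed.
* Transition overshoot in the simulator is disturbance-dominated: the
  metabolic step reaches the AL within ~3 s, faster than the 1 Hz outer
  loop plus measurement delay can respond, so the peak excursion is nearly
  independent of `kp`. The physical device's reported overshoot reduction
  from a gentler proportional term is therefore *not* reproduced —
  `tune_gains()` exposes the knob, but on this plant it mainly trades
  settling time. The calibrated loop is also tighter than the physical
  device (settling in seconds rather than ~0.5 min), since nothing in the
  reported envelope pins the dominant lag of the real exhaust path.
* The blower model is a constant-pressure source; real centrifugal
  pressure–flow curves droop with flow, so duty-to-flow linearity is an
  approximation between the two calibrated endpoints.
* With `internal_resistance = 0` (default), losing one blower does not
  reduce the achievable flow — redundancy is free in the model unless an
  internal resistance is configured, where it is shared across active
  blowers.
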