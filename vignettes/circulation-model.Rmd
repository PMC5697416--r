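---
title: "A closed-loop lumped-parameter model of the left heart and systemic circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop lumped-parameter model of the left heart and systemic circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cardiolpm)
```

## The model and its assumptions

`cardiolpm` implements a zero-dimensional circulation model built on the
hydraulic–electrical analogy: pressures are voltages, flows are currents,
vascular beds are resistors and capacitors, heart chambers are time-varying
capacitors (elastances), and heart valves are diodes. Four compartments
close the loop:

| compartment | pressure law | state |
|---|---|---|
| left atrium | `P_la = E_la(t) (V_la − V0_la)` | `V_la` |
| left ventricle | `P_lv = E_lv(t) (V_lv − V0_lv)` | `V_lv` |
| arteries | `P_art = (V_art − V0_art) / C_art` | `V_art` |
| veins | `P_ven = (V_ven − V0_ven) / C_ven` | `V_ven` |

with flows `Q_mi = max(P_la − P_lv, 0)/R_mi` (mitral),
`Q_ao = max(P_lv − P_art, 0)/R_ao` (aortic),
`Q_sys = (P_art − P_ven)/R_sys` and `Q_ven = (P_ven − P_la)/R_ven`, and
volume balances `dV/dt = Q_in − Q_out` per compartment. The four
derivatives sum to zero identically, so total blood volume is a conserved
quantity of the continuous system — the property the test-suite uses as its
integration oracle.

Assumptions worth stating plainly: a single (left) heart with the
right heart and pulmonary circulation lumped into the venous node; linear
elastance and compliance laws; no inertance (no flow momentum, hence no
dicrotic features); no baroreflex or any other control loop; strictly
periodic forcing. Within those assumptions the model is the minimal
circuit in which contractility, resistance, compliance, volume and heart
rate all have mechanistically distinct effects.

### Activation waveforms

The ventricular activation is a piecewise cosine:
`e(t) = (1 − cos(π t / (f_peak T)))/2` on `[0, f_peak T)`,
`(1 + cos(π (t − f_peak T)/((f_end − f_peak) T)))/2` on
`[f_peak T, f_end T)`, and 0 until the cycle ends. It is continuous,
C¹ except at the peak, and keeps the ODE system friendly to an adaptive
stiff solver. The atrial beat is a single raised-cosine hump placed in late
diastole (`f_atrial_onset = 0.85` to `f_atrial_end = 1.0` of the cycle by
default); the implementation permits the hump to wrap across the cycle
boundary.

### The venous compartment

A bare arterial Windkessel returning directly to the atrium would leave
total blood volume with no mechanistic role: you could not bleed the model.
The venous reservoir is the minimal extension that makes `V_total` a
meaningful input — volume removed from the loop lowers venous (filling)
pressure, preload, and ultimately cardiac output. Because the loop has no
right heart, the venous node is best read as the pulmonary-venous/left-atrial
filling pressure, which is why its calibrated operating point (~17 mmHg)
sits above systemic central-venous values.

## Parameters

Five inputs define a preset (units mmHg, ml, s):

| symbol | meaning | normal value |
|---|---|---|
| `E_lv_max` | peak LV elastance (contractility) | 2.5 |
| `R_sys` | systemic vascular resistance | 0.994 |
| `C_art` | total arterial compliance | 1.75 |
| `V_total` | circulating blood volume | 5700 |
| `T` | cycle period (60/HR) | 1 |

Two registry notes. First, the published normal-row resistance prints as
0.094, which is inconsistent with every disease row (0.99–1.61) and would
put mean arterial pressure near 8 mmHg at 5 l/min; the registry stores
0.994 — matching the haemorrhage Stage I row — with a provenance note on the
preset. Second, the resistance unit prints elsewhere as mmHg·s/min; the
values are only dimensionally consistent with mmHg·s/ml, which is what the
package uses throughout.

The remaining constants (diastolic elastances, atrial elastance bounds,
valve and venous resistances, venous compliance, unstressed volumes,
activation timings) are shipped in `inst/extdata/constants.conf` and are
shared, unchanged, by every preset.

## Baseline calibration

The fixed constants are not published anywhere; they were recovered once by
`calibrateBaseline()` and frozen. The procedure:

* **Anchor**: only the normal preset, with targets SBP 120 mmHg, DBP
  80 mmHg, CO 5 l/min at HR 60.
* **Objective**: equal-weight sum of squared relative errors over the three
  targets, minimised by bounded Nelder–Mead (deterministic: same start,
  same answer).
* **Free constants**: `E_lv_min`, `E_la_min`, `E_la_max`, `C_ven`, `R_ven`,
  `V0_ven`, `f_peak`, `f_end`, started from round physiological defaults
  (`E_lv_min` 0.08, `E_la` 0.15/0.25, `C_ven` 270, `R_ven` 0.05, `V0_ven`
  1800, `f_peak` 0.30, `f_end` 0.45).
* **Bounds**: physiological ranges, with one structural constraint —
  `V0_ven ≤ 2100` ml so that every preset, including the 2850 ml
  haemorrhage Stage IV row, retains positive stressed volume. The venous
  compliance start was set so the normal venous node sits near 10 mmHg
  given that bound.
* **Freeze**: the optimum (objective ~1e-13) was written to
  `constants.conf`. Every disease preset thereafter is a pure input
  override; no constant is ever re-tuned per preset.

Calibration is anchored to the normal row only, deliberately: per-row
re-tuning would turn the disease presets into curve fits and destroy their
value as predictions. The acceptance tests therefore read as a genuine
out-of-sample check of the circuit, and their misses (below) are informative
rather than embarrassing.

## Simulation protocol

`runToSteadyState()` starts from a deterministic warm start — stressed
volume `V_total − ΣV0` split across compartments in proportion to their
diastolic compliances, so every node begins at a common pressure — and
integrates cycle by cycle (lsoda, `rtol = atol = 1e-8`). After each cycle
it compares stroke volume *and* cycle-mean arterial pressure with the
previous cycle; when both change by less than `ss_rel_tol` (default 1e-3)
the run is converged and the final cycle is re-sampled at `dt_output`
(default 1 ms). Stroke volume alone can settle several cycles before the
pressures do, which is why both are required. If `max_cycles` (default 50)
is reached the result is returned flagged `converged = FALSE` rather than
thrown, so batch runs can report rather than crash.

All presets converge in 12–30 cycles from the warm start; the recorded
relative volume drift is at machine precision (~1e-14), comfortably inside
the 1e-5 conservation bound the tests enforce. Halving the solver
tolerances moves SBP, DBP and CO by well under 0.5%.

Metric conventions: SBP/DBP are the extrema of `P_art` over the final
cycle, MAP its trapezoidal time average, EDV/ESV the extrema of `V_lv`,
`SV = EDV − ESV`, `CO = SV·(60/T)/1000` with the unrounded rate, and HR is
reported rounded to the nearest beat. PV-loop area (stroke work) uses the
shoelace formula on the closed `(V_lv, P_lv)` trajectory, oriented so that
ejection at high pressure gives positive work.

## Staging conventions

Three classifiers map outputs to guideline bands, with deliberate boundary
closures where printed bands leave gaps:

* **Hypertension** (from SBP and DBP, the *higher* of the two implied
  stages wins — a 140/80 reading is Stage 1 on the systolic criterion
  alone): normal < 140/90; Stage 1 from 140 or 90; Stage 2 from 160 or
  100; Accelerated from 180 or 120. The printed "140–159" then ">160"
  leaves 159–160 unassigned; it is closed at 160, the usual guideline
  convention.
* **Heart failure** (from LVEF): Severe < 30% < Moderate < 40% < Mild
  < 50% < normal.
* **Haemorrhage** (from fractional volume loss, analytic — the preset's
  `V_total` against the normal 5700 ml): I < 15% ≤ II < 30% ≤ III ≤ 40% <
  IV. The published classes jump from "30–40%" to "50%"; Stage IV is
  closed as > 40% so the range has no hole.

`stagePreset()` dispatches on the preset's disease category; for heart
failure the grade is computed from the *simulated* ejection fraction, not
asserted from the registry.

## What the predictions do and do not reproduce

With all constants frozen at the normal anchor, the eleven presets
reproduce the qualitative physiology across the board — every response
direction (resistance→pressure, volume→output, contractility→stroke
volume, the heart-rate column exactly) and the pressure ordering of every
disease ladder. Quantitatively, the hypertension systolic pressures land
within a few percent of the published table; the stage recovery check
returns Stage 1 for the Stage 1 preset, while the Stage 2 preset simulates
158.6/99.96 mmHg — a band short of its own label by 0.04 mmHg of diastolic
pressure — and the accelerated preset classifies as Stage 2. Two structural
facts cap what any parameterisation of this circuit could do there:

* In a pure RC arterial bed, pulse pressure cannot exceed `SV/C_art` (the
  artery gains at most one stroke volume during ejection). The published
  accelerated row (180/100 at CO 5 l/min, so PP 80 against
  `SV/C_art ≈ 71.5`) is beyond that bound for *any* elastance/Windkessel
  model with these inputs.
* `CO × R_sys` for the accelerated row is ≈134 mmHg, above that row's
  implied MAP (~127) even with zero downstream pressure, so its published
  pressure and output are jointly unreachable.

The heart-failure and haemorrhage rows expose the model's missing control
loops rather than its circuit: without a baroreflex, falling contractility
is buffered by the venous preload reserve (simulated CO falls less than
published), and haemorrhage beyond ~15% loss collapses filling pressure
faster than the published table, which embeds the compensated physiology of
a real patient (venoconstriction recruiting unstressed volume). The
comparison table printed by the acceptance tests reports every entry's
deviation openly; treat the reflex-dependent rows as illustrating the
*uncompensated* circulation.

The heart-failure grade agreement via simulated LVEF is reported rather
than asserted: the model's normal ejection fraction (~0.59) sits lower than
a healthy human's (~0.65) because the linear diastolic elastance fixes the
EDV–filling-pressure relation globally, so the mild preset's simulated EF
(0.53) stays above the 50% band.

## Numerical and degenerate-input choices

* Valve diodes use a small open resistance (0.01 mmHg·s/ml) instead of an
  ideal switch; the kink in `max(ΔP, 0)` is handled by lsoda without event
  detection.
* `activation()` rejects times outside `[0, T)`; the integrator-facing core
  wraps time modulo `T` instead.
* Transient `V < V0` (negative chamber pressure) is permitted — it occurs
  benignly in deep haemorrhage — but non-finite states abort with the
  offending compartment named.
* `extractMetrics()` refuses series that do not cover exactly one cycle;
  `pvLoop()` drops a duplicated endpoint before closing the polygon so the
  shoelace area is not biased by a zero-length edge.
* A zero baseline in `compareToBaseline()` flags the row `NA` rather than
  failing the whole table.

## Problem sizes

The shipped defaults — 1 ms output sampling (≈1000 samples per cycle),
201-point convergence sampling, 1e-8 integrator tolerances — were chosen so
a single preset runs to steady state in a couple of seconds and the full
eleven-preset battery, ladders and calibration fixed-point checks complete
in about a minute; they sit two orders of magnitude inside the refinement
band where halving tolerances changes nothing reportable.

## Known limitations

Single-sided heart; no pulmonary loop, no inertance, no reflex control, no
beat-to-beat variability; linear EDPVR; the haemorrhage and advanced
heart-failure rows consequently describe uncompensated physiology. The
calibrated constants are one point on a three-constraint manifold — other
fixed-constant sets reproduce the same normal baseline with somewhat
different disease predictions; ours is pinned by the documented starts,
bounds and procedure, not hand-picked per row.
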