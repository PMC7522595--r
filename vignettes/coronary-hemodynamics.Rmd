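---
title: "Methods: coronary and LV hemodynamics under microaxial pump support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coronary and LV hemodynamics under microaxial pump support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corohemo)
```

## Scope

`corohemo` implements the measurement chain used when a dissected coronary
artery is studied under two levels of transaortic microaxial pump support:
no support (P0) and maximal flow (P8). Four measurement blocks —
waveform conditioning, conductance-catheter pressure–volume (PV) analysis,
an angiographic delay-time statistic, and paired condition statistics — are
paired with a lumped-parameter simulator that generates the same kind of
multichannel recordings with known ground truth. The simulator is
first-class, tested code: it is how every pipeline stage is validated at
desk scale, since raw animal recordings of this type are not publicly
deposited.

## Waveform conditioning

Signals arrive at 1 kHz. The pipeline is:

1. **Down-sample to 200 Hz** (`downsample()`). The decimator applies a
   Hamming-window FIR low-pass with cutoff at 80% of the output Nyquist
   frequency before taking every fifth sample. The coefficients are
   renormalized to sum exactly to one, so constant levels (and the mean of
   any trace) pass unchanged; edges are padded by sample replication and the
   symmetric filter introduces no phase shift. Naive striding is refused —
   out-of-band noise at 1 kHz would alias into the cardiac band.
2. **Savitzky–Golay smoothing** (`sg_smooth()`, window 11 samples = 55 ms at
   200 Hz, polynomial order 3). Each output sample is the centre value of a
   least-squares cubic fitted in the sliding window; the first and last five
   samples take the first/last full window's fit evaluated off-centre. An
   order-3 filter passes any locally cubic waveform unchanged, which is why
   the test suite checks exact reproduction of cubics and per-point
   agreement with a brute-force sliding least-squares oracle.
3. **Cycle detection** (`detect_cycles()`). Cardiac cycles are delimited by
   local minima of a (smoothed) pressure trace. Two guards that the
   minimum-of-pressure rule needs in practice are exposed as parameters:
   a refractory period `min_period_s` (default 0.3 s, a 200 beats/min
   ceiling) and a topographic prominence floor `prominence_frac` (default
   0.2 of the trace's total range) so dicrotic notches and noise wiggles do
   not split beats. When two candidate minima fall within the refractory
   distance the deeper one wins. A cycle spans `[boundary_i,
   boundary_{i+1})`; half-open indexing avoids double-counting, and the
   trailing partial cycle is discarded.
4. **Ensemble averaging** (`ensemble_average()`, n = 10). Ten consecutive
   cycles are linearly resampled to the median cycle length and averaged
   pointwise; iid beat noise shrinks by about √10. Which ten is an analysis
   choice: the `offset` argument selects the starting beat (simulated
   recordings are analysed with `offset = 5` to skip the integrator's
   startup transient). Whether averaging acts on smoothed or raw beats is
   ambiguous in common practice; the default here smooths first, and
   `beat_summary(smooth = FALSE)` averages raw beats instead.
5. **Beat statistics** (`beat_stats()`): maximum, minimum, arithmetic mean
   of the averaged beat.

## PV analysis and conductance calibration

The conductance channel is volume-proportional but uncalibrated. Two
reference scalars fix it:

* gain: `alpha = CO_ref / CO_raw`, with `CO_ref` from thermodilution
  (Stewart–Hamilton, `thermodilution_co()`: trapezoid integral of the
  thermistor washout curve; the computation constant defaults to 1 and is a
  parameter, since device constants vary) and `CO_raw` = uncalibrated stroke
  volume × heart rate from the raw channel;
* offset: `V_parallel = EDV_scaled − EDV_echo`, matching the α-scaled
  end-diastolic volume to 3D-echo EDV.

Scaling is applied before the offset (`V = alpha · V_raw − V_parallel`), so
that α matches cardiac output — a scale-only quantity — independently of the
offset. `CO_raw` is estimated from the ensemble-averaged raw beat
(`raw_volume_metrics()`), whose extrema are read after a mild circular
re-smoothing: the volume extremes sit on the isovolumic plateaus, and the
extremum of a noisy trace is biased upward, which would propagate a
systematic error into α and — amplified by the ~150 ml scaled-EDV lever
arm — into `V_parallel`. On noiseless input generated by the exact inverse
map the calibration recovers the planted gain and offset to numerical
precision, because every conditioning step is linear. With realistic channel
noise the gain is recovered to within 2%; the offset is judged on the
volume-axis scale (a percentage of EDV), the natural scale for an additive
volume offset.

Per-cycle metrics (`pv_metrics()`): end-diastole is the sample of maximal
volume and end-systole the sample of minimal volume within a cycle — robust
landmarks when no ECG channel is recorded, though on strongly assisted
beats, where the pump keeps draining the ventricle after aortic valve
closure, the minimum-volume sample migrates into diastole and the "ESP"
read there is low. Stroke work is the unsigned shoelace area of the closed
P–V polygon (closed by joining last to first point; the area is invariant
to the starting index and to orientation). Loops with fewer than 8 points
are rejected as degenerate. Reported values are means over the ten analysis
beats, and `sv = edv − esv` and `co = sv·hr/1000` hold exactly by
construction.

## Angiographic delay time

`DT = (LAD first-fill frame − LCX first-fill frame) / frame rate` at
30 frames/s. "Filling time" is operationalized as the first-fill frame —
the frame-reading criterion is not standardized, so when per-frame
opacification intensity traces are available,
`fill_frame_from_intensity()` uses a configurable threshold crossing
(default 50% of the plateau, the plateau being the mean of the last 10% of
frames). DT is negative when the LAD fills first and invariant to a common
frame offset. No TIMI grade is derived from DT; a visually assigned grade
can travel as metadata.

## Paired statistics

`compare_conditions()` emits, per metric, mean ± SD per condition (sample
SD, n−1 denominator) and a two-sided paired Student's t-test
(`t = mean(d)/(sd(d)/√n)`, df = n−1). Zero-variance differences are flagged
degenerate rather than erroring (p = 1 for identical pairs, p = 0 as the
limiting bound for a constant nonzero shift). No multiple-testing
correction is applied — each metric is tested marginally, matching how such
tables are conventionally reported. Tests check the implementation against
an independent numerical integration of the t density and verify the
empirical type-I error at n = 6.

## The simulator

`simulate_hemo()` integrates, with fixed-step fourth-order Runge–Kutta at
the acquisition rate (1 kHz), a minimal closed-loop model:

* **LV**: time-varying elastance `P_lv = E(t)(V_lv − V0)` with
  `E(t) = e_min + (e_max − e_min)·a(t)`; `a(t)` is a two-cosine activation
  (rising half-cosine over 30% of the cycle, falling over 15%).
* **Valves**: diode resistances; mitral inflow from a constant atrial
  pressure, aortic outflow into the Windkessel.
* **Systemic circulation**: two-element Windkessel
  (`c_aorta`, `r_systemic`, venous pressure).
* **Pump**: `Q_pump = max(0, Q_nom − k_p (P_ao − P_lv))` — a linear,
  head-pressure-clipped pump curve; `Q_nom` is 0 at P0 and `q_nominal_p8`
  at P8.
* **Dissected coronary branch**: the false lumen relaxes toward aortic
  pressure with time constant `tau_false`; the true-lumen inlet resistance
  inflates with the false-over-true pressure excess,
  `R_true = r_base (1 + γ · max(0, P_false − P_true)/10 mmHg)` (the 10 mmHg
  is a documented normalization scale); microvascular resistance
  interpolates between its diastolic and systolic values with `a(t)`
  (systolic compression); flow and distal pressure follow from the
  resistive divider, and velocity is flow divided by the vessel
  cross-section. `P_true` is an algebraic constraint solved by damped
  fixed-point iteration at every derivative evaluation.

The conductance channel is emitted as the exact inverse of the calibration
map, `(V_lv + v_parallel_true)/alpha_true`, and seeded Gaussian noise is
added per channel class (pressures 1.5 mmHg, velocity 2 cm/s, conductance
0.8 raw units). Ground truth — per-beat PV metrics, coronary beat
statistics, pump flow — is computed from the noiseless trajectory over
steady-state beats 6–15, never from the noisy channels.

### Default parameters and what they emulate

Defaults describe a ~50 kg pig after creation of a proximal LAD dissection:
heart rate 72 beats/min, `e_max` 2.2 and `e_min` 0.15 mmHg/ml, `V0` 10 ml,
atrial pressure 26 mmHg, mitral resistance 0.1 mmHg·s/ml, aortic valve
0.015, systemic resistance 1.15 mmHg·s/ml, aortic compliance 1.3 ml/mmHg,
coronary inlet 4 and microvascular 35 (diastole) / 110 (systole) mmHg·s/ml,
vessel area 0.035 cm², `alpha_true` 1.25, `v_parallel_true` 30 ml,
record length 20 s. At no support this settles near EDV 126 ml, SV 65 ml,
ESP 111 mmHg and mean aortic pressure ~92 mmHg. Three choices deserve
comment:

* **Flow-limited filling.** The atrium is a pressure source, so preload
  sensitivity must come from the mitral resistance; with the default
  0.1 mmHg·s/ml diastolic filling does not saturate within one diastole,
  and continuous pump drainage therefore lowers EDV, EDP, SV and stroke
  work at P8 — LV unloading is emergent, not prescribed. (Heart-rate
  slowing under support is *not* emergent; `make_paired_cohort()` applies a
  per-condition heart-rate ratio, default 0.91.)
* **Pump operating point.** `q_nominal_p8 = 3.34 L/min` was calibrated once
  so that the default P8 configuration delivers a time-averaged pump flow
  of 2.7 L/min over beats 6–15, and is shipped frozen.
* **Slow false-lumen equilibration** (`tau_false` 1.5 s). The false lumen
  then sits near *mean* aortic pressure while the true lumen remains
  pulsatile. With a large flap (`flap_gamma` ~50) true-lumen inflow is only
  unobstructed while instantaneous true-lumen pressure exceeds the
  false-lumen level; maximal support raises mean aortic pressure and
  reduces pulsatility, shrinking that window, so mean distal pressure
  *falls* while the false lumen is pressurized. With `flap_gamma = 0` the
  same support raises distal pressure along with aortic pressure. This is
  the mechanism contrast the simulator exists to reproduce, and it is
  asserted directionally in the tests. With the flap resistance alone
  (fast false-lumen equilibration) the cycle-averaged distal pressure
  saturates and the contrast would be numerically marginal.

The simulator emulates directions and plausible magnitudes, not porcine
physiology in quantitative detail: there is no coronary autoregulation, no
ischemic mechanics, no right heart, no baroreflex, and noise is additive
Gaussian without baseline wander (an optional drift is deliberately absent
because Savitzky–Golay smoothing is the pipeline's only denoising step).
Passing tests therefore certify the *pipeline's* correctness and the
model's directional fidelity — they do not certify magnitudes on real
animals.

## Numerical choices

* Fixed-step RK4 at 1/fs keeps trajectories bit-reproducible (asserted:
  identical configuration including seed gives identical recordings);
  instability is caught by a non-finite guard naming the step rather than
  by adaptive stepping.
* The flap fixed-point iteration is damped 50/50 and iterated to 1e-10 (cap
  30 iterations); it is contractive throughout the parameter ranges used.
* Cycles of unequal length are linearly resampled to the median length
  before averaging — the simplest defensible alignment when beats differ by
  a few samples.
* Ties at flat volume plateaus resolve to the first extremal sample
  (`which.max`/`which.min` semantics).
* RNG state is saved and restored around every seeded simulation, so
  package calls never disturb the caller's stream; cohort subject seeds are
  drawn from the master seed, keeping cohorts reproducible as a unit.
* Validation problem sizes: 20 s records (≈24 beats) per condition,
  6-subject paired cohorts, 100 cohort replicates for the directional
  power check, 200 replicates for the ensemble noise-reduction check, and
  2000 null replicates for the t-test level check.

## Known limitations

* Baseline-table volumes in the source literature for this preparation are
  not used as numeric fixtures anywhere (one published baseline table
  transposes ESV/EDV against the stated ejection fraction); calibration
  references are always explicit function arguments.
* The ED/ES landmarks are volume extrema; with heavy assistance the ES
  landmark drifts into diastole (see above), so ESP under P8 should be
  interpreted with care. EDP read at the maximum-volume sample inherits
  plateau ambiguity under noise.
* DT requires both vessels annotated; there is no imputation.
* The waveform dialect is a repository convention (plain text, `#` headers);
  vendor acquisition formats are out of scope.
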