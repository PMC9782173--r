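---
title: "Models and methods behind smartinsole"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smartinsole}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartinsole)
```

`smartinsole` packages the full measurement-and-analysis chain of a
capacitive plantar-pressure insole: a physics-based stand-in for the hardware
(one sensor plus the dynamic loading rig, and a 16-sensor insole worn during
gait), the bench characterization metrics, and the gait analysis pipeline.
No recordings from the original device are available, so the simulators are
first-class, tested components whose defaults encode the device's published
operating conditions; every analysis routine also accepts externally recorded
traces through a documented CSV dialect.

## The sensor model

A sensor is a parallel-plate capacitor with a two-layer dielectric (a 1.0 mm
air cavity over a 0.2 mm flexible printed polymer) on a 14.5 mm circular
face. Its static capacitance is the series formula

$$C = \frac{\epsilon_0 A}{d_1/k_1 + d_2/k_2},$$

about 1.40 pF for the default stack. The relative permittivity of the
flexible layer is not published; the default `k2 = 4.2` is typical of
thermoplastic polyurethane and is exposed as a configuration field. The
absolute baseline never enters the analysis chain — all characterization
works on the relative change $\Delta C / C_0$.

**Transduction.** The forward model is linear in pressure with slope $S_c$
(the sensitivity, in MPa^-1): $\Delta C/C_0 = S_c P$. Two calibrated profiles
are shipped: `out-of-insole` ($S_c = 1.19$ MPa^-1, the bench value) and
`in-insole` ($S_c = 0.55$ MPa^-1, the ~2.1-fold attenuation measured after
mounting inside the printed insole). The mechanical gap-compression chain of
the series-capacitance formula is deliberately *not* used as the forward
model — only slope and linearity were characterized for the device — so the
formula is provided as a standalone calculator.

**Hysteresis.** The unloading branch lies slightly above the loading branch.
We model the gap with the simplest closed loop that (a) vanishes at both the
origin and the turning point and (b) has an analytic loop area: a quadratic
bump

$$\delta(P) = \alpha\, P\, (P_{max} - P).$$

The degree of hysteresis (trapezoidal area difference of the two branches,
as a percentage of the loading area) is then exactly
$DH = 100\,\alpha P_{max} / (3 S_c)$, which doubles as an independent oracle
for the numerical integrator. The default
$\alpha = 3 S_c \cdot 0.098 / P_{max} = 0.4010$ MPa^-2 calibrates the bench
profile to the measured $DH = 9.8\%$. No separate in-insole hysteresis was
published; the in-insole default keeps $DH = 9.8\%$ by scaling $\alpha$ with
the profile's $S_c$. An unloading-above-loading loop is unusual for
capacitive sensors, but it is what the device showed and is implemented as
reported, not "corrected".

**Dynamics.** Response and recovery are an asymmetric first-order lag
$\dot y = (x - y)/\tau$, with $\tau_{rise} = 142/\ln 9 = 64.63$ ms and
$\tau_{fall} = 160/\ln 9 = 72.82$ ms, so that the standard 10–90% /
90–10% estimators recover the measured 142 ms response and 160 ms recovery
($t_{10-90} = \tau \ln 9$ for a first-order step). The discrete update is the
exact zero-order-hold solution, so the filter is unconditionally stable and
settles to the input.

**Noise.** Additive Gaussian noise on the relative capacitance, default
SD 0.01. Every stochastic entry point requires an explicit seed and restores
the caller's RNG state.

## The rig simulator

The loading rig presses a piston of the sensor's own face area with
dead-weights from 0.7 kg (bare shaft) to 14.7 kg. The conversion
$P = mg/(\pi r^2)$ uses $g = 9.8$ m/s² — the value that reproduces *both*
printed endpoints (41.5 and 872.4 kPa) exactly; $g = 9.81$ does not.
Protocols:

* **staircase** — fifteen one-minute levels, 0.7–14.7 kg in 1.0 kg steps
  (59.35 kPa increments), 40 steps/min;
* **periodic** — constant-pressure square wave for cadence sweeps
  (30–70 steps/min, the supported gait-speed range; outside it a warning is
  issued) and durability runs;
* **ramp cycles** — symmetric triangular ramps for quasi-static hysteresis
  measurement, default three cycles.

The loading waveform is not published beyond "pulse-like"; we use a 50%
duty-cycle square wave (low quarter, high half, low quarter per period, so
traces start and end unloaded) smoothed by the dynamics stage. Rig
simulations sample at 1 kHz to give millisecond timing resolution; the
original acquisition rate was user-configurable and unpublished. The
durability run is parameterized because the published "1 h … 2.280 cycles"
(read as the thousands separator, 2,280) conflicts with its 40 steps/min
caption (2,400 cycles/h); the acceptance suite uses 2,280 cycles at
38 steps/min, which is exactly one hour.

## The gait simulator

Sixteen sensors in four anatomical zones — phalanges (T1–T4), metatarsals
(ME1–ME5), plantar arch (M1–M4), calcaneus (H1–H3) — on a 250 mm × 85 mm
(EU 39) insole. The published layout gives zones only, so the shipped
coordinate table (`extdata/layout.json`) is a synthetic stand-in placing each
sensor anatomically: heel sensors in the posterior quarter, phalanges in the
anterior fifth. All center-of-pressure results are defined relative to this
frozen table.

Each sensor produces one raised-cosine bump per gait cycle. Default cycle
1.5 s (40 steps/min), stance fraction 0.62, phase onsets (cycle fractions)
heel strike 0, foot flat 0.10, midstance 0.25, heel off 0.45, toe off 0.55,
swing 0.62. Zone windows are *solved*, not hand-tuned: given a zone's mean
peak and the 45 kPa activation threshold, the bump window is chosen so the
zone-mean pressure crosses the threshold exactly at the zone's ground-truth
activation boundaries (calcaneus active heel strike→foot flat, metatarsals
foot flat→heel off, arch foot flat→midstance, phalanges heel off→toe off).
This makes the rule-based segmentation recover the ground-truth boundaries
to within about one frame at 100 Hz by construction — which is precisely what
a green segmentation test establishes, and no more.

Default peaks encode the recorded subject: H1 = 295, T1 = 370, ME5 = 380,
T4 = 127 kPa; T2 = T3 = 0 (the middle toes bore no load); arch sensors
90–120 kPa (below the 150 kPa bound reported for the arch). The remaining
sensors (H2/H3, ME1–ME4) were not given numerically and default to
anatomically plausible values between their zone-mates. Two deliberate
consequences of the symmetric-bump construction: swing frames near the
toe-off and heel-strike transitions are *below threshold* rather than
exactly zero (the raised-cosine tails extend slightly past the stance
window), and the phalange peak falls inside heel off rather than exactly at
the midstance/heel-off transition. Neither affects the segmentation or the
reported peaks.

What the generator does **not** emulate: biomechanical coupling between
zones, left/right asymmetry, stride-to-stride variability, load-dependent
drift, or any subject anthropometry beyond the peak table. A green
pipeline test therefore establishes correct *recovery of the stated
waveform family*, not validity on real gait.

## Characterization estimators

* **Cycle amplitudes / sensitivity.** Per level, the mean over cycles of
  (cycle peak − cycle baseline)/C0, with the baseline the local pre-cycle
  minimum — robust to slow drift — and the first cycle of each level
  discarded as transient. Sensitivity is the OLS slope of amplitude versus
  pressure in MPa; R² is the ordinary unweighted coefficient of
  determination (no weighting was published).
* **Degree of hysteresis.** Trapezoidal integration of both branches on the
  common grid; checked against the closed form above to 0.1 percentage
  points.
* **Response/recovery.** First 10%→90% rising interval and 90%→10% falling
  interval with linear interpolation between samples, averaged over all
  qualifying edges (whether the published numbers came from one edge or an
  average is unstated). Thresholds are relative to the trace's own range, so
  the estimator is scale-invariant.
* **Frequency invariance.** Steady-cycle amplitude per cadence; reported as
  the maximum relative deviation from the cadence mean. Below 1% for the
  default time constants over 30–70 steps/min; a 10× slower recovery is
  detected as > 5% at high cadence.
* **Durability drift.** Mean cycle baseline (C0) and peak (Cf) compared
  between the first and last window of a long run. The drift-free model
  reproduces the reported stability; a fabricated 5% linear drift is
  detected at its injected size.

The printed "1.19 ± 0.03 MPa^-1" is the average of sixteen physical sensors.
Measurement noise alone (SD 0.01 on relative capacitance, amplitudes
averaged over ~40 cycles) yields per-fit standard errors near 0.001, two
orders too small — the ±0.03 must be *between-sensor* variability. The
acceptance suite therefore draws sixteen per-sensor sensitivities from
N(1.19, 0.12²) (SD chosen once so the standard error of the 16-sensor mean
is 0.03) and checks that the mean fitted slope lands within 3 SE of truth
with SE ≈ 0.03. The published R² = 0.993 is not matched exactly — its noise
realization is unknowable — only bounded (R² ≥ 0.99).

## Gait pipeline

* **Calibration** inverts the linear transduction per channel,
  $P = ((C/C_0) - 1)/S$, floors negative estimates at zero and flags (never
  clips) values below the 41.5 kPa limit of detection. The forward
  conversion used by the simulator (`to_capacitance`) applies, by default,
  only this invertible linear map: switching on the first-order lag
  (142/160 ms against 0.4–0.9 s pressure bumps attenuates peaks 4–15%) or
  the hysteretic branch (up to ~12 kPa of non-invertible excess) would break
  the pipeline's sub-kPa round-trip contract. Both effects remain available
  as flags for generating rawer signals.
* **Center of pressure** is the pressure-weighted centroid of the sensor
  coordinates (pressure- and force-weighting coincide here because all
  sensors share one face area); frames with under 1 kPa total are flagged
  invalid rather than erroring.
* **Heatmap.** The display's insole is divided into exactly 227 cells. The
  tessellation is not published beyond the count, so the cells are the
  members of a fixed square raster (pitch 8.47 mm, origin offset
  (0.5, 7.0) mm — found once by search over the elliptical outline so that
  exactly 227 cell centers fall inside, then frozen in the layout file),
  each mapped to its nearest sensor. Colors use the display's ten-level
  0–450 kPa scale, `floor(10 * clip(p, 0, 450)/450)` capped at level 9.
* **Segmentation** classifies frames from zone activations (zone mean at or
  above 45 kPa, inclusive with a float tolerance because the simulated means
  touch the threshold exactly at boundaries): heel only → heel strike;
  heel + metatarsals → foot flat; metatarsals without heel or toes →
  midstance; metatarsals + toes without heel → heel off; toes only →
  toe off; nothing → swing. A 5-frame running median removes chatter; cycle
  boundaries sit at swing → heel-strike transitions. The published "stance"
  posture (a static, evenly loaded standing frame) is outside this cyclic
  inventory and is treated as a separate non-cyclic condition.

## Numerical choices and degenerate inputs

Range checks against the 872.4 kPa working bound carry a 1e-5 relative slack
because the bound itself is the *rounded* rig conversion of 14.7 kg
(872.4036 kPa exactly). The staircase requires a whole number of cycles per
level; non-uniform sample times (jitter above 1% of the interval) are format
errors naming the offending line; empty trace files read as empty traces
with a warning; an all-zero frame series segments as all-swing with a
warning. Tests scale long protocols down (4–6 cycles per staircase level
instead of the bench's 40) where the noiseless result is provably identical
because steady state is reached well within one cycle; the durability
criterion runs its full 2,280 cycles.

## Known limitations

Temperature, humidity and electromagnetic interference — acknowledged
sensitivities of capacitive sensing — are not modelled. The grid-to-sensor
assignment of the original display and the true sensor coordinates are
unrecoverable; only the cell count and the zone structure are authoritative,
so absolute CoP coordinates are meaningful only relative to the shipped
layout. The gait waveform family is a stylized stance-only construction; it
is calibrated to the published per-sensor peaks, not to force-plate ground
truth.
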