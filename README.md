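# smartinsole

Simulation and analysis chain for a 3D-printed capacitive smart insole: a
16-channel plantar-pressure wearable built from printed capacitive pressure
sensors. The package is aimed at wearable-biomechanics researchers and
sensor engineers who need a tested, reproducible software counterpart to
such a device — to characterize sensors, to prototype gait-analysis
algorithms against synthetic ground truth, or to analyze their own recorded
traces via CSV.

It implements, as first-class tested code:

* **Sensor model** — series two-dielectric capacitance
  `C = ε₀A / (d₁/k₁ + d₂/k₂)`; linear transduction `ΔC/C₀ = S·P`
  (S = 1.19 MPa⁻¹ on the bench, 0.55 MPa⁻¹ inside the insole); a hysteretic
  unloading branch `S·P + α·P(P_max − P)` calibrated to a 9.8% degree of
  hysteresis; asymmetric first-order dynamics tuned to 142 ms response /
  160 ms recovery (10–90% convention, `t = τ·ln 9`).
* **Rig simulator** — staircase calibration (0.7–14.7 kg ⇒ 41.5–872.4 kPa in
  59.35 kPa steps), cadence sweeps (30–70 steps/min), durability runs
  (2,280 cycles/h), triangular hysteresis ramps.
* **Characterization** — sensitivity/linearity (OLS slope, SE, R²), degree of
  hysteresis `DH(%) = 100(A_unload − A_load)/A_load` by trapezoidal
  integration, 10–90% response/recovery with sub-sample interpolation,
  loading-frequency invariance, durability drift.
* **Gait simulator** — 16 sensors in four anatomical zones (phalanges,
  metatarsals, arch, calcaneus) producing labelled gait cycles with the
  recorded per-sensor peak structure (H1 = 295, T1 = 370, ME5 = 380,
  T4 = 127 kPa; middle toes unloaded; arch < 150 kPa).
* **Gait pipeline** — capacitance→pressure calibration with LoD flagging,
  center-of-pressure trajectories (pressure-weighted centroid), the display's
  227-cell heatmap on its ten-level 0–450 kPa scale, rule-based gait-phase
  segmentation (heel strike → foot flat → midstance → heel off → toe off →
  swing), per-zone peak summaries.

See `vignettes/smartinsole-methods.Rmd` for the models, their assumptions and
the design decisions.

## Worked example

```r
library(smartinsole)

## bench characterization of the default sensor (scaled staircase/durability)
sp <- sensor_spec()
characterize_sensor(sp, duration_per_level = 7.5, durability_cycles = 80)
#> <characterization_report>
#>   sensitivity: 1.190 +/- 0.000 MPa^-1 (R^2 = 1.0000)
#>   degree of hysteresis: 9.8 %
#>   response/recovery: 142 / 160 ms
#>   cadence invariance: 0.0029; drift C0 0.0000, Cf 0.0000

## synthetic gait: 3 cycles at 100 Hz, segmented and summarized
fr   <- simulate_gait(gait_spec(), n_cycles = 3)
seg  <- segment_phases(fr)
zone_summaries(fr, seg)$zones
#>          zone peak_kpa sensor
#> 1   phalanges 369.8783     T1
#> 2 metatarsals 379.9703    ME5
#> 3        arch 119.9920     M1
#> 4   calcaneus 294.9318     H1
```

The characterization report reproduces the device's headline numbers: the
sensitivity slope (relative capacitance change per MPa of applied pressure),
its perfect linearity in the noiseless model, the 9.8% loading/unloading
loop-area difference, the 10–90% step timing in milliseconds, the sub-1%
amplitude variation across gait speeds, and zero baseline/peak drift over a
durability run. The zone table shows each zone's peak plantar pressure over
the simulated stance (kPa) and which sensor carried it — metatarsal ME5 and
hallux-side T1 dominate push-off, heel H1 dominates heel strike, and the arch
stays below 150 kPa, matching the recorded subject.

## Command line

```sh
Rscript inst/exec/insole simulate-gait --out frames.csv --n-cycles 3
Rscript inst/exec/insole analyze-gait --frames frames.csv \
    --out summary.json --cop cop.csv --segmentation seg.json
Rscript inst/exec/insole report --seed 1 --out report.json
```

(after installation the launcher also lives in the installed package's
`exec/` directory).

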