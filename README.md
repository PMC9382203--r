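# thermoramp

Cardiorespiratory analysis of acute thermal-ramping trials in fish.

When a fish is warmed toward its critical thermal maximum (CTmax, the
temperature at which it can no longer hold an upright posture), the question
of *why* it fails is usually framed through oxygen supply: by the Fick
principle,

    MO2 = CO x (A-V O2),

whole-animal oxygen uptake (ṀO₂, mg O₂ kg⁻¹ h⁻¹) is the product of
mass-specific cardiac output (CO, ml min⁻¹ kg⁻¹) and the arteriovenous O₂
content difference (mg O₂ ml⁻¹). Water oxygenation above air saturation
(hyperoxia) can expand this supply capacity and raise CTmax. `thermoramp`
implements the full analysis chain for such trials, for experimental
physiologists working with intermittent stop-flow respirometry and
ventral-aortic flow probes:

- **Respirometry**: closed-phase O₂ declines (recorded in % air saturation
  at 10 Hz) are converted to mg L⁻¹ with the Benson–Krause freshwater
  solubility curve, fit by ordinary least squares, QC'd on R² (default
  threshold 0.95, flag-don't-drop), corrected with a temperature-interpolated
  background slope anchored at the start (10 °C) and end (CTmax temperature)
  of the protocol, and converted to mass-specific ṀO₂. Routine ṀO₂
  (ṀO₂-ROU) at each temperature step is the mean of its three measurement
  cycles; the maximal ṀO₂-ROU is the highest step mean.
- **Cardiac variables**: beat detection on the pulsatile flow trace gives
  heart rate; the time-mean flow over the *same* closed-cycle windows gives
  cardiac output; stroke volume is CO/HR; and A-V O₂ is estimated as
  `mo2 / (co * 60)`. Maximal cardiac values are tied to the step where
  maximal ṀO₂-ROU occurred.
- **Statistics**: natural-log transforms, Welch/Student t-tests, a
  Mann–Whitney U test with an exact enumeration branch for small samples,
  and mixed two-way (treatment × temperature) ANOVA with the
  Greenhouse–Geisser sphericity adjustment.
- **Thermal tolerance**: CTmax group comparison (mean and median difference
  plus Mann–Whitney), an LT50 logistic fit with bootstrap confidence
  intervals, and a packaged literature table of hyperoxia × CTmax
  experiments across 20 fish species with prevalence summaries.
- **Synthetic trials**: a generator that emulates the whole protocol —
  step-wise ramping (5 °C h⁻¹ to 20 °C, then 2 °C h⁻¹, with 20-min
  measurement plateaus), closed/flush respirometry cycles contaminated by a
  temperature-dependent background slope, a pulsatile flow channel, blood
  panels, and per-fish loss-of-equilibrium events — with ground-truth
  sidecars, so every stage is testable end to end without animal data.

## Worked example

Simulate the default two-arm trial (9 fish per oxygen treatment, ~100% vs
~200% air saturation) and run every stage:

```r
library(thermoramp)

cfg    <- cohort_config(seed = 1)
cohort <- generate_cohort(cfg)
report <- run_pipeline(cohort = cohort)
```

The report printed (seed 1):

```
max MO2-ROU: normoxia 292.1 +/- 5.1, hyperoxia 451.9 +/- 7.7 mg O2/kg/h
occurring at 24.9 vs 25.8 degC
contrasts at max window: CO +31.4%, SV +44.7%, HR -9.2%, A-V O2 +17.6%
CTmax: 26.24 vs 27.26 degC (diff 1.01), Mann-Whitney p = 4.1e-05
lactate at 26 degC: 10.4 vs 1.6 mM (p = 5.6e-09)
literature: 20 species, 9 significant, 50% increased, range 0.4-1.8 degC
```

Reading this: the hyperoxic arm sustains a far higher maximal routine ṀO₂
(+55%) at a slightly warmer temperature, driven mostly by stroke volume
(+45%) and cardiac output (+31%) at the max-ṀO₂ window; its CTmax is about
1 °C higher; and the lactate surge near the thermal limit is strongly
attenuated. The mixed ANOVA on ln ṀO₂-ROU up to 25 °C reports
Greenhouse–Geisser adjusted treatment × temperature interaction statistics
(`report$anova_mo2`). The literature line is the packaged synthesis: of 20
species tested to date, 9 show a statistically significant CTmax elevation
under hyperoxia and 10 (50%) show an increase, the significant improvements
spanning 0.4–1.8 °C.

`run_pipeline(cfg, output_dir = "out")` additionally writes `report.json`
and `report.md`; `write_cohort()` / `read_cohort()` round-trip the raw
trial (10 Hz trace CSVs, event logs, blood panels, ground-truth JSON
sidecars). A thin command-line wrapper lives at
`inst/scripts/thermoramp.R` (`simulate`, `run`, `meta` subcommands).

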