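---
title: "Methods: thermal-ramping cardiorespiratory analysis and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-ramping cardiorespiratory analysis and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thermoramp` analyses acute-warming trials in which a fish sits in a sealed,
intermittently flushed respirometer while water temperature is ramped
step-wise to the loss of equilibrium (CTmax). This vignette documents the
measurement model each stage assumes, the tunable parameters and their
defaults, what the synthetic-trial generator does and does not emulate, and
the numerical and design choices that were genuinely open.

## The measurement model

**Respirometry.** During a closed phase the chamber O₂ concentration
declines linearly when temperature is stable and uptake is constant:

    dC/dt = -(MO2 · m) / V_eff + b(T),        V_eff = V - m / rho

with `C` in mg O₂ L⁻¹, `MO2` the mass-specific uptake (mg O₂ kg⁻¹ h⁻¹,
after unit conversion), `m` the body mass (kg), `V` the chamber volume (10 L
default) and `rho` = 1 kg L⁻¹ the assumed fish density. `b(T)` is the
background flux from everything that is not the fish — microbial
respiration, probe drift, and the small (~0.15 °C) warming of the sealed
chamber by the mixing pump. The probe reports % air saturation; conversion
to concentration uses the Benson–Krause freshwater saturation function at
standard pressure with salinity fixed at zero (the trials are freshwater;
there is no salinity or pressure correction in scope). Each closed phase is
fit by ordinary least squares of concentration on time in minutes.

*Background model.* `b(T)` is linear in temperature between two measured
anchors: the empty-chamber slope at the starting temperature (10 °C,
typically slightly positive, i.e. apparent O₂ gain) and at the CTmax
temperature (often slightly negative). The sign convention is locked by
tests: the corrected fish slope is `raw − b(T)`, so a positive background
*steepens* the fish-attributed decline. The small closed-phase warming
artefact is deliberately absorbed into the background anchors rather than
modelled as a separate temperature term.

*QC.* A cycle passes QC when its slope R² ≥ 0.95 (configurable). Failing
cycles are flagged, never silently dropped; routine values then average the
passing cycles and report how many were used. Lowering the threshold can
only add passing cycles (tested as a monotonicity property).

*Step summaries.* Each cycle is labelled with the protocol step nearest the
mean of its temperature channel. Routine ṀO₂ at a step is the mean of its
(three) cycles; the maximal routine value is the arg-max over steps, with
ties broken toward the higher temperature (warming trials approach the
maximum from below, so the warmer of two tied steps is the physiologically
later, more informative one).

**Cardiac variables.** Heart rate comes from local-maximum beat detection on
the 10 Hz pulsatile flow trace. Two parameters matter: the minimum peak
height, 0.3 of the window's amplitude range above its minimum, and a
refractory period, `60 / (2.5 × running HR)` s with the running estimate
taken from the median inter-candidate interval. Both are configurable;
the defaults resolve trout-like rates (50–120 bpm) at 10 Hz with pulse
amplitude noise up to ~10%. Heart rate is `60 (n−1) / (t_n − t_1)` over the
detected beats — the first-to-last-span estimator, unbiased for windows that
do not contain a whole number of beats. Cardiac output is the time-mean flow
over the window divided by body mass; stroke volume is CO/HR and is carried
mass-specific (ml beat⁻¹ kg⁻¹) because CO is mass-normalised — multiply by
mass for the absolute per-beat volume. Cardiac windows are *tied* to the
respirometry cycles: routine cardiac values at a step average the same three
closed intervals as ṀO₂-ROU, and the "maximal" cardiac values are taken at
the step of maximal ṀO₂-ROU even if CO is numerically higher elsewhere,
because the scientific question is what the heart was doing when oxygen
supply peaked. The arteriovenous O₂ content difference is the Fick
rearrangement `avo2 = mo2 / (co · 60)` (mg O₂ ml⁻¹); mass cancels.

**Statistics.** Repeated-measures comparisons use a split-plot
(between-treatment × within-temperature) ANOVA restricted to the steps all
animals completed, with subjects missing a level removed listwise.
Sphericity is assumed violated: the within and interaction tests scale both
degrees of freedom by the Greenhouse–Geisser epsilon, estimated from the
pooled within-group covariance of the repeated measures via orthonormal
contrasts and clamped to `[1/(k−1), 1]` (`k = 2` forces ε = 1). The sums of
squares come from the classical balanced split-plot decomposition (fit with
`stats::aov`); tests verify them against an explicit cell-means computation
and against an independent multivariate-model route. Pairwise contrasts use
Welch's t-test by default — the safer choice when variances may differ and
the historical analyses do not state a pooling assumption — with the pooled
Student form available. Skewed positive variables (ṀO₂, SV, A-V O₂,
lactate) are compared on the natural-log scale. The Mann–Whitney U test
enumerates all label assignments exactly when `n1+n2 ≤ 20` and the data are
untied (at 9 vs 9 that is all C(18,9) = 48 620 assignments); larger or tied
samples use the normal approximation with tie and continuity corrections,
which agrees with the exact branch to < 0.01 in p at these sizes.

**Thermal tolerance and literature synthesis.** CTmax groups are compared by
both mean and median difference (the headline group effect is reported both
ways since either summary is defensible for these skewed distributions) plus
the Mann–Whitney test. The packaged literature table holds one row per
species × condition; per-species aggregation takes the *maximum* difference
across conditions (the conditions differ in O₂ dose and heating rate, and
the question is whether the species *can* benefit). A species counts as
"increased" when any condition is significant, or — for the one historical
study that could not run a test — when all its conditions show positive
differences. The improvement range is summarised over the significant
species only, to one decimal. The LT50 utility fits a two-parameter logistic
by binomial maximum likelihood; its confidence interval is a nonparametric
bootstrap over individuals (binomial resampling within each temperature
level, percentile interval), and non-overlap of two such intervals is the
significance criterion for LT50-style comparisons.

## The synthetic-trial generator

The generator exists so that every stage can be validated against known
ground truth. Its defaults *are* the study conditions the package targets: a
two-arm trial (≈97% vs ≈209% air saturation set-points), nine ~0.9 kg fish
per arm, ramping from 10 °C at 5 °C h⁻¹ to 20 °C and 2 °C h⁻¹ beyond, with
20-min plateaus at 15, 20, 22 °C and every degree thereafter. Each plateau
packs three 3-min closed cycles separated by two 5.5-min flushes
(closed–flush–closed–flush–closed = 20 min exactly); the stated ranges (2–5
min closed, 5–8 min flush) cannot fit three full closed+flush pairs into a
20-min plateau, so the flushes sit between the closed phases and ramping
doubles as the final flush.

Ground-truth curves per fish:

- ṀO₂(T): a Q10 exponential (Q10 = 2, 90 mg O₂ kg⁻¹ h⁻¹ at 10 °C) up to a
  divergence temperature of 23 °C, then a log-quartic cap rising to a
  treatment-specific peak — 292.8 mg O₂ kg⁻¹ h⁻¹ near 24.9 °C (normoxia) vs
  462.1 near 25.7 °C (hyperoxia) — and declining beyond it. The quartic
  exponent makes the curve rounded and nearly flat within ±0.5 °C of the
  peak, so sampling at whole-degree plateaus still observes essentially the
  peak value; a quadratic cap would bias the observed maximum low by a few
  percent.
- Heart rate: Q10 rise (Q10 = 1.6 from 52 bpm at 10 °C) capped at 98 bpm.
  Stroke volume: 0.45 ml beat⁻¹ kg⁻¹ shared below 23 °C, ramping over one
  degree to 0.56 (normoxia) vs 0.82 (hyperoxia). The hyperoxic arm's heart
  rate is scaled by 0.911 above the divergence window: the targeted +33% CO
  and +46% SV contrasts are only mutually consistent with CO = HR × SV if
  HR is ~9% lower under hyperoxia, so the generator injects exactly that.
- CTmax: truncated normal on (20, 30) °C, means 26.30 (normoxia) and 27.17
  (hyperoxia) — a +0.87 °C treatment effect — with sd 0.18 °C.
- Blood panel: lactate rises exponentially above a treatment-specific onset
  (23.5 vs 25.5 °C), venous PO₂ declines with temperature and carries a
  +1.2 kPa hyperoxia offset, haematocrit rises supralinearly above 20 °C
  and is lower under hyperoxia.
- Background: anchor slopes +0.004 mg O₂ L⁻¹ min⁻¹ at 10 °C and −0.002 at
  CTmax, per fish jittered 20%.

The flow channel is one half-rectified sinusoid per beat (systole occupying
40% of the period) over a 15% diastolic baseline, with the per-beat
amplitude set so the beat-mean flow equals HR × SV × mass; beat onsets are
stored as ground truth. The O₂ channel integrates the closed-phase balance
equation above and relaxes exponentially to the set-point during flushes
and ramps.

**Variability and noise calibration.** O₂ sensor noise is 0.1% air
saturation — the level at which closed-phase fits keep R² above 0.95 at
every step (mostly above 0.98), matching the data quality such systems
achieve in practice. Flow noise is 5% of the mean pulse amplitude.
Between-fish variability (CV 4.5% on the metabolic curve with a further
1.5% on the peak, 2% on the cardiac scales, sd 0.3 °C on the peak
temperature) is set so that a nine-fish group mean recovers the injected
group value with roughly a 3-standard-error margin inside the package's
stated recovery tolerances (±5% on group maximal ṀO₂, ±5 percentage points
on the cardiac contrasts, ±0.25 °C on the CTmax difference). These CVs are
deliberately *below* typical between-animal physiological variability
(often 10–20%): the generator is a parameter-recovery test bed, not a
variance-realistic population model, and a passing recovery test shows the
pipeline's estimators are accurate through realistic *measurement*
conditions, not that nine animals suffice in a real experiment. CTmax sd is
likewise a calibration choice, not a literature value.

**Determinism.** One master seed drives everything; per-fish substreams are
derived by a fixed affine hash of the master seed and fish index, so cohorts
are reproducible fish-by-fish and files written twice are byte-identical.

**What the generator does not emulate.** Haemodynamic waveform realism
(pressure, compliance, reflected waves); probe drift beyond Gaussian noise;
the exhaustive-exercise and recovery phase preceding ramping (trials start
at the recovered 10 °C state); behavioural artefacts (spontaneous activity
spikes in either channel); partial cycle dropouts. Passing tests therefore
demonstrate correctness of the computations under clean protocol structure
with realistic noise, not robustness to every field pathology.

## Numerical choices and degenerate inputs

- Ramp arithmetic follows the configured rates (10→15 °C at 5 °C h⁻¹ takes
  60 min); plateau and cycle packing is validated at construction and an
  infeasible combination is a configuration error.
- A constant-concentration segment yields slope 0 with undefined R² and an
  explicit QC failure; a degenerate time axis is an error.
- Negative corrected ṀO₂ is returned and flagged, never clipped.
- Mean squares below `1e-10 × (1 + mean(y²))` in the ANOVA are treated as
  numerically zero: the F ratio is reported as NaN with a "degenerate" note
  rather than a spurious 0/0 artefact.
- Bootstrap LT50 replicates with no response variation or estimates far
  outside the temperature span are discarded; the interval reports how many
  replicates remained.
- Cycles whose flow coverage is incomplete are flagged and excluded from
  window means rather than biasing them.
- The 26 °C blood comparison pools each fish's pre-CTmax 26 °C sample with
  the at-CTmax sample of fish that lost equilibrium during the 26 °C step
  (CTmax in [26, 27)); a flag records which kind each sample is.

## Problem sizes used by the test suite

Unit tests run on reduced protocols (plateaus to 22 °C) and one- to
three-fish cohorts; the end-to-end recovery checks use the full default
cohort (18 fish, ~10.7 h of protocol at 10 Hz ≈ 385k samples per channel per
fish). The interaction test's type-I error is estimated from a 2 000-rep
null simulation at n = 9 per group and k = 5 levels; bootstrap LT50 coverage
from 150 simulated challenges × 500 replicates; LT50 recovery at 50
individuals per temperature level. These sizes give stable Monte-Carlo
estimates while keeping the default suite around two minutes.

## Known limitations

- The solubility conversion is freshwater-only at standard pressure.
- Background correction assumes linearity in temperature between two
  anchors; curvature in the true background is absorbed into the residuals.
- The split-plot ANOVA requires complete cases after listwise deletion and
  at least two subjects per group; heavily unbalanced designs reduce to the
  subjects that completed all levels.
- Beat detection assumes a single dominant peak per beat; dicrotic
  waveforms would need a longer refractory period.
- The generator's hyperoxic heart-rate offset (−9%) is an internal
  consistency device for the CO/SV/HR triplet; a trial whose heart rates
  are truly identical across arms would show a CO contrast equal to its SV
  contrast instead.
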