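# Fish phenotypes: the ground-truth physiological curves a synthetic trial is
# built from. Oxygen uptake follows a Q10-style exponential rise to a
# treatment-specific peak (log-quartic cap around the peak temperature, so the
# curve is rounded near its maximum and treatments diverge only above the
# divergence temperature). Heart rate rises with a Q10 coefficient to a
# plateau; stroke volume ramps from a shared routine level to a
# treatment-specific maximum over the divergence window.

#' Construct a fish phenotype
#'
#' Bundles the ground-truth parameter set from which synthetic traces are
#' generated. Defaults (via [default_phenotype()]) describe a ~0.9 kg rainbow
#' trout acclimated to 10 degC.
#'
#' @param mass Body mass, kg.
#' @param treatment `"normoxia"` or `"hyperoxia"`.
#' @param mo2_baseline Routine oxygen uptake at 10 degC, mg O2 kg-1 h-1.
#' @param mo2_q10 Q10 coefficient of the routine rise below `t_div`.
#' @param t_div Temperature (degC) above which treatments diverge.
#' @param mo2_peak Peak routine oxygen uptake, mg O2 kg-1 h-1.
#' @param mo2_peak_temp Temperature of the peak, degC (> `t_div`).
#' @param hr_baseline Heart rate at 10 degC, beats min-1.
#' @param hr_q10 Q10 coefficient of heart rate.
#' @param hr_max Heart-rate plateau, beats min-1 (shared cap).
#' @param hr_treatment_scale Multiplier applied to heart rate above the
#'   divergence window (1 = no treatment effect).
#' @param sv_base Routine stroke volume below `t_div`, ml beat-1 kg-1.
#' @param sv_max Stroke volume above the divergence window, ml beat-1 kg-1.
#' @param ctmax_mean,ctmax_sd Mean and sd of the loss-of-equilibrium
#'   temperature, degC.
#' @param lactate_base Plasma lactate baseline, mmol L-1.
#' @param lactate_onset Temperature above which lactate rises, degC.
#' @param lactate_amp,lactate_rate Amplitude (mmol L-1) and exponential rate
#'   (per degC) of the lactate rise above onset.
#' @param pvo2_base Venous O2 partial pressure at 10 degC, kPa.
#' @param pvo2_slope Change in PvO2 per degC.
#' @param hct_base,hct_rise Haematocrit (%) at/below 20 degC and the
#'   supralinear rise coefficient above 20 degC.
#' @param bg_slope_start Background slope at 10 degC, mg O2 L-1 min-1
#'   (positive = apparent O2 gain).
#' @param bg_slope_end Background slope at the CTmax temperature.
#' @return An object of class `fish_phenotype`.
#' @export
fish_phenotype <- function(mass = 0.9,
                           treatment = c("normoxia", "hyperoxia"),
                           mo2_baseline = 90,
                           mo2_q10 = 2.0,
                           t_div = 23,
                           mo2_peak = 292.8,
                           mo2_peak_temp = 24.9,
                           hr_baseline = 52,
                           hr_q10 = 1.6,
                           hr_max = 98,
                           hr_treatment_scale = 1,
                           sv_base = 0.45,
                           sv_max = 0.56,
                           ctmax_mean = 26.3,
                           ctmax_sd = 0.18,
                           lactate_base = 0.8,
                           lactate_onset = 23.5,
                           lactate_amp = 0.5,
                           lactate_rate = 1.1,
                           pvo2_base = 4.0,
                           pvo2_slope = -0.125,
                           hct_base = 26.0,
                           hct_rise = 0.746,
                           bg_slope_start = 0.004,
                           bg_slope_end = -0.002) {
  treatment <- match.arg(treatment)
  if (mass <= 0) stop("mass must be positive")
  if (ctmax_sd < 0) stop("ctmax_sd must be non-negative")
  if (mo2_peak_temp <= t_div) stop("mo2_peak_temp must exceed t_div")
  mo2_tdiv <- mo2_baseline * mo2_q10^((t_div - 10) / 10)
  if (mo2_peak <= mo2_tdiv) {
    # keep the post-divergence branch a genuine peak
    mo2_peak <- mo2_tdiv * 1.05
  }
  structure(list(
    mass = mass, treatment = treatment,
    mo2_baseline = mo2_baseline, mo2_q10 = mo2_q10, t_div = t_div,
    mo2_peak = mo2_peak, mo2_peak_temp = mo2_peak_temp,
    hr_baseline = hr_baseline, hr_q10 = hr_q10, hr_max = hr_max,
    hr_treatment_scale = hr_treatment_scale,
    sv_base = sv_base, sv_max = sv_max,
    ctmax_mean = ctmax_mean, ctmax_sd = ctmax_sd,
    lactate_base = lactate_base, lactate_onset = lactate_onset,
    lactate_amp = lactate_amp, lactate_rate = lactate_rate,
    pvo2_base = pvo2_base, pvo2_slope = pvo2_slope,
    hct_base = hct_base, hct_rise = hct_rise,
    bg_slope_start = bg_slope_start, bg_slope_end = bg_slope_end
  ), class = "fish_phenotype")
}

# linear 0..1 ramp between lo and hi
ramp01 <- function(x, lo, hi) pmin(1, pmax(0, (x - lo) / (hi - lo)))

#' Ground-truth routine oxygen uptake at a temperature
#'
#' Below the divergence temperature the curve is a Q10 exponential; above it,
#' a log-quartic cap rises to the phenotype's peak and declines beyond the
#' peak temperature. Continuous at the divergence temperature.
#'
#' @param phenotype A [fish_phenotype()].
#' @param temp_C Temperature(s), degC.
#' @return Oxygen uptake in mg O2 kg-1 h-1 (vectorised).
#' @export
mo2_at_temp <- function(phenotype, temp_C) {
  p <- phenotype
  base_branch <- p$mo2_baseline * p$mo2_q10^((temp_C - 10) / 10)
  mo2_tdiv <- p$mo2_baseline * p$mo2_q10^((p$t_div - 10) / 10)
  c4 <- log(p$mo2_peak / mo2_tdiv) / (p$mo2_peak_temp - p$t_div)^4
  peak_branch <- exp(log(p$mo2_peak) - c4 * (temp_C - p$mo2_peak_temp)^4)
  ifelse(temp_C <= p$t_div, base_branch, peak_branch)
}

#' Ground-truth heart rate at a temperature
#'
#' Q10 rise capped at `hr_max`, with the treatment multiplier phased in over
#' the divergence window (`t_div` to `t_div + 1` degC).
#'
#' @inheritParams mo2_at_temp
#' @return Heart rate in beats min-1 (vectorised).
#' @export
hr_at_temp <- function(phenotype, temp_C) {
  p <- phenotype
  hr <- pmin(p$hr_baseline * p$hr_q10^((temp_C - 10) / 10), p$hr_max)
  mult <- 1 + (p$hr_treatment_scale - 1) * ramp01(temp_C, p$t_div, p$t_div + 1)
  hr * mult
}

#' Ground-truth stroke volume at a temperature
#'
#' Shared routine level below the divergence temperature, ramping linearly to
#' the treatment-specific maximum over one degree.
#'
#' @inheritParams mo2_at_temp
#' @return Stroke volume in ml beat-1 kg-1 (vectorised).
#' @export
sv_at_temp <- function(phenotype, temp_C) {
  p <- phenotype
  p$sv_base + (p$sv_max - p$sv_base) * ramp01(temp_C, p$t_div, p$t_div + 1)
}

# Blood-panel ground truth ----------------------------------------------------

lactate_at_temp <- function(phenotype, temp_C) {
  p <- phenotype
  over <- pmax(0, temp_C - p$lactate_onset)
  p$lactate_base + ifelse(over > 0, p$lactate_amp * expm1(p$lactate_rate * over), 0)
}

pvo2_at_temp <- function(phenotype, temp_C) {
  pmax(0.5, phenotype$pvo2_base + phenotype$pvo2_slope * (temp_C - 10))
}

hct_at_temp <- function(phenotype, temp_C) {
  phenotype$hct_base + phenotype$hct_rise * pmax(0, temp_C - 20)^1.5
}

# Temperature-interpolated background slope (mg O2 L-1 min-1); anchored at
# 10 degC and the fish's CTmax temperature.
bg_at_temp <- function(phenotype, temp_C, ctmax_temp) {
  b <- (phenotype$bg_slope_end - phenotype$bg_slope_start) / (ctmax_temp - 10)
  phenotype$bg_slope_start + b * (temp_C - 10)
}

#' Draw a critical thermal maximum for one fish
#'
#' CTmax (the loss-of-equilibrium temperature) is drawn from a normal
#' distribution truncated to (20, 30) degC. With `sd = 0` the mean is
#' returned exactly.
#'
#' @param mean,sd Mean and standard deviation of the CTmax distribution, degC.
#' @return A single CTmax draw in degC, inside (20, 30).
#' @export
draw_ctmax <- function(mean, sd) {
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) return(min(max(mean, 20), 30))
  lo <- stats::pnorm(20, mean, sd)
  hi <- stats::pnorm(30, mean, sd)
  stats::qnorm(stats::runif(1, lo, hi), mean, sd)
}

#' Treatment-default phenotype
#'
#' Group-level phenotype defaults for the two oxygen treatments. The normoxia
#' and hyperoxia parameter sets encode the study conditions the generator
#' emulates: a peak routine oxygen uptake of 292.8 vs 462.1 mg O2 kg-1 h-1
#' reached near 24.9 vs 25.7 degC, a 46% higher peak stroke volume and 33%
#' higher cardiac output under hyperoxia, a CTmax elevation of 0.87 degC, an
#' attenuated lactate rise, higher venous PO2 and lower haematocrit in
#' hyperoxia.
#'
#' @param treatment `"normoxia"` or `"hyperoxia"`.
#' @param mass Body mass, kg.
#' @return A [fish_phenotype()].
#' @export
default_phenotype <- function(treatment = c("normoxia", "hyperoxia"), mass = 0.9) {
  treatment <- match.arg(treatment)
  if (treatment == "normoxia") {
    fish_phenotype(
      mass = mass, treatment = "normoxia",
      mo2_peak = 292.8, mo2_peak_temp = 24.9,
      hr_treatment_scale = 1, sv_max = 0.56,
      ctmax_mean = 26.30, ctmax_sd = 0.18,
      lactate_onset = 23.5,
      pvo2_base = 4.0,
      hct_base = 26.0, hct_rise = 0.746)
  } else {
    fish_phenotype(
      mass = mass, treatment = "hyperoxia",
      mo2_peak = 462.1, mo2_peak_temp = 25.7,
      hr_treatment_scale = 0.911, sv_max = 0.56 * 1.46,
      ctmax_mean = 27.17, ctmax_sd = 0.18,
      lactate_onset = 25.5,
      pvo2_base = 5.2,
      hct_base = 20.2, hct_rise = 0.597)
  }
}
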