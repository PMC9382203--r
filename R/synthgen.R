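# Synthetic thermal-ramping trials with known ground truth. Each fish gets a
# 10 Hz water-O2 channel (percent air saturation) and a pulsatile
# ventral-aortic flow channel (ml/min) on a shared time grid, an event log of
# closed/flush cycles, blood draws and the loss-of-equilibrium event, a blood
# panel, and a ground-truth sidecar holding the injected per-step values.

#' Configure a synthetic cohort
#'
#' Defines the study conditions for one simulated trial: two treatment arms
#' (normoxia ~97% and hyperoxia ~209% air saturation), `n_per_group` fish per
#' arm, sensor noise levels and between-fish variability, all fully
#' determined by `seed`.
#'
#' @param n_per_group Fish per treatment arm (default 9).
#' @param seed Master seed; per-fish substreams are derived from it.
#' @param o2_levels Named vector of water O2 set-points (% air saturation)
#'   for the two arms.
#' @param noise_o2 Gaussian sd of the O2 channel, % air saturation.
#' @param noise_flow Gaussian sd of the flow channel as a fraction of the
#'   mean pulse amplitude.
#' @param respirometer_volume Respirometer volume, litres.
#' @param dt Sampling interval, seconds (0.1 s = 10 Hz).
#' @param protocol A [ramp_protocol()].
#' @param mass_mean,mass_sd Named vectors (per arm) of body-mass mean and sd, kg.
#' @param cv_mo2 Between-fish CV of the whole metabolic curve (scales baseline
#'   and peak together).
#' @param cv_mo2_peak Additional independent CV of the peak level.
#' @param sd_peak_temp Between-fish sd of the peak temperature, degC.
#' @param cv_hr,cv_sv Between-fish CVs of the cardiac curves.
#' @param cv_bg Between-fish CV of the background anchor slopes.
#' @param output_dir Optional directory; when set, [generate_cohort()] writes
#'   the trial to disk.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 9,
                          seed = 1,
                          o2_levels = c(normoxia = 96.9, hyperoxia = 208.8),
                          noise_o2 = 0.1,
                          noise_flow = 0.05,
                          respirometer_volume = 10,
                          dt = 0.1,
                          protocol = ramp_protocol(),
                          mass_mean = c(normoxia = 0.8965, hyperoxia = 0.9018),
                          mass_sd = c(normoxia = 0.1425, hyperoxia = 0.2217),
                          cv_mo2 = 0.045,
                          cv_mo2_peak = 0.015,
                          sd_peak_temp = 0.3,
                          cv_hr = 0.02,
                          cv_sv = 0.02,
                          cv_bg = 0.2,
                          output_dir = NULL) {
  if (n_per_group < 1) stop("n_per_group must be at least 1")
  if (any(o2_levels <= 0)) stop("o2_levels must be positive")
  if (!all(c("normoxia", "hyperoxia") %in% names(o2_levels))) {
    stop("o2_levels must be named 'normoxia' and 'hyperoxia'")
  }
  structure(list(
    n_per_group = n_per_group, seed = as.integer(seed),
    o2_levels = o2_levels, noise_o2 = noise_o2, noise_flow = noise_flow,
    respirometer_volume = respirometer_volume, dt = dt, protocol = protocol,
    mass_mean = mass_mean, mass_sd = mass_sd,
    cv_mo2 = cv_mo2, cv_mo2_peak = cv_mo2_peak, sd_peak_temp = sd_peak_temp,
    cv_hr = cv_hr, cv_sv = cv_sv, cv_bg = cv_bg,
    output_dir = output_dir
  ), class = "cohort_config")
}

# stable per-fish substream seeds from the master seed
derive_seeds <- function(master, n) {
  as.integer(((as.numeric(master) %% 2147483647) +
                7919 * seq_len(n) * 104729) %% 2147483646 + 1)
}

# Per-fish phenotype draw around the treatment defaults. Uses the current RNG
# state (callers seed the per-fish substream first).
draw_phenotype <- function(treatment, config) {
  mass <- max(0.4, stats::rnorm(1, config$mass_mean[[treatment]],
                                config$mass_sd[[treatment]]))
  base <- default_phenotype(treatment, mass)
  s_mo2 <- max(0.5, stats::rnorm(1, 1, config$cv_mo2))
  s_pk <- max(0.5, stats::rnorm(1, 1, config$cv_mo2_peak))
  s_hr <- max(0.5, stats::rnorm(1, 1, config$cv_hr))
  s_sv <- max(0.5, stats::rnorm(1, 1, config$cv_sv))
  pk_temp <- max(base$t_div + 0.8,
                 base$mo2_peak_temp + stats::rnorm(1, 0, config$sd_peak_temp))
  fish_phenotype(
    mass = mass, treatment = treatment,
    mo2_baseline = base$mo2_baseline * s_mo2,
    mo2_q10 = base$mo2_q10, t_div = base$t_div,
    mo2_peak = base$mo2_peak * s_mo2 * s_pk,
    mo2_peak_temp = pk_temp,
    hr_baseline = base$hr_baseline * s_hr,
    hr_q10 = base$hr_q10, hr_max = base$hr_max * s_hr,
    hr_treatment_scale = base$hr_treatment_scale,
    sv_base = base$sv_base * s_sv, sv_max = base$sv_max * s_sv,
    ctmax_mean = base$ctmax_mean, ctmax_sd = base$ctmax_sd,
    lactate_base = base$lactate_base, lactate_onset = base$lactate_onset,
    lactate_amp = base$lactate_amp, lactate_rate = base$lactate_rate,
    pvo2_base = base$pvo2_base, pvo2_slope = base$pvo2_slope,
    hct_base = base$hct_base, hct_rise = base$hct_rise,
    bg_slope_start = base$bg_slope_start * max(0, stats::rnorm(1, 1, config$cv_bg)),
    bg_slope_end = base$bg_slope_end * max(0, stats::rnorm(1, 1, config$cv_bg)))
}

#' Generate a water-O2 trace for one fish
#'
#' During closed (sealed) phases dissolved O2 declines at the rate set by the
#' fish's oxygen uptake plus the temperature-interpolated background slope;
#' outside closed phases the chamber relaxes exponentially back to the
#' treatment set-point. The trace is returned in percent air saturation with
#' additive Gaussian sensor noise.
#'
#' @param phenotype A [fish_phenotype()].
#' @param profile Temperature profile data frame (`time_s`, `temp_C`),
#'   already truncated at loss of equilibrium.
#' @param closed_windows Data frame with `closed_start_s` / `closed_end_s`
#'   columns (see [cycle_schedule()]), truncated to the profile.
#' @param sat_pct Water O2 set-point, % air saturation.
#' @param volume Respirometer volume, litres.
#' @param ctmax_temp CTmax temperature anchoring the background model, degC.
#' @param noise_sd Sensor noise sd, % air saturation.
#' @param relax_rate Flush relaxation rate constant, per second.
#' @return Numeric vector of % air saturation, one value per profile row.
#' @export
generate_o2_trace <- function(phenotype, profile, closed_windows, sat_pct,
                              volume, ctmax_temp, noise_sd = 0.1,
                              relax_rate = 0.02) {
  mass <- phenotype$mass
  v_fish <- mass / 1.0  # fish density assumed 1 kg/L
  if (volume <= v_fish) stop("respirometer volume must exceed fish volume")
  veff <- volume - v_fish
  tt <- profile$time_s
  temp <- profile$temp_C
  n <- length(tt)
  dt <- tt[2] - tt[1]
  sat <- o2_sat_mgL(temp)
  sp <- sat_pct / 100 * sat
  conc <- numeric(n)
  cw <- closed_windows[order(closed_windows$closed_start_s), , drop = FALSE]
  cw <- cw[cw$closed_end_s <= tt[n], , drop = FALSE]
  idx_of <- function(t) as.integer(round(t / dt)) + 1L

  c0 <- sp[1]
  pos <- 1L  # next unfilled sample
  fill_open <- function(i1, i2, c0) {
    if (i2 < i1) return(c0)
    rel <- exp(-relax_rate * (tt[i1:i2] - tt[i1] + dt))
    conc[i1:i2] <<- sp[i1:i2] + (c0 - sp[max(1L, i1 - 1L)]) * rel
    conc[i2]
  }
  fill_closed <- function(i1, i2, c0) {
    if (i2 < i1) return(c0)
    rate <- -mo2_at_temp(phenotype, temp[i1:i2]) * mass / (veff * 3600) +
      bg_at_temp(phenotype, temp[i1:i2], ctmax_temp) / 60
    conc[i1:i2] <<- c0 + cumsum(rate * dt)
    conc[i2]
  }
  for (w in seq_len(nrow(cw))) {
    i_c0 <- idx_of(cw$closed_start_s[w])  # last open sample: seal moment
    i_c1 <- min(n, idx_of(cw$closed_end_s[w]))
    c0 <- fill_open(pos, min(i_c0, n), c0)
    c0 <- fill_closed(i_c0 + 1L, i_c1, c0)
    pos <- i_c1 + 1L
    if (pos > n) break
  }
  if (pos <= n) fill_open(pos, n, c0)
  if (min(conc) <= 0) {
    stop("simulated O2 fell to zero: fish too large or closed phase too long")
  }
  pct <- 100 * conc / sat
  if (noise_sd > 0) pct <- pct + stats::rnorm(n, 0, noise_sd)
  pct
}

#' Generate a pulsatile blood-flow trace for one fish
#'
#' One half-rectified sinusoidal pulse per heart beat over a diastolic
#' baseline, scheduled so that the per-beat mean flow equals
#' `heart_rate(T) * stroke_volume(T) * mass` in ml/min. Beat onset times
#' (ground truth) are returned alongside the sampled trace.
#'
#' @inheritParams generate_o2_trace
#' @param noise_frac Gaussian noise sd as a fraction of the mean pulse
#'   amplitude.
#' @param systole_frac Fraction of the beat period occupied by the pulse.
#' @param diastole_level Diastolic baseline flow as a fraction of the beat
#'   mean flow.
#' @return A list with `flow_mL_min` (vector matching the profile grid) and
#'   `beats_s` (true beat onset times, seconds).
#' @export
generate_flow_trace <- function(phenotype, profile, noise_frac = 0.05,
                                systole_frac = 0.4, diastole_level = 0.15) {
  tt <- profile$time_s
  temp <- profile$temp_C
  n <- length(tt)
  dt <- tt[2] - tt[1]
  hrg <- hr_at_temp(phenotype, temp)
  if (min(hrg) <= 0) stop("heart-rate curve must be positive over the protocol")
  if (max(hrg) >= 60 * 0.5 / dt) {
    stop("heart rate exceeds the Nyquist-resolvable rate at this sampling interval")
  }
  t_end <- tt[n]
  cap <- as.integer(ceiling(t_end * max(hrg) / 60)) + 2L
  onsets <- numeric(cap)
  nb <- 0L
  t <- 0
  while (t <= t_end) {
    nb <- nb + 1L
    onsets[nb] <- t
    t <- t + 60 / hrg[min(n, as.integer(t / dt) + 1L)]
  }
  onsets <- onsets[seq_len(nb)]
  period <- c(diff(onsets), 60 / hrg[n])
  ionset <- pmin(n, as.integer(onsets / dt) + 1L)
  svb <- sv_at_temp(phenotype, temp[ionset])
  mf <- (60 / period) * svb * phenotype$mass  # per-beat mean flow, ml/min
  bl <- diastole_level * mf
  ds <- systole_frac * period
  amp <- (mf - bl) * period / (ds * 2 / pi)
  idx <- findInterval(tt, onsets)
  phase <- tt - onsets[idx]
  flow <- bl[idx] + ifelse(phase < ds[idx], amp[idx] * sin(pi * phase / ds[idx]), 0)
  if (noise_frac > 0) flow <- flow + stats::rnorm(n, 0, noise_frac * mean(amp))
  list(flow_mL_min = flow, beats_s = onsets)
}

#' Generate a venous blood panel for one fish
#'
#' Samples at the protocol's scheduled temperatures that the fish reached,
#' plus a final draw at CTmax. Lactate follows the phenotype's exponential
#' rise above its onset temperature; PvO2, haematocrit and haemoglobin follow
#' the phenotype curves, all with measurement noise.
#'
#' @inheritParams generate_o2_trace
#' @param protocol The [ramp_protocol()].
#' @param ctmax CTmax temperature, degC.
#' @param t_loe Loss-of-equilibrium time, seconds.
#' @param noise Logical; add measurement noise.
#' @return Data frame: `time_s`, `nominal_temp_C`, `temp_C`, `pvo2_kPa`,
#'   `hct_pct`, `hb_g_dL`, `lactate_mM`, `at_ctmax`.
#' @export
generate_blood_samples <- function(phenotype, protocol, ctmax, t_loe,
                                   noise = TRUE) {
  sch <- blood_sample_schedule(protocol)
  sch <- sch[sch$time_s <= t_loe, , drop = FALSE]
  temps <- c(sch$step_temp, ctmax)
  times <- c(sch$time_s, t_loe)
  at_ct <- c(rep(FALSE, nrow(sch)), TRUE)
  m <- length(temps)
  lac <- lactate_at_temp(phenotype, temps)
  pv <- pvo2_at_temp(phenotype, temps)
  hct <- hct_at_temp(phenotype, temps)
  if (noise) {
    lac <- lac * exp(stats::rnorm(m, 0, 0.10))
    pv <- pmax(0.3, pv + stats::rnorm(m, 0, 0.15))
    hct <- pmax(5, hct + stats::rnorm(m, 0, 1.2))
  }
  hb <- pmax(1, hct * 0.33 + if (noise) stats::rnorm(m, 0, 0.2) else 0)
  data.frame(time_s = times,
             nominal_temp_C = c(sch$step_temp, NA_real_),
             temp_C = temps,
             pvo2_kPa = pv, hct_pct = hct, hb_g_dL = hb,
             lactate_mM = lac, at_ctmax = at_ct)
}

# Event log for one fish: completed closed/flush cycles, blood draws and the
# terminal loss-of-equilibrium event, ordered by time.
build_event_log <- function(closed_windows, blood, t_loe) {
  ev <- list()
  add <- function(time_s, event) {
    ev[[length(ev) + 1L]] <<- data.frame(time_s = time_s, event = event)
  }
  for (w in seq_len(nrow(closed_windows))) {
    add(closed_windows$closed_start_s[w], "closed_start")
    add(closed_windows$closed_end_s[w], "closed_end")
    if (!is.na(closed_windows$flush_start_s[w]) &&
        closed_windows$flush_end_s[w] <= t_loe) {
      add(closed_windows$flush_start_s[w], "flush_start")
      add(closed_windows$flush_end_s[w], "flush_end")
    }
  }
  for (b in seq_len(nrow(blood))) add(blood$time_s[b], "blood_sample")
  add(t_loe, "loss_of_equilibrium")
  out <- do.call(rbind, ev)
  out[order(out$time_s, out$event), , drop = FALSE]
}

# Simulate one fish end to end on its own RNG substream.
simulate_fish <- function(id, treatment, config, profile, schedule, seed) {
  set.seed(seed)
  ph <- draw_phenotype(treatment, config)
  ctmax <- draw_ctmax(ph$ctmax_mean, ph$ctmax_sd)
  iloe <- match(TRUE, profile$temp_C >= ctmax)
  if (is.na(iloe)) iloe <- nrow(profile)
  t_loe <- profile$time_s[iloe]
  prof <- profile[seq_len(iloe), , drop = FALSE]
  cw <- schedule[schedule$closed_end_s <= t_loe, , drop = FALSE]
  if (nrow(cw) == 0) stop("fish lost equilibrium before any measurement cycle")
  o2 <- generate_o2_trace(ph, prof, cw, config$o2_levels[[treatment]],
                          config$respirometer_volume, ctmax,
                          noise_sd = config$noise_o2)
  fl <- generate_flow_trace(ph, prof, noise_frac = config$noise_flow)
  blood <- generate_blood_samples(ph, config$protocol, ctmax, t_loe)
  events <- build_event_log(cw, blood, t_loe)
  steps <- unique(cw$step_temp)
  truth_steps <- data.frame(
    step_temp = steps,
    mo2 = mo2_at_temp(ph, steps),
    heart_rate = hr_at_temp(ph, steps),
    stroke_volume = sv_at_temp(ph, steps),
    cardiac_output = hr_at_temp(ph, steps) * sv_at_temp(ph, steps))
  list(id = id, treatment = treatment, mass = ph$mass,
       phenotype = ph, ctmax_C = ctmax, t_loe_s = t_loe,
       trace = data.frame(time_s = prof$time_s, temp_C = prof$temp_C,
                          o2_airsat_pct = o2, flow_mL_min = fl$flow_mL_min),
       events = events, blood = blood, beats_s = fl$beats_s,
       truth = list(id = id, treatment = treatment, mass_kg = ph$mass,
                    ctmax_C = ctmax, t_loe_s = t_loe,
                    bg_slope_start = ph$bg_slope_start,
                    bg_slope_end = ph$bg_slope_end,
                    steps = truth_steps))
}

#' Generate a complete synthetic cohort
#'
#' Simulates `n_per_group` fish per treatment arm, each with O2 and flow
#' traces, event log, blood panel and a ground-truth sidecar. Fully
#' determined by the config's master seed (per-fish substreams are derived
#' from it, so cohorts are reproducible fish by fish).
#'
#' @param config A [cohort_config()].
#' @param write Write the trial to `config$output_dir` (default: only when an
#'   output directory is configured).
#' @return An object of class `thermoramp_cohort`: a list with `config` and
#'   `fish` (one entry per fish, see [simulate_fish] internals).
#' @export
generate_cohort <- function(config, write = !is.null(config$output_dir)) {
  stopifnot(inherits(config, "cohort_config"))
  profile <- generate_temperature_profile(config$protocol, config$dt)
  schedule <- cycle_schedule(config$protocol)
  treatments <- rep(c("normoxia", "hyperoxia"), each = config$n_per_group)
  seeds <- derive_seeds(config$seed, length(treatments))
  fish <- lapply(seq_along(treatments), function(i) {
    simulate_fish(sprintf("fish%02d_%s", i, treatments[i]), treatments[i],
                  config, profile, schedule, seeds[i])
  })
  names(fish) <- vapply(fish, `[[`, "", "id")
  cohort <- structure(list(config = config, fish = fish),
                      class = "thermoramp_cohort")
  if (write) write_cohort(cohort, config$output_dir)
  cohort
}

#' @export
print.thermoramp_cohort <- function(x, ...) {
  tr <- vapply(x$fish, `[[`, "", "treatment")
  cat(sprintf("Synthetic thermal-ramping cohort: %d fish (%d normoxia, %d hyperoxia), seed %d\n",
              length(x$fish), sum(tr == "normoxia"), sum(tr == "hyperoxia"),
              x$config$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One trace CSV, event-log CSV, blood-panel CSV and ground-truth JSON
#' sidecar per fish, plus the cohort config JSON. Outputs are plain text and
#' byte-identical across runs of the same config.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  cfg_out <- cfg
  cfg_out$protocol <- unclass(cfg$protocol)
  jsonlite::write_json(unclass(cfg_out), file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  for (f in cohort$fish) {
    data.table::fwrite(f$trace, file.path(dir, paste0(f$id, "_trace.csv")))
    data.table::fwrite(f$events, file.path(dir, paste0(f$id, "_events.csv")))
    data.table::fwrite(f$blood, file.path(dir, paste0(f$id, "_blood.csv")))
    jsonlite::write_json(f$truth, file.path(dir, paste0(f$id, "_truth.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
  }
  invisible(dir)
}

#' Read a cohort back from disk
#'
#' Reconstructs the per-fish objects written by [write_cohort()] (traces,
#' events, blood panels and ground-truth sidecars) for analysis.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `thermoramp_cohort`-like list with `config` (raw list) and `fish`.
#' @export
read_cohort <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "cohort_config.json"),
                             simplifyVector = TRUE)
  ids <- sub("_truth\\.json$", "",
             basename(list.files(dir, pattern = "_truth\\.json$")))
  fish <- lapply(ids, function(id) {
    truth <- jsonlite::read_json(file.path(dir, paste0(id, "_truth.json")),
                                 simplifyVector = TRUE)
    list(id = id, treatment = truth$treatment, mass = truth$mass_kg,
         ctmax_C = truth$ctmax_C, t_loe_s = truth$t_loe_s,
         trace = as.data.frame(data.table::fread(
           file.path(dir, paste0(id, "_trace.csv")))),
         events = as.data.frame(data.table::fread(
           file.path(dir, paste0(id, "_events.csv")))),
         blood = as.data.frame(data.table::fread(
           file.path(dir, paste0(id, "_blood.csv")))),
         truth = truth)
  })
  names(fish) <- ids
  structure(list(config = cfg, fish = fish), class = "thermoramp_cohort")
}
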