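# Shared fixtures: reduced protocols and cohorts built in code at test time.

small_protocol <- function(targets = c(15, 20, 22)) {
  ramp_protocol(step_targets = targets)
}

# deterministic config: no noise, no between-fish variability
quiet_config <- function(seed = 11, protocol = small_protocol(), ...) {
  cohort_config(n_per_group = 1, seed = seed, noise_o2 = 0, noise_flow = 0,
                protocol = protocol,
                cv_mo2 = 0, cv_mo2_peak = 0, sd_peak_temp = 0,
                cv_hr = 0, cv_sv = 0, cv_bg = 0,
                mass_sd = c(normoxia = 0, hyperoxia = 0), ...)
}

# default noise levels but no between-fish variability
noisy_config <- function(seed = 12, protocol = small_protocol(), ...) {
  cohort_config(n_per_group = 1, seed = seed, protocol = protocol,
                cv_mo2 = 0, cv_mo2_peak = 0, sd_peak_temp = 0,
                cv_hr = 0, cv_sv = 0, cv_bg = 0,
                mass_sd = c(normoxia = 0, hyperoxia = 0), ...)
}

analyze_one <- function(f, cfg) {
  steps <- c(cfg$protocol$start_temp, cfg$protocol$step_targets)
  bg <- background_model(f$truth$bg_slope_start, f$truth$bg_slope_end,
                         10, f$truth$ctmax_C)
  resp <- analyze_respirometry(f$trace, f$events, f$mass,
                               cfg$respirometer_volume, bg, steps = steps)
  card <- analyze_cardio(f$trace, f$events, f$mass, resp, steps = steps)
  list(resp = resp, card = card)
}

# a clean synthetic pulse train on a 10 Hz grid
pulse_train <- function(hr_bpm, duration_s, sv_ml_kg = 0.5, mass = 1,
                        noise = 0, dt = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ph <- fish_phenotype(mass = mass, hr_baseline = hr_bpm, hr_q10 = 1,
                       hr_max = hr_bpm, sv_base = sv_ml_kg, sv_max = sv_ml_kg)
  profile <- data.frame(time_s = seq(0, duration_s, by = dt), temp_C = 10)
  generate_flow_trace(ph, profile, noise_frac = noise)
}
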