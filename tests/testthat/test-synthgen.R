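test_that("closed-phase O2 loss conserves the injected oxygen uptake", {
  cfg <- quiet_config()
  co <- generate_cohort(cfg)
  f <- co$fish$fish01_normoxia
  segs <- segment_cycles(f$trace, f$events,
                         steps = c(10, cfg$protocol$step_targets))
  for (seg in segs) {
    step <- attr(seg, "step_temp")
    conc <- airsat_to_mgL(seg$o2_airsat_pct, seg$temp_C)
    dur_min <- (seg$time_s[nrow(seg)] - seg$time_s[1]) / 60
    veff <- cfg$respirometer_volume - f$mass
    mo2_true <- f$truth$steps$mo2[f$truth$steps$step_temp == step]
    bg_true <- thermoramp:::bg_at_temp(f$phenotype, step, f$ctmax_C)
    loss_mg <- (conc[1] - conc[nrow(seg)]) * veff
    expected <- mo2_true * f$mass * dur_min / 60 - bg_true * veff * dur_min
    expect_equal(loss_mg, expected, tolerance = 1e-6)
  }
})

test_that("a resting chamber with positive background gains oxygen", {
  ph <- fish_phenotype(mo2_baseline = 0, mo2_peak = 1, bg_slope_start = 0.01,
                       bg_slope_end = 0.01)
  profile <- data.frame(time_s = seq(0, 300, 0.1), temp_C = 10)
  cw <- data.frame(closed_start_s = 0, closed_end_s = 300)
  pct <- generate_o2_trace(ph, profile, cw, 100, 10, 26, noise_sd = 0)
  expect_gt(pct[length(pct)], pct[1])
})

test_that("noisy closed-phase slopes recover truth within the OLS error", {
  cfg <- noisy_config(seed = 31)
  co <- generate_cohort(cfg)
  f <- co$fish$fish01_normoxia
  segs <- segment_cycles(f$trace, f$events,
                         steps = c(10, cfg$protocol$step_targets))
  seg <- segs[[4]]
  conc <- airsat_to_mgL(seg$o2_airsat_pct, seg$temp_C)
  tmin <- (seg$time_s - seg$time_s[1]) / 60
  ols <- stats::lm(conc ~ tmin)
  se <- summary(ols)$coefficients["tmin", "Std. Error"]
  step <- attr(seg, "step_temp")
  veff <- cfg$respirometer_volume - f$mass
  truth_slope <- -f$truth$steps$mo2[f$truth$steps$step_temp == step] *
    f$mass / (veff * 60) +
    thermoramp:::bg_at_temp(f$phenotype, step, f$ctmax_C)
  expect_lt(abs(unname(coef(ols)[2]) - truth_slope), 2 * se + 1e-12)
})

test_that("clean pulse trains carry exactly one peak per beat", {
  tr <- pulse_train(60, 60)
  expect_equal(length(tr$beats_s), 61)  # onset at t = 0 plus one per second
  # doubling stroke volume doubles the window mean at fixed heart rate
  tr2 <- pulse_train(60, 60, sv_ml_kg = 1.0)
  expect_equal(mean(tr2$flow_mL_min) / mean(tr$flow_mL_min), 2,
               tolerance = 1e-9)
})

test_that("window mean flow equals heart rate times stroke volume", {
  # zero noise: time-mean of the pulse train reproduces HR x SV (ml/min/kg)
  tr <- pulse_train(97, 180, sv_ml_kg = 0.55, mass = 0.9)
  co_meas <- mean(tr$flow_mL_min) / 0.9
  expect_equal(co_meas, 97 * 0.55, tolerance = 5e-3)
  # integrated flow per beat recovers the stroke volume within 3%
  sv_meas <- co_meas / heart_rate(tr$beats_s)
  expect_lt(abs(sv_meas / 0.55 - 1), 0.03)
})

test_that("flow generation rejects unresolvable heart rates", {
  expect_error(pulse_train(400, 60), "Nyquist")
})

test_that("CTmax draws honour mean, sd, truncation and the seed", {
  expect_identical(draw_ctmax(26.5, 0), 26.5)
  set.seed(5); a <- draw_ctmax(26.5, 0.3)
  set.seed(5); b <- draw_ctmax(26.5, 0.3)
  expect_identical(a, b)
  set.seed(6)
  draws <- replicate(10000, draw_ctmax(26, 0.4))
  expect_true(all(draws > 20 & draws < 30))
  se <- 0.4 / sqrt(10000)
  expect_lt(abs(mean(draws) - 26), 3 * se)
  # heavy truncation still stays inside the bounds
  set.seed(7)
  wide <- replicate(2000, draw_ctmax(29, 4))
  expect_true(all(wide > 20 & wide < 30))
})

test_that("blood panels follow the phenotype curves", {
  # onset above CTmax: lactate stays at baseline in every sample
  ph <- fish_phenotype(lactate_onset = 40)
  b <- generate_blood_samples(ph, small_protocol(), ctmax = 23.5,
                              t_loe = 1e6, noise = FALSE)
  expect_true(all(b$lactate_mM == ph$lactate_base))
  expect_true(all(b$at_ctmax == c(rep(FALSE, nrow(b) - 1), TRUE)))
  # two treatments with equal parameters and no noise give identical panels
  b2 <- generate_blood_samples(ph, small_protocol(), 23.5, 1e6, noise = FALSE)
  expect_identical(b, b2)
  # the hyperoxia PvO2 offset appears in the noiseless panel
  pn <- default_phenotype("normoxia")
  phh <- default_phenotype("hyperoxia")
  bn <- generate_blood_samples(pn, small_protocol(), 26, 1e6, noise = FALSE)
  bh <- generate_blood_samples(phh, small_protocol(), 26, 1e6, noise = FALSE)
  expect_equal(bh$pvo2_kPa - bn$pvo2_kPa,
               rep(phh$pvo2_base - pn$pvo2_base, nrow(bn)))
  expect_true(all(bh$hct_pct < bn$hct_pct))
  expect_true(all(bn$lactate_mM > 0 & bn$pvo2_kPa > 0 & bn$hb_g_dL > 0))
})

test_that("cohorts are deterministic and write byte-identical files", {
  cfg <- noisy_config(seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$fish$fish01_normoxia$trace, b$fish$fish01_normoxia$trace)
  expect_identical(a$fish$fish02_hyperoxia$blood, b$fish$fish02_hyperoxia$blood)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(a, d1); write_cohort(b, d2)
  for (fn in list.files(d1)) {
    expect_identical(readBin(file.path(d1, fn), "raw", 1e7),
                     readBin(file.path(d2, fn), "raw", 1e7))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("n_per_group 1 yields two fish, one per arm", {
  co <- generate_cohort(quiet_config())
  expect_length(co$fish, 2)
  expect_setequal(vapply(co$fish, `[[`, "", "treatment"),
                  c("normoxia", "hyperoxia"))
})

test_that("ground-truth sidecars survive a disk round trip", {
  cfg <- noisy_config(seed = 19)
  co <- generate_cohort(cfg)
  d <- file.path(tempdir(), "coh_rt")
  write_cohort(co, d)
  back <- read_cohort(d)
  f0 <- co$fish$fish01_normoxia
  f1 <- back$fish$fish01_normoxia
  expect_equal(f1$truth$ctmax_C, f0$ctmax_C)
  expect_equal(f1$truth$steps$mo2, f0$truth$steps$mo2)
  expect_equal(f1$mass, f0$mass)
  expect_equal(nrow(f1$trace), nrow(f0$trace))
  expect_equal(f1$trace$o2_airsat_pct, f0$trace$o2_airsat_pct,
               tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
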