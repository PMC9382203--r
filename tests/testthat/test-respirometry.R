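make_segment <- function(conc_fun, temp = 15, minutes = 3, dt = 0.1) {
  tt <- seq(0, minutes * 60, by = dt)
  conc <- conc_fun(tt / 60)
  data.frame(time_s = tt, temp_C = temp,
             o2_airsat_pct = mgL_to_airsat(conc, temp))
}

test_that("an exact linear decline is fit exactly", {
  seg <- make_segment(function(tmin) 10 - 0.5 * tmin)
  fit <- fit_slope(seg)
  expect_equal(fit$slope, -0.5, tolerance = 1e-9)
  expect_equal(fit$intercept, 10, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_true(fit$qc_pass)
})

test_that("a constant concentration is flagged, not dropped silently", {
  seg <- make_segment(function(tmin) rep(8, length(tmin)))
  fit <- fit_slope(seg)
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_true(is.na(fit$r_squared))
  expect_false(fit$qc_pass)
})

test_that("fit_slope equals the closed-form normal-equations solution", {
  set.seed(21)
  for (i in 1:5) {
    seg <- make_segment(function(tmin) 9 - 0.3 * tmin + rnorm(length(tmin), 0, 0.02),
                        temp = 10 + 3 * i)
    fit <- fit_slope(seg)
    conc <- airsat_to_mgL(seg$o2_airsat_pct, seg$temp_C)
    tmin <- (seg$time_s - seg$time_s[1]) / 60
    slope_ne <- sum((tmin - mean(tmin)) * (conc - mean(conc))) /
      sum((tmin - mean(tmin))^2)
    expect_equal(fit$slope, slope_ne, tolerance = 1e-12)
    expect_equal(fit$intercept, mean(conc) - slope_ne * mean(tmin),
                 tolerance = 1e-12)
  }
})

test_that("background interpolation and sign convention are locked", {
  bg <- background_model(0.02, -0.01, temp_start = 10, temp_end = 26)
  expect_equal(bg_predict(bg, 10), 0.02)
  expect_equal(bg_predict(bg, 26), -0.01)
  expect_equal(bg_predict(bg, 18), 0.005)
  raw <- data.frame(slope = -0.100, mean_temp = 18)
  # a positive background steepens the fish-attributed decline
  expect_equal(background_correct(raw, bg), -0.105)
  # zero background is the identity
  bg0 <- background_model(0, 0, temp_start = 10, temp_end = 26)
  expect_equal(background_correct(raw, bg0), raw$slope)
})

test_that("slope-to-MO2 conversion uses the effective volume", {
  expect_equal(compute_mo2(-10 / 60, mass = 1, volume = 10), 90)
  expect_equal(compute_mo2(0, mass = 1, volume = 10), 0)
  expect_error(compute_mo2(-0.1, mass = 10, volume = 10), "effective volume")
})

test_that("routine MO2 averages QC-passing cycles and warns when none pass", {
  expect_equal(routine_mo2(c(90, 100, 110))$mo2_rou, 100)
  one <- routine_mo2(c(90, 100, 110), c(FALSE, TRUE, FALSE))
  expect_equal(one$mo2_rou, 100)
  expect_equal(one$n_used, 1L)
  expect_warning(none <- routine_mo2(c(90, 100), c(FALSE, FALSE)), "missing")
  expect_true(is.na(none$mo2_rou))
})

test_that("the maximum routine value breaks ties toward higher temperature", {
  s <- data.frame(step_temp = c(20, 22, 24), mo2_rou = c(100, 150, 200))
  expect_equal(max_routine_mo2(s)$max_step, 24)
  s1 <- data.frame(step_temp = 22, mo2_rou = 150)
  expect_equal(max_routine_mo2(s1)$max_mo2, 150)
  tie <- data.frame(step_temp = c(22, 24), mo2_rou = c(150, 150))
  expect_equal(max_routine_mo2(tie)$max_step, 24)
})

test_that("lowering the QC threshold never loses passing cycles", {
  set.seed(33)
  cfg <- noisy_config(seed = 33)
  co <- generate_cohort(cfg)
  f <- co$fish$fish01_normoxia
  segs <- segment_cycles(f$trace, f$events,
                         steps = c(10, cfg$protocol$step_targets))
  thresholds <- c(0.999, 0.99, 0.95, 0.8, 0)
  passing <- vapply(thresholds, function(th)
    sum(vapply(segs, function(s) fit_slope(s, r2_min = th)$qc_pass, logical(1))),
    integer(1))
  expect_true(all(diff(passing) >= 0))
})

test_that("segmentation matches the logged cycle structure", {
  cfg <- quiet_config()
  co <- generate_cohort(cfg)
  f <- co$fish$fish01_normoxia
  segs <- segment_cycles(f$trace, f$events,
                         steps = c(10, cfg$protocol$step_targets))
  n_plateaus_completed <- length(unique(vapply(segs, attr, numeric(1), "step_temp")))
  expect_equal(length(segs),
               cfg$protocol$cycles_per_plateau * n_plateaus_completed)
  expect_equal(length(segment_cycles(f$trace,
                                     f$events[f$events$event == "blood_sample", ])),
               0)
  bad <- f$events[f$events$event != "closed_end", ]
  expect_error(segment_cycles(f$trace, bad), "unmatched")
})

test_that("a zero-noise cohort is recovered to better than 0.5% at every step", {
  cfg <- quiet_config()
  co <- generate_cohort(cfg)
  for (f in co$fish) {
    res <- analyze_one(f, cfg)$resp
    truth <- f$truth$steps$mo2[match(res$summary$step_temp,
                                     f$truth$steps$step_temp)]
    expect_true(all(abs(res$summary$mo2_rou / truth - 1) < 0.005))
    expect_true(all(res$records$qc_pass))
  }
})
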