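# Intermittent stop-flow respirometry: closed-phase O2 declines are fit by
# ordinary least squares in concentration units, corrected for a
# temperature-interpolated background slope, and converted to mass-specific
# oxygen uptake. Routine values at each temperature step are the mean of the
# (QC-passing) cycles run there.

#' Segment closed measurement cycles from a trace
#'
#' Pairs `closed_start` / `closed_end` events and extracts the samples of
#' each sealed phase, labelling each cycle with the nearest protocol
#' temperature step (by mean of its temperature channel).
#'
#' @param trace Data frame with at least `time_s`, `temp_C`,
#'   `o2_airsat_pct`.
#' @param events Event-log data frame (`time_s`, `event`).
#' @param steps Optional vector of protocol step temperatures used for
#'   labelling; when `NULL`, cycle temperatures are rounded to the nearest
#'   integer degC.
#' @return A list of closed-phase segments; each element is the sample data
#'   frame with attributes `step_temp` and `cycle`.
#' @export
segment_cycles <- function(trace, events, steps = NULL) {
  st <- events$time_s[events$event == "closed_start"]
  en <- events$time_s[events$event == "closed_end"]
  if (length(st) != length(en)) stop("unmatched closed_start/closed_end events")
  if (length(st) == 0) return(list())
  st <- sort(st); en <- sort(en)
  if (any(en <= st)) stop("closed_end precedes closed_start")
  segs <- vector("list", length(st))
  labels <- numeric(length(st))
  for (k in seq_along(st)) {
    seg <- trace[trace$time_s >= st[k] & trace$time_s <= en[k], , drop = FALSE]
    if (nrow(seg) < 10) stop(sprintf("closed segment %d has fewer than 10 samples", k))
    mt <- mean(seg$temp_C)
    labels[k] <- if (is.null(steps)) round(mt) else steps[which.min(abs(steps - mt))]
    segs[[k]] <- seg
  }
  for (k in seq_along(segs)) {
    attr(segs[[k]], "step_temp") <- labels[k]
    attr(segs[[k]], "cycle") <- sum(labels[seq_len(k)] == labels[k])
  }
  segs
}

#' Fit the linear O2 decline of one closed segment
#'
#' Converts the O2 channel to mg/L via the freshwater solubility curve and
#' fits concentration against time (minutes) by ordinary least squares.
#' The QC flag requires the fit's R-squared to reach `r2_min`; a slope is
#' never dropped here, only flagged.
#'
#' @param segment One element of [segment_cycles()] (or any data frame with
#'   `time_s`, `temp_C`, `o2_airsat_pct`).
#' @param r2_min QC threshold on R-squared (default 0.95).
#' @return A one-row data frame: `slope` (mg O2 L-1 min-1), `intercept`,
#'   `r_squared`, `n_points`, `mean_temp`, `qc_pass`. A constant-concentration
#'   segment yields slope 0, `r_squared` NA and `qc_pass` FALSE.
#' @export
fit_slope <- function(segment, r2_min = 0.95) {
  if (nrow(segment) < 3) stop("need at least 3 samples to fit a slope")
  conc <- airsat_to_mgL(segment$o2_airsat_pct, segment$temp_C)
  tmin <- (segment$time_s - segment$time_s[1]) / 60
  if (stats::var(tmin) == 0) stop("degenerate time axis in segment")
  fit <- stats::lm(conc ~ tmin)
  cf <- stats::coef(fit)
  sst <- sum((conc - mean(conc))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(stats::residuals(fit)^2) / sst
  data.frame(slope = unname(cf[2]), intercept = unname(cf[1]),
             r_squared = r2, n_points = nrow(segment),
             mean_temp = mean(segment$temp_C),
             qc_pass = isTRUE(r2 >= r2_min),
             step_temp = if (!is.null(attr(segment, "step_temp")))
               attr(segment, "step_temp") else NA_real_,
             cycle = if (!is.null(attr(segment, "cycle")))
               attr(segment, "cycle") else NA_integer_)
}

#' Linear background-respiration model
#'
#' Background O2 flux in the chamber (microbial / sensor / thermal
#' artefacts) interpolated linearly in temperature between the slope measured
#' at the start of the protocol and the slope measured at the CTmax
#' temperature. Evaluates exactly to the two anchors at their temperatures.
#'
#' @param slope_start Background slope at `temp_start`, mg O2 L-1 min-1
#'   (positive = apparent O2 gain in the sealed chamber).
#' @param slope_end Background slope at `temp_end`.
#' @param temp_start,temp_end Anchor temperatures, degC (start of protocol
#'   and CTmax temperature).
#' @return An object of class `background_model`.
#' @export
background_model <- function(slope_start, slope_end, temp_start = 10, temp_end) {
  if (temp_end == temp_start) stop("anchor temperatures must differ")
  b <- (slope_end - slope_start) / (temp_end - temp_start)
  structure(list(slope_start = slope_start, slope_end = slope_end,
                 temp_start = temp_start, temp_end = temp_end,
                 intercept = slope_start - b * temp_start, per_degC = b),
            class = "background_model")
}

#' Evaluate a background model at a temperature
#'
#' @param bg A [background_model()].
#' @param temp_C Temperature(s), degC.
#' @return Background slope(s) in mg O2 L-1 min-1.
#' @export
bg_predict <- function(bg, temp_C) {
  bg$intercept + bg$per_degC * temp_C
}

#' Background-correct a measured slope
#'
#' The fish-attributable decline is the measured closed-phase slope minus the
#' background slope at the cycle's mean temperature:
#' `corrected = raw - bg(T)`. A positive background (apparent O2 gain)
#' therefore steepens the fish-attributed decline, and a negative background
#' shallows it.
#'
#' @param raw A [fit_slope()] row (or any list with `slope` and `mean_temp`).
#' @param bg A [background_model()].
#' @return The corrected slope, mg O2 L-1 min-1.
#' @export
background_correct <- function(raw, bg) {
  raw$slope - bg_predict(bg, raw$mean_temp)
}

#' Convert a corrected slope to mass-specific oxygen uptake
#'
#' `mo2 = -slope * 60 * (V - mass / 1.0) / mass`, with the fish's displaced
#' volume at a density of 1 kg/L. Negative results (slope upward after
#' correction) are returned as-is so callers can flag them; nothing is
#' clipped.
#'
#' @param corrected_slope Corrected slope, mg O2 L-1 min-1.
#' @param mass Fish mass, kg.
#' @param volume Respirometer volume, litres.
#' @return Oxygen uptake in mg O2 kg-1 h-1.
#' @export
compute_mo2 <- function(corrected_slope, mass, volume) {
  veff <- volume - mass / 1.0
  if (veff <= 0) stop("non-positive effective volume: fish larger than respirometer")
  (-corrected_slope) * 60 * veff / mass
}

#' Routine oxygen uptake at one temperature step
#'
#' The mean of the QC-passing measurement cycles at a step.
#'
#' @param mo2 Vector of per-cycle oxygen uptake values at one step.
#' @param qc_pass Logical vector of per-cycle QC flags.
#' @return A list with `mo2_rou` (NA with a warning when no cycle passes QC)
#'   and `n_used`.
#' @export
routine_mo2 <- function(mo2, qc_pass = rep(TRUE, length(mo2))) {
  use <- qc_pass & is.finite(mo2)
  if (!any(use)) {
    warning("no QC-passing cycles at this step; routine MO2 is missing")
    return(list(mo2_rou = NA_real_, n_used = 0L))
  }
  list(mo2_rou = mean(mo2[use]), n_used = sum(use))
}

#' Maximal routine oxygen uptake over the ramp
#'
#' The highest per-step routine value and the step where it occurred. Ties
#' are broken toward the higher temperature.
#'
#' @param step_summary Data frame with `step_temp` and `mo2_rou`.
#' @return A list with `max_mo2` and `max_step` (degC).
#' @export
max_routine_mo2 <- function(step_summary) {
  ok <- is.finite(step_summary$mo2_rou)
  if (!any(ok)) stop("no routine MO2 values available")
  s <- step_summary[ok, , drop = FALSE]
  s <- s[order(s$step_temp), , drop = FALSE]
  best <- which(s$mo2_rou == max(s$mo2_rou))
  i <- best[length(best)]  # ties -> higher temperature
  list(max_mo2 = s$mo2_rou[i], max_step = s$step_temp[i])
}

#' Run the respirometry stage for one fish
#'
#' Segments closed cycles, fits and background-corrects every slope, converts
#' to mass-specific oxygen uptake, and summarises routine and maximal values
#' per temperature step.
#'
#' @param trace,events Trace and event-log data frames (synthetic-cohort
#'   dialect: `time_s`, `temp_C`, `o2_airsat_pct`).
#' @param mass Fish mass, kg.
#' @param volume Respirometer volume, litres.
#' @param bg A [background_model()].
#' @param steps Optional protocol step temperatures for labelling.
#' @param r2_min QC threshold on the slope R-squared.
#' @return A list: `records` (one row per cycle), `summary` (one row per
#'   step with `mo2_rou`, `n_used`, `is_max`), `max_mo2`, `max_step`.
#' @export
analyze_respirometry <- function(trace, events, mass, volume, bg,
                                 steps = NULL, r2_min = 0.95) {
  segs <- segment_cycles(trace, events, steps)
  if (length(segs) == 0) stop("no closed cycles found in event log")
  recs <- do.call(rbind, lapply(segs, fit_slope, r2_min = r2_min))
  recs$slope_corrected <- vapply(seq_len(nrow(recs)), function(i)
    background_correct(recs[i, ], bg), numeric(1))
  recs$mo2 <- compute_mo2(recs$slope_corrected, mass, volume)
  recs$anomalous <- recs$mo2 < 0
  steps_seen <- unique(recs$step_temp)
  summ <- do.call(rbind, lapply(steps_seen, function(s) {
    r <- recs[recs$step_temp == s, ]
    rou <- routine_mo2(r$mo2, r$qc_pass)
    data.frame(step_temp = s, mo2_rou = rou$mo2_rou, n_used = rou$n_used,
               mean_temp = mean(r$mean_temp))
  }))
  summ <- summ[order(summ$step_temp), , drop = FALSE]
  mx <- max_routine_mo2(summ)
  summ$is_max <- summ$step_temp == mx$max_step
  list(records = recs, summary = summ,
       max_mo2 = mx$max_mo2, max_step = mx$max_step)
}
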