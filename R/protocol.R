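# The step-wise thermal ramping protocol: linear ramps between target
# temperatures with flat measurement plateaus, and the intermittent stop-flow
# cycle schedule (closed measurement phases interleaved with flushing) run on
# each plateau.

#' Define a thermal ramping protocol
#'
#' Step-wise warming from `start_temp` through `step_targets`, ramping at
#' `rate_fast` (degC/h) up to `rate_switch_temp` and `rate_slow` beyond it.
#' Each target (and the start temperature) carries a flat measurement plateau
#' during which `cycles_per_plateau` closed respirometry cycles are run,
#' interleaved with flushing periods (closed-flush-...-closed inside the
#' plateau).
#'
#' @param start_temp Starting (acclimation) temperature, degC.
#' @param step_targets Strictly increasing vector of plateau temperatures, degC.
#' @param rate_fast Ramp rate up to `rate_switch_temp`, degC per hour.
#' @param rate_slow Ramp rate above `rate_switch_temp`, degC per hour.
#' @param rate_switch_temp Temperature at which the ramp slows, degC.
#' @param plateau_duration Plateau length, minutes.
#' @param cycles_per_plateau Closed measurement cycles per plateau.
#' @param closed_phase Closed (sealed) phase duration, minutes; must lie in
#'   \[2, 5\].
#' @param flush_phase Flushing duration between closed phases, minutes; must
#'   lie in \[5, 8\].
#' @param blood_sample_temps Plateau temperatures at which a venous blood
#'   sample is drawn (a final sample is always taken at CTmax).
#' @return An object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(start_temp = 10,
                          step_targets = c(15, 20, 22:30),
                          rate_fast = 5,
                          rate_slow = 2,
                          rate_switch_temp = 20,
                          plateau_duration = 20,
                          cycles_per_plateau = 3,
                          closed_phase = 3,
                          flush_phase = 5.5,
                          blood_sample_temps = c(10, 20, 24, 26)) {
  if (any(diff(step_targets) <= 0)) stop("step_targets must be strictly increasing")
  if (step_targets[1] <= start_temp) stop("first step target must exceed start_temp")
  if (closed_phase < 2 || closed_phase > 5) stop("closed_phase must be within 2-5 min")
  if (flush_phase < 5 || flush_phase > 8) stop("flush_phase must be within 5-8 min")
  if (rate_fast <= 0 || rate_slow <= 0) stop("ramp rates must be positive")
  need <- cycles_per_plateau * closed_phase + (cycles_per_plateau - 1) * flush_phase
  if (need > plateau_duration + 1e-9) {
    stop(sprintf(
      "infeasible protocol: %d cycles of %g min closed + %g min flush need %g min but the plateau is %g min",
      cycles_per_plateau, closed_phase, flush_phase, need, plateau_duration))
  }
  structure(list(
    start_temp = start_temp,
    step_targets = step_targets,
    rate_fast = rate_fast,
    rate_slow = rate_slow,
    rate_switch_temp = rate_switch_temp,
    plateau_duration = plateau_duration,
    cycles_per_plateau = cycles_per_plateau,
    closed_phase = closed_phase,
    flush_phase = flush_phase,
    blood_sample_temps = blood_sample_temps
  ), class = "ramp_protocol")
}

#' @export
print.ramp_protocol <- function(x, ...) {
  cat("Thermal ramping protocol\n")
  cat(sprintf("  start %g degC; targets: %s degC\n", x$start_temp,
              paste(x$step_targets, collapse = ", ")))
  cat(sprintf("  rates %g degC/h (to %g degC) then %g degC/h\n",
              x$rate_fast, x$rate_switch_temp, x$rate_slow))
  cat(sprintf("  plateaus %g min with %d closed cycles (%g min closed / %g min flush)\n",
              x$plateau_duration, x$cycles_per_plateau, x$closed_phase, x$flush_phase))
  cat(sprintf("  total duration %.1f min\n", protocol_duration(x)))
  invisible(x)
}

# Piecewise segments of the protocol: one row per plateau or ramp, with times
# in minutes from protocol start. Plateau rows carry their step temperature.
protocol_segments <- function(protocol) {
  stopifnot(inherits(protocol, "ramp_protocol"))
  p <- protocol
  segs <- list()
  t0 <- 0
  cur <- p$start_temp
  add <- function(type, dur, temp0, temp1, step) {
    segs[[length(segs) + 1L]] <<- data.frame(
      type = type, t0_min = t0, t1_min = t0 + dur,
      temp0 = temp0, temp1 = temp1, step_temp = step)
    t0 <<- t0 + dur
  }
  add("plateau", p$plateau_duration, cur, cur, cur)
  for (tg in p$step_targets) {
    rate <- if (tg <= p$rate_switch_temp) p$rate_fast else p$rate_slow
    dur <- (tg - cur) / rate * 60  # zero-span segments get zero duration
    add("ramp", dur, cur, tg, NA_real_)
    cur <- tg
    add("plateau", p$plateau_duration, cur, cur, cur)
  }
  do.call(rbind, segs)
}

#' Total protocol duration in minutes
#'
#' @param protocol A [ramp_protocol()].
#' @return Duration in minutes (ramps plus all plateaus, CTmax permitting).
#' @export
protocol_duration <- function(protocol) {
  segs <- protocol_segments(protocol)
  segs$t1_min[nrow(segs)]
}

#' Generate the temperature profile of a protocol
#'
#' Samples the piecewise-linear protocol temperature on a regular grid. The
#' profile is monotone non-decreasing: flat plateaus joined by linear ramps.
#'
#' @param protocol A [ramp_protocol()].
#' @param dt Sampling interval in seconds (default 0.1 s, i.e. 10 Hz).
#' @return A data frame with columns `time_s` and `temp_C`.
#' @export
generate_temperature_profile <- function(protocol, dt = 0.1) {
  if (dt <= 0) stop("dt must be positive")
  segs <- protocol_segments(protocol)
  keep <- segs$t1_min > segs$t0_min
  segs <- segs[keep, , drop = FALSE]
  breaks_s <- c(segs$t0_min[1], segs$t1_min) * 60
  temps <- c(segs$temp0[1], segs$temp1)
  tgrid <- seq(0, breaks_s[length(breaks_s)], by = dt)
  temp <- stats::approx(breaks_s, temps, xout = tgrid, rule = 2)$y
  data.frame(time_s = tgrid, temp_C = temp)
}

# Closed/flush cycle schedule over all plateaus. Returns one row per closed
# cycle: step temperature, cycle index within the plateau, closed start/end
# and the following flush window (NA after the last cycle of a plateau), all
# in seconds. Blood-sample draw times sit at the end of the plateau for the
# temperatures named in the protocol.
cycle_schedule <- function(protocol) {
  p <- protocol
  segs <- protocol_segments(p)
  plats <- segs[segs$type == "plateau", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(plats))) {
    p0 <- plats$t0_min[i] * 60
    for (k in seq_len(p$cycles_per_plateau)) {
      c0 <- p0 + (k - 1) * (p$closed_phase + p$flush_phase) * 60
      c1 <- c0 + p$closed_phase * 60
      last <- k == p$cycles_per_plateau
      out[[length(out) + 1L]] <- data.frame(
        step_temp = plats$step_temp[i], cycle = k,
        closed_start_s = c0, closed_end_s = c1,
        flush_start_s = if (last) NA_real_ else c1,
        flush_end_s = if (last) NA_real_ else c1 + p$flush_phase * 60,
        plateau_end_s = plats$t1_min[i] * 60)
    }
  }
  do.call(rbind, out)
}

# Blood sampling times: end of the measurement block at each named plateau.
blood_sample_schedule <- function(protocol) {
  sch <- cycle_schedule(protocol)
  per_plat <- sch[!duplicated(sch$step_temp), c("step_temp", "plateau_end_s")]
  per_plat <- per_plat[per_plat$step_temp %in% protocol$blood_sample_temps, , drop = FALSE]
  # draw right at the end of the last closed cycle of the plateau
  last_cycle <- sch[sch$cycle == protocol$cycles_per_plateau, ]
  idx <- match(per_plat$step_temp, last_cycle$step_temp)
  data.frame(step_temp = per_plat$step_temp, time_s = last_cycle$closed_end_s[idx])
}
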