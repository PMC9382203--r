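# Cardiac variables from the pulsatile ventral-aortic flow trace. Heart rate
# comes from peak detection on the pulse train; cardiac output is the
# time-mean flow normalised to body mass; stroke volume is their quotient;
# and the arteriovenous O2 content difference is estimated from the tied
# oxygen-uptake measurement via the Fick principle.

#' Detect heart beats in a flow window
#'
#' Local-maximum detection with a minimum height (a fraction of the window's
#' amplitude range above its minimum) and a refractory period. By default the
#' refractory period is `60 / (2.5 * running HR estimate)` seconds, with the
#' running estimate taken from the median inter-candidate interval.
#' Candidates are accepted greedily in order of decreasing amplitude.
#'
#' @param time_s Sample times, seconds (strictly increasing).
#' @param flow Flow samples, ml/min.
#' @param prominence_frac Minimum peak height as a fraction of the window
#'   amplitude range (default 0.3).
#' @param refractory Refractory period in seconds, or `NULL` for the default.
#' @param min_window Minimum window span accepted, seconds.
#' @return Strictly increasing beat times, seconds.
#' @export
detect_beats <- function(time_s, flow, prominence_frac = 0.3,
                         refractory = NULL, min_window = 30) {
  n <- length(flow)
  if (n < 3) stop("window too short for beat detection")
  if (time_s[n] - time_s[1] < min_window) {
    stop(sprintf("beat-detection window must span at least %g s", min_window))
  }
  rng <- max(flow) - min(flow)
  if (!is.finite(rng) || rng <= 0) stop("flat or zero-amplitude flow signal: no beats")
  loc <- which(flow[2:(n - 1)] >= flow[1:(n - 2)] & flow[2:(n - 1)] > flow[3:n]) + 1L
  thr <- min(flow) + prominence_frac * rng
  loc <- loc[flow[loc] >= thr]
  if (length(loc) == 0) stop("no beats detected above the prominence threshold")
  if (is.null(refractory)) {
    refractory <- if (length(loc) < 2) 0 else
      stats::median(diff(time_s[loc])) / 2.5
  }
  ord <- loc[order(flow[loc], decreasing = TRUE)]
  accepted <- numeric(0)
  for (i in ord) {
    ti <- time_s[i]
    if (length(accepted) == 0 || all(abs(accepted - ti) > refractory)) {
      accepted <- c(accepted, ti)
    }
  }
  sort(accepted)
}

#' Heart rate from beat times
#'
#' `60 * (n_beats - 1) / (t_last - t_first)` beats per minute: the first-to-
#' last-beat span estimator, which is unbiased for partial windows.
#'
#' @param beat_times Beat times, seconds (at least 2).
#' @return Heart rate, beats min-1.
#' @export
heart_rate <- function(beat_times) {
  n <- length(beat_times)
  if (n < 2) stop("need at least 2 beats to estimate heart rate")
  60 * (n - 1) / (beat_times[n] - beat_times[1])
}

#' Mass-specific cardiac output of a flow window
#'
#' Time-mean of the flow channel divided by body mass.
#'
#' @param flow Flow samples over the window, ml/min.
#' @param mass Body mass, kg.
#' @return Cardiac output, ml min-1 kg-1.
#' @export
cardiac_output <- function(flow, mass) {
  if (length(flow) == 0) stop("empty flow window")
  mean(flow) / mass
}

#' Stroke volume from cardiac output and heart rate
#'
#' @param co Cardiac output, ml min-1 kg-1.
#' @param hr Heart rate, beats min-1.
#' @return Stroke volume, ml beat-1 kg-1. Multiply by body mass for the
#'   absolute (ml beat-1) form.
#' @export
stroke_volume <- function(co, hr) {
  if (any(hr <= 0)) stop("heart rate must be positive")
  co / hr
}

#' Fick-estimated arteriovenous O2 content difference
#'
#' Rearranging the Fick principle, the tissue O2 extraction is the oxygen
#' uptake divided by cardiac output: `avo2 = mo2 / (co * 60)` with `mo2` in
#' mg O2 kg-1 h-1 and `co` in ml min-1 kg-1, giving mg O2 per ml of blood.
#' Mass terms cancel.
#'
#' @param mo2 Oxygen uptake, mg O2 kg-1 h-1.
#' @param co Cardiac output, ml min-1 kg-1.
#' @return A-V O2 content difference, mg O2 ml-1.
#' @export
fick_avo2 <- function(mo2, co) {
  if (any(co <= 0)) stop("cardiac output must be positive")
  mo2 / (co * 60)
}

#' Tie cardiac windows to the oxygen-uptake measurement cycles
#'
#' Routine cardiac values at each temperature step are the mean over the same
#' closed-cycle intervals used for the routine oxygen uptake; the "maximal"
#' window is the step where the maximal routine oxygen uptake occurred (even
#' if cardiac output is numerically higher elsewhere). Cycles whose flow
#' coverage is incomplete are flagged and excluded from the means.
#'
#' @param trace Trace data frame with `time_s` and `flow_mL_min`.
#' @param events Event-log data frame.
#' @param mass Body mass, kg.
#' @param respiro Result of [analyze_respirometry()] for the same fish.
#' @param steps Optional protocol step temperatures for labelling.
#' @return Data frame with one row per step: `step_temp`, `n_cycles`,
#'   `heart_rate`, `cardiac_output`, `stroke_volume`, `avo2`, `tied_mo2`,
#'   `is_max_window`, `incomplete`.
#' @export
tie_windows <- function(trace, events, mass, respiro, steps = NULL) {
  segs <- segment_cycles(trace, events, steps)
  if (length(segs) == 0) stop("no cycle intervals available from the event log")
  dt <- stats::median(diff(trace$time_s))
  lab <- vapply(segs, attr, numeric(1), "step_temp")
  out <- lapply(sort(unique(lab)), function(s) {
    hrs <- cos <- numeric(0)
    inc <- FALSE
    for (seg in segs[lab == s]) {
      span <- seg$time_s[nrow(seg)] - seg$time_s[1]
      if (nrow(seg) < 0.9 * span / dt) {
        inc <- TRUE
        next
      }
      beats <- detect_beats(seg$time_s, seg$flow_mL_min)
      hrs <- c(hrs, heart_rate(beats))
      cos <- c(cos, cardiac_output(seg$flow_mL_min, mass))
    }
    if (length(hrs) == 0) {
      return(data.frame(step_temp = s, n_cycles = 0L, heart_rate = NA_real_,
                        cardiac_output = NA_real_, stroke_volume = NA_real_,
                        avo2 = NA_real_, tied_mo2 = NA_real_,
                        is_max_window = FALSE, incomplete = TRUE))
    }
    hr <- mean(hrs)
    co <- mean(cos)
    i <- match(s, respiro$summary$step_temp)
    mo2 <- if (is.na(i)) NA_real_ else respiro$summary$mo2_rou[i]
    data.frame(step_temp = s, n_cycles = length(hrs), heart_rate = hr,
               cardiac_output = co, stroke_volume = stroke_volume(co, hr),
               avo2 = if (is.finite(mo2)) fick_avo2(mo2, co) else NA_real_,
               tied_mo2 = mo2,
               is_max_window = isTRUE(s == respiro$max_step),
               incomplete = inc)
  })
  do.call(rbind, out)
}

#' Run the cardiac stage for one fish
#'
#' Thin wrapper over [tie_windows()] that also pulls out the max-window row.
#'
#' @inheritParams tie_windows
#' @return A list: `windows` (per-step data frame) and `at_max` (the row tied
#'   to the maximal routine oxygen uptake).
#' @export
analyze_cardio <- function(trace, events, mass, respiro, steps = NULL) {
  w <- tie_windows(trace, events, mass, respiro, steps)
  list(windows = w, at_max = w[w$is_max_window, , drop = FALSE])
}
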