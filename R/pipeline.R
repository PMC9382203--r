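# Orchestration: simulate (or load) a cohort, run the respirometry and
# cardiac stages per fish, run the group statistics, CTmax comparison and
# literature synthesis, and write a reproducible report (JSON + markdown)
# whose every number comes from a stage output.

#' Run the full thermal-ramping analysis pipeline
#'
#' Simulates a synthetic cohort (or analyses one supplied / read from disk),
#' then runs each enabled stage and assembles a report. All randomness is
#' governed by the cohort config's seed, so a re-run of the same config is
#' identical.
#'
#' @param config A [cohort_config()]. Ignored when `cohort` is given.
#' @param cohort Optional pre-generated [generate_cohort()] result (or a
#'   [read_cohort()] result).
#' @param stages Character vector of stages to run, from
#'   `c("respirometry", "cardio", "stats", "tolerance", "meta")`. Disabled
#'   stages are marked "skipped" in the report.
#' @param output_dir Optional directory for the report (and, when simulating
#'   with a configured `output_dir`, the raw trial files).
#' @param r2_min QC threshold for respirometry slope fits.
#' @param literature_path Optional path to a literature table CSV (defaults
#'   to the packaged table).
#' @param anova_max_temp Repeated-measures analyses are restricted to steps
#'   at or below this temperature (the range all fish complete; default 25).
#' @return A `thermoramp_report` list; see [write_report()].
#' @export
run_pipeline <- function(config = cohort_config(),
                         cohort = NULL,
                         stages = c("respirometry", "cardio", "stats",
                                    "tolerance", "meta"),
                         output_dir = NULL,
                         r2_min = 0.95,
                         literature_path = NULL,
                         anova_max_temp = 25) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(cohort)) cohort <- generate_cohort(config)
  cfg <- cohort$config
  volume <- cfg$respirometer_volume
  steps_known <- if (inherits(cfg$protocol, "ramp_protocol")) {
    c(cfg$protocol$start_temp, cfg$protocol$step_targets)
  } else NULL

  skipped <- function(name) !(name %in% stages)
  report <- list(meta = list(
    package = "thermoramp",
    seed = if (!is.null(cfg$seed)) cfg$seed else NA,
    n_fish = length(cohort$fish),
    stages = stats::setNames(
      as.list(ifelse(c("respirometry", "cardio", "stats", "tolerance", "meta")
                     %in% stages, "run", "skipped")),
      c("respirometry", "cardio", "stats", "tolerance", "meta"))))

  # ---- per-fish stages -----------------------------------------------------
  fish_rows <- NULL
  per_fish <- list()
  if (!skipped("respirometry")) {
    for (f in cohort$fish) {
      bg <- background_model(f$truth$bg_slope_start, f$truth$bg_slope_end,
                             10, f$truth$ctmax_C)
      resp <- tryCatch(
        analyze_respirometry(f$trace, f$events, f$mass, volume, bg,
                             steps = steps_known, r2_min = r2_min),
        error = function(e) stop("respirometry stage failed for ", f$id,
                                 ": ", conditionMessage(e)))
      card <- NULL
      if (!skipped("cardio")) {
        card <- tryCatch(
          analyze_cardio(f$trace, f$events, f$mass, resp, steps = steps_known),
          error = function(e) stop("cardio stage failed for ", f$id, ": ",
                                   conditionMessage(e)))
      }
      # detected CTmax: temperature at the logged loss-of-equilibrium event
      t_loe <- f$events$time_s[f$events$event == "loss_of_equilibrium"]
      ct <- if (length(t_loe)) {
        f$trace$temp_C[which.min(abs(f$trace$time_s - t_loe[1]))]
      } else NA_real_
      amax <- if (!is.null(card) && nrow(card$at_max)) card$at_max else NULL
      fish_rows <- rbind(fish_rows, data.frame(
        id = f$id, treatment = f$treatment, mass_kg = f$mass,
        ctmax_C = ct, max_mo2 = resp$max_mo2, max_step = resp$max_step,
        hr_max = if (!is.null(amax)) amax$heart_rate else NA_real_,
        co_max = if (!is.null(amax)) amax$cardiac_output else NA_real_,
        sv_max = if (!is.null(amax)) amax$stroke_volume else NA_real_,
        avo2_max = if (!is.null(amax)) amax$avo2 else NA_real_))
      per_fish[[f$id]] <- list(respirometry = resp, cardio = card)
    }
    report$fish <- fish_rows
  }

  grp <- function(v, tr) v[fish_rows$treatment == tr]
  msem <- function(v) list(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
                           n = length(v))

  if (!is.null(fish_rows)) {
    gs <- list()
    for (tr in c("normoxia", "hyperoxia")) {
      gs[[tr]] <- list(
        n = sum(fish_rows$treatment == tr),
        max_mo2 = msem(grp(fish_rows$max_mo2, tr)),
        temp_of_max = msem(grp(fish_rows$max_step, tr)),
        ctmax = c(msem(grp(fish_rows$ctmax_C, tr)),
                  list(median = stats::median(grp(fish_rows$ctmax_C, tr)))))
      if (!skipped("cardio")) {
        gs[[tr]]$co_at_max <- msem(grp(fish_rows$co_max, tr))
        gs[[tr]]$sv_at_max <- msem(grp(fish_rows$sv_max, tr))
        gs[[tr]]$hr_at_max <- msem(grp(fish_rows$hr_max, tr))
        gs[[tr]]$avo2_at_max <- msem(grp(fish_rows$avo2_max, tr))
      }
    }
    report$groups <- gs
    ctr <- list(max_mo2_pct = percent_difference(gs$normoxia$max_mo2$mean,
                                                 gs$hyperoxia$max_mo2$mean))
    if (!skipped("cardio")) {
      ctr$co_pct <- percent_difference(gs$normoxia$co_at_max$mean,
                                       gs$hyperoxia$co_at_max$mean)
      ctr$sv_pct <- percent_difference(gs$normoxia$sv_at_max$mean,
                                       gs$hyperoxia$sv_at_max$mean)
      ctr$hr_pct <- percent_difference(gs$normoxia$hr_at_max$mean,
                                       gs$hyperoxia$hr_at_max$mean)
      ctr$avo2_pct <- percent_difference(gs$normoxia$avo2_at_max$mean,
                                         gs$hyperoxia$avo2_at_max$mean)
    }
    report$contrasts <- ctr
  }

  # ---- statistics stage ----------------------------------------------------
  if (!skipped("stats") && !is.null(fish_rows)) {
    long <- do.call(rbind, lapply(cohort$fish, function(f) {
      s <- per_fish[[f$id]]$respirometry$summary
      s <- s[s$step_temp <= anova_max_temp & is.finite(s$mo2_rou), ]
      if (!nrow(s)) return(NULL)
      data.frame(subject = f$id, group = f$treatment,
                 level = s$step_temp, value = ln_transform(s$mo2_rou))
    }))
    report$anova_mo2 <- mixed_anova(long)

    pw <- list()
    add_t <- function(name, v, log = TRUE) {
      x <- grp(v, "normoxia"); y <- grp(v, "hyperoxia")
      if (log) { x <- ln_transform(x); y <- ln_transform(y) }
      tt <- t_test_independent(x, y)
      pw[[length(pw) + 1L]] <<- data.frame(
        variable = name, test = if (log) "welch_t_ln" else "welch_t",
        statistic = tt$t, p_value = tt$p_value)
    }
    add_mw <- function(name, v) {
      mw <- mann_whitney(grp(v, "normoxia"), grp(v, "hyperoxia"))
      pw[[length(pw) + 1L]] <<- data.frame(
        variable = name, test = paste0("mann_whitney_", mw$method),
        statistic = mw$U, p_value = mw$p_value)
    }
    add_t("max_mo2", fish_rows$max_mo2)
    if (!skipped("cardio")) {
      add_t("co_at_max", fish_rows$co_max, log = FALSE)
      add_t("sv_at_max", fish_rows$sv_max)
      add_t("avo2_at_max", fish_rows$avo2_max)
      add_mw("hr_at_max", fish_rows$hr_max)
    }
    report$pairwise <- do.call(rbind, pw)

    # lactate at 26 degC: pre-CTmax step samples pooled with at-CTmax draws
    # from fish that lost equilibrium during the 26 degC step
    lac <- do.call(rbind, lapply(cohort$fish, function(f) {
      b <- f$blood
      ct <- f$ctmax_C
      row <- NULL
      if (!is.null(ct) && is.finite(ct) && ct >= 26 && ct < 27 &&
          any(b$at_ctmax)) {
        row <- b[b$at_ctmax, ][1, ]
      } else if (any(!is.na(b$nominal_temp_C) & b$nominal_temp_C == 26)) {
        row <- b[!is.na(b$nominal_temp_C) & b$nominal_temp_C == 26, ][1, ]
      }
      if (is.null(row)) return(NULL)
      data.frame(treatment = f$treatment, lactate_mM = row$lactate_mM,
                 at_ctmax = row$at_ctmax)
    }))
    if (!is.null(lac) && length(unique(lac$treatment)) == 2 &&
        all(table(lac$treatment) >= 2)) {
      xn <- lac$lactate_mM[lac$treatment == "normoxia"]
      xh <- lac$lactate_mM[lac$treatment == "hyperoxia"]
      tt <- t_test_independent(ln_transform(xn), ln_transform(xh))
      report$lactate_26 <- list(
        mean_normoxia = mean(xn), mean_hyperoxia = mean(xh),
        n_normoxia = length(xn), n_hyperoxia = length(xh),
        n_at_ctmax_normoxia = sum(lac$at_ctmax[lac$treatment == "normoxia"]),
        n_at_ctmax_hyperoxia = sum(lac$at_ctmax[lac$treatment == "hyperoxia"]),
        t = tt$t, p_value = tt$p_value)
    }
  } else if (skipped("stats")) {
    report$anova_mo2 <- "skipped"
    report$pairwise <- "skipped"
  }

  # ---- tolerance stage -----------------------------------------------------
  if (!skipped("tolerance") && !is.null(fish_rows)) {
    cc <- compare_ctmax(grp(fish_rows$ctmax_C, "normoxia"),
                        grp(fish_rows$ctmax_C, "hyperoxia"))
    report$ctmax <- list(
      mean_normoxia = cc$mean_a, mean_hyperoxia = cc$mean_b,
      median_normoxia = cc$median_a, median_hyperoxia = cc$median_b,
      mean_diff = cc$mean_diff, median_diff = cc$median_diff,
      mw_U = cc$mw$U, mw_p = cc$mw$p_value, mw_method = cc$mw$method)
  } else if (skipped("tolerance")) {
    report$ctmax <- "skipped"
  }

  # ---- literature meta stage ----------------------------------------------
  if (!skipped("meta")) {
    lit <- load_literature(literature_path)
    report$literature <- prevalence_summary(species_aggregate(lit))
  } else {
    report$literature <- "skipped"
  }

  report <- structure(report, class = "thermoramp_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

fmt_num <- function(x) {
  if (is.character(x)) return(x)
  format(x, digits = 12, trim = TRUE, scientific = FALSE)
}

#' Render a pipeline report as markdown
#'
#' Every numeric line in the markdown mirrors a field of the report list (and
#' hence of `report.json`), so the two are losslessly interconvertible.
#'
#' @param report A `thermoramp_report` (or the list read back from its JSON).
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  ln <- character(0)
  put <- function(...) ln <<- c(ln, sprintf(...))
  put("# Thermal-ramping trial report")
  put("")
  put("- seed: %s", fmt_num(report$meta$seed))
  put("- n_fish: %s", fmt_num(report$meta$n_fish))
  for (s in names(report$meta$stages)) {
    put("- stage %s: %s", s, report$meta$stages[[s]])
  }
  if (!is.null(report$groups)) {
    put("")
    put("## Group summaries")
    for (tr in names(report$groups)) {
      g <- report$groups[[tr]]
      put("")
      put("### %s (n = %s)", tr, fmt_num(g$n))
      put("- maximal routine MO2: %s +/- %s mg O2/kg/h at %s +/- %s degC",
          fmt_num(g$max_mo2$mean), fmt_num(g$max_mo2$sem),
          fmt_num(g$temp_of_max$mean), fmt_num(g$temp_of_max$sem))
      put("- CTmax: mean %s, median %s degC",
          fmt_num(g$ctmax$mean), fmt_num(g$ctmax$median))
      if (!is.null(g$co_at_max)) {
        put("- at max MO2: CO %s ml/min/kg, SV %s ml/beat/kg, HR %s bpm, A-V O2 %s mg/ml",
            fmt_num(g$co_at_max$mean), fmt_num(g$sv_at_max$mean),
            fmt_num(g$hr_at_max$mean), fmt_num(g$avo2_at_max$mean))
      }
    }
  }
  if (!is.null(report$contrasts)) {
    put("")
    put("## Hyperoxia vs normoxia contrasts (percent)")
    for (nm in names(report$contrasts)) {
      put("- %s: %s", nm, fmt_num(report$contrasts[[nm]]))
    }
  }
  if (!is.null(report$ctmax)) {
    put("")
    put("## CTmax comparison")
    if (identical(report$ctmax, "skipped")) {
      put("- skipped")
    } else {
      put("- mean difference (hyperoxia - normoxia): %s degC",
          fmt_num(report$ctmax$mean_diff))
      put("- median difference: %s degC", fmt_num(report$ctmax$median_diff))
      put("- Mann-Whitney U = %s, p = %s (%s)", fmt_num(report$ctmax$mw_U),
          fmt_num(report$ctmax$mw_p), report$ctmax$mw_method)
    }
  }
  if (!is.null(report$lactate_26)) {
    put("")
    put("## Plasma lactate at 26 degC")
    put("- normoxia %s mM (n = %s, %s at CTmax); hyperoxia %s mM (n = %s, %s at CTmax)",
        fmt_num(report$lactate_26$mean_normoxia),
        fmt_num(report$lactate_26$n_normoxia),
        fmt_num(report$lactate_26$n_at_ctmax_normoxia),
        fmt_num(report$lactate_26$mean_hyperoxia),
        fmt_num(report$lactate_26$n_hyperoxia),
        fmt_num(report$lactate_26$n_at_ctmax_hyperoxia))
    put("- ln-scale t = %s, p = %s", fmt_num(report$lactate_26$t),
        fmt_num(report$lactate_26$p_value))
  }
  if (!is.null(report$literature)) {
    put("")
    put("## Literature synthesis")
    if (identical(report$literature, "skipped")) {
      put("- skipped")
    } else {
      l <- report$literature
      put("- species examined: %s", fmt_num(l$n_species))
      put("- significant CTmax elevation: %s species", fmt_num(l$n_significant))
      put("- counted as increased: %s species (%s%%)",
          fmt_num(l$n_increased), fmt_num(l$percent_increased))
      put("- significant improvement range: %s to %s degC",
          fmt_num(l$range_significant[[1]]), fmt_num(l$range_significant[[2]]))
    }
  }
  ln
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (full precision, machine readable) and `report.md`
#' (rendered from the same values). Errors on an empty report.
#'
#' @param report A `thermoramp_report`.
#' @param dir Output directory (created if missing).
#' @return Named paths of the two files, invisibly.
#' @export
write_report <- function(report, dir) {
  if (is.null(report) || length(report) == 0 ||
      !any(c("fish", "groups", "literature", "ctmax") %in% names(report))) {
    stop("empty report: run at least one pipeline stage first")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "columns",
                       null = "null")
  writeLines(report_markdown(report), md_path)
  invisible(c(json = json_path, markdown = md_path))
}
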