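# CTmax group comparison for a trial, plus the literature synthesis of
# hyperoxia-induced upper thermal tolerance across fishes, and an LT50
# logistic-regression utility for studies that report the temperature at
# which half the individuals become unresponsive.

#' Load the packaged literature table of hyperoxia CTmax studies
#'
#' One row per species x experimental condition collated from published
#' hyperoxia / thermal-tolerance experiments (including this package's focal
#' trout trial). `ctmax_diff_C` is CTmax in hyperoxia minus CTmax in
#' normoxia; `significant` is `yes` / `no`, or `na` when the study design
#' allowed no statistical comparison. One historical condition does not state
#' its O2 level (`NA`).
#'
#' @param path Path to a CSV with the table schema; defaults to the packaged
#'   table.
#' @return A validated data frame of literature entries.
#' @export
load_literature <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "literature_table.csv",
                        package = "thermoramp", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", "ns", ""))
  need <- c("species", "ecotype", "climatic_region", "acclimation_temp_C",
            "heating_rate_C_per_h", "o2_level_pct_airsat", "ctmax_diff_C",
            "significant", "reference")
  problems <- character(0)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    problems <- c(problems, paste("missing columns:",
                                  paste(missing_cols, collapse = ", ")))
  } else {
    bad_sig <- !tab$significant %in% c("yes", "no", "na")
    if (any(bad_sig)) {
      problems <- c(problems, sprintf(
        "row %d: significance '%s' not one of yes/no/na",
        which(bad_sig), tab$significant[bad_sig]))
    }
    bad_o2 <- !is.na(tab$o2_level_pct_airsat) & tab$o2_level_pct_airsat <= 100
    if (any(bad_o2)) {
      problems <- c(problems, sprintf(
        "row %d: o2 level %g is not hyperoxic (> 100%% air saturation)",
        which(bad_o2), tab$o2_level_pct_airsat[bad_o2]))
    }
    if (any(!is.finite(tab$ctmax_diff_C))) {
      problems <- c(problems, "non-numeric ctmax_diff_C values")
    }
  }
  if (length(problems)) {
    stop("literature table validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  }
  tab
}

#' Aggregate literature entries to one summary per species
#'
#' `any_significant` is true when any condition for the species showed a
#' significant CTmax elevation; `increased` additionally counts species whose
#' conditions permitted no statistical test but all showed a positive CTmax
#' difference. `max_diff` is the largest difference across the species'
#' conditions.
#'
#' @param entries Data frame from [load_literature()].
#' @return One row per species: `species`, `n_conditions`, `max_diff`,
#'   `any_significant`, `increased`.
#' @export
species_aggregate <- function(entries) {
  if (nrow(entries) == 0) stop("no literature entries")
  out <- lapply(split(entries, entries$species), function(e) {
    any_sig <- any(e$significant == "yes")
    all_na <- all(e$significant == "na")
    mx <- max(e$ctmax_diff_C)
    data.frame(species = e$species[1], n_conditions = nrow(e), max_diff = mx,
               any_significant = any_sig,
               increased = any_sig || (all_na && mx > 0))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Prevalence and magnitude of hyperoxia-induced thermal tolerance
#'
#' Counts of species examined, species with a statistically significant
#' CTmax elevation, and species counted as increased (significant, or
#' untestable-but-positive), plus the range of the CTmax improvement across
#' the significant species (reported to 1 decimal, with the unrounded values
#' alongside).
#'
#' @param summaries Data frame from [species_aggregate()].
#' @return A list: `n_species`, `n_significant`, `n_increased`,
#'   `percent_increased`, `range_significant` (1-dp), `range_unrounded`.
#' @export
prevalence_summary <- function(summaries) {
  if (nrow(summaries) == 0) stop("no species summaries")
  sig <- summaries[summaries$any_significant, , drop = FALSE]
  rng <- if (nrow(sig)) range(sig$max_diff) else c(NA_real_, NA_real_)
  list(n_species = nrow(summaries),
       n_significant = sum(summaries$any_significant),
       n_increased = sum(summaries$increased),
       percent_increased = 100 * mean(summaries$increased),
       range_significant = round(rng, 1),
       range_unrounded = rng)
}

#' Compare CTmax between two groups
#'
#' Reports both the median and mean difference (`group_b - group_a`) and the
#' Mann-Whitney U test on the raw CTmax values (CTmax distributions are
#' typically non-normal).
#'
#' @param group_a,group_b CTmax values, degC (>= 2 per group). Conventionally
#'   `group_a` = normoxia, `group_b` = hyperoxia, so positive differences
#'   mean higher tolerance in hyperoxia.
#' @return A list: `median_diff`, `mean_diff`, `median_a`, `median_b`,
#'   `mean_a`, `mean_b`, `mw` (a [mann_whitney()] result for b vs a).
#' @export
compare_ctmax <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least 2 CTmax values per group")
  }
  list(median_diff = stats::median(group_b) - stats::median(group_a),
       mean_diff = mean(group_b) - mean(group_a),
       median_a = stats::median(group_a), median_b = stats::median(group_b),
       mean_a = mean(group_a), mean_b = mean(group_b),
       mw = mann_whitney(group_b, group_a))
}

#' Fit an LT50 sigmoidal (logistic) dose-response to thermal-challenge data
#'
#' Two-parameter logistic regression of the proportion unresponsive against
#' temperature, fit by maximum likelihood (binomial GLM with logit link).
#' LT50 is the temperature of 50% response. The confidence interval is a
#' nonparametric bootstrap over individuals (resampling outcomes within each
#' temperature level); interval separation between two fits is the
#' significance criterion used by LT50-style studies.
#'
#' @param temps Temperature levels, degC (>= 3, spanning the response).
#' @param n_exposed Individuals exposed per level.
#' @param n_unresponsive Individuals unresponsive per level.
#' @param bootstrap_reps Bootstrap replicates for the CI (default 500).
#' @param seed Optional seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `lt50_fit`: `lt50`, `slope` (per degC),
#'   `ci` (bootstrap percentile interval), `n_boot`.
#' @export
lt50_fit <- function(temps, n_exposed, n_unresponsive, bootstrap_reps = 500,
                     seed = NULL, conf = 0.95) {
  if (length(temps) < 3) stop("need at least 3 temperature levels")
  if (length(n_exposed) != length(temps) ||
      length(n_unresponsive) != length(temps)) {
    stop("temps, n_exposed and n_unresponsive must have equal length")
  }
  if (any(n_unresponsive > n_exposed) || any(n_exposed <= 0)) {
    stop("0 <= n_unresponsive <= n_exposed required")
  }
  if (all(n_unresponsive == 0) || all(n_unresponsive == n_exposed)) {
    stop("no response variation: LT50 is not identifiable")
  }
  fit_one <- function(k) {
    f <- suppressWarnings(stats::glm(cbind(k, n_exposed - k) ~ temps,
                                     family = stats::binomial()))
    cf <- stats::coef(f)
    c(lt50 = unname(-cf[1] / cf[2]), slope = unname(cf[2]))
  }
  est <- fit_one(n_unresponsive)
  if (!is.null(seed)) set.seed(seed)
  span <- diff(range(temps))
  boot <- vapply(seq_len(bootstrap_reps), function(r) {
    k <- stats::rbinom(length(temps), n_exposed, n_unresponsive / n_exposed)
    if (all(k == 0) || all(k == n_exposed)) return(NA_real_)
    fit_one(k)[["lt50"]]
  }, numeric(1))
  boot <- boot[is.finite(boot) &
                 boot > min(temps) - 2 * span & boot < max(temps) + 2 * span]
  alpha <- (1 - conf) / 2
  ci <- if (length(boot) >= 10) {
    unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  } else c(NA_real_, NA_real_)
  structure(list(lt50 = est[["lt50"]], slope = est[["slope"]],
                 ci = ci, n_boot = length(boot), conf = conf),
            class = "lt50_fit")
}

#' @export
print.lt50_fit <- function(x, ...) {
  cat(sprintf("LT50 = %.2f degC (slope %.2f per degC), %d%% CI [%.2f, %.2f]\n",
              x$lt50, x$slope, round(100 * x$conf), x$ci[1], x$ci[2]))
  invisible(x)
}

#' Do two LT50 confidence intervals separate?
#'
#' Non-overlapping bootstrap intervals are taken as a statistically
#' significant difference between the two fits.
#'
#' @param fit_a,fit_b Two [lt50_fit()] objects.
#' @return A list: `separated` (logical) and `difference`
#'   (`fit_b$lt50 - fit_a$lt50`).
#' @export
lt50_ci_separated <- function(fit_a, fit_b) {
  sep <- fit_a$ci[2] < fit_b$ci[1] || fit_b$ci[2] < fit_a$ci[1]
  list(separated = isTRUE(sep), difference = fit_b$lt50 - fit_a$lt50)
}

#' Percent difference relative to a reference
#'
#' `100 * (value - reference) / reference`; e.g. the elevation of a
#' hyperoxia group mean over its normoxia reference.
#'
#' @param reference Reference value (non-zero).
#' @param value Comparison value.
#' @return Percent difference (vectorised).
#' @export
percent_difference <- function(reference, value) {
  if (any(reference == 0)) stop("reference must be non-zero")
  100 * (value - reference) / reference
}
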