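# The study's statistical battery: natural-log transforms, independent-sample
# t-tests, a Mann-Whitney U test with an exact small-sample enumeration
# branch, and a mixed two-way (between-group x repeated-temperature) ANOVA
# with the Greenhouse-Geisser sphericity adjustment.

#' Natural-log transform
#'
#' @param values Strictly positive numeric vector.
#' @return `log(values)`.
#' @export
ln_transform <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("ln_transform requires strictly positive finite values")
  }
  log(values)
}

#' Independent-samples t-test
#'
#' Welch's t-test by default; set `equal_var = TRUE` for the pooled-variance
#' Student form. Two-sided.
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @param equal_var Pool the variances (Student) instead of Welch.
#' @return A list: `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
t_test_independent <- function(x, y, equal_var = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 observations per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero variance in both groups: t-test undefined")
  }
  res <- stats::t.test(x, y, var.equal = equal_var)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Mann-Whitney U test
#'
#' U is computed from midranks (so ties contribute 1/2). The two-sided
#' p-value is exact -- by full enumeration of all label assignments -- when
#' `n1 + n2 <= 20` and the data are untied; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' `U + U' = n1 * n2` always.
#'
#' @param x,y Numeric samples.
#' @return A list: `U` (for `x`), `U_prime`, `p_value`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  mu <- n1 * n2 / 2
  if (!ties && n1 + n2 <= 20) {
    cmb <- utils::combn(n1 + n2, n1)
    allU <- colSums(cmb) - n1 * (n1 + 1) / 2
    p <- mean(abs(allU - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      d <- U - mu
      z <- (abs(d) - 0.5) / sqrt(sig2)  # continuity-corrected
      z <- max(0, z)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal"
  }
  list(U = U, U_prime = n1 * n2 - U, p_value = p, method = method)
}

#' Greenhouse-Geisser epsilon of a within-subject covariance matrix
#'
#' Computed from the covariance of orthonormal contrasts of the k repeated
#' measures; clamped to its theoretical bounds `[1/(k-1), 1]`. Equals 1
#' exactly when k = 2.
#'
#' @param S k x k covariance matrix of the repeated measures (pooled within
#'   groups).
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(S) {
  k <- nrow(S)
  if (k < 2) stop("need at least 2 repeated measures")
  H <- stats::contr.helmert(k)           # columns orthogonal to the unit vector
  C <- qr.Q(qr(H))                       # orthonormalised
  M <- t(C) %*% S %*% C
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M * M))
  min(1, max(1 / (k - 1), eps))
}

#' Mixed two-way (split-plot) ANOVA with Greenhouse-Geisser adjustment
#'
#' Between-subjects factor `group` crossed with the repeated factor `level`
#' (temperature step). Subjects missing any level are removed (listwise
#' deletion), mirroring an analysis restricted to the temperatures all
#' animals reached. Sphericity is assumed violated: the within and
#' interaction tests report Greenhouse-Geisser adjusted p-values
#' (degrees of freedom scaled by epsilon); the between-group test is
#' unaffected by sphericity and reported unadjusted.
#'
#' @param data Data frame with columns `subject`, `group`, `level`, `value`.
#'   Each (subject, level) pair must appear at most once and each subject
#'   must belong to exactly one group.
#' @return A data frame with one row per effect (`group`, `within`,
#'   `interaction`): `F`, `df_num`, `df_den`, `gg_epsilon`, `p_value`
#'   (unadjusted), `p_gg`, `note`. Degenerate (zero-variance) designs yield
#'   `NaN` F with a note.
#' @export
mixed_anova <- function(data) {
  need <- c("subject", "group", "level", "value")
  if (!all(need %in% names(data))) {
    stop("data must have columns subject, group, level, value")
  }
  data <- data[stats::complete.cases(data[need]), need]
  data$subject <- as.character(data$subject)
  if (anyDuplicated(data[c("subject", "level")]) > 0) {
    stop("each (subject, level) pair may appear at most once")
  }
  gmap <- unique(data[c("subject", "group")])
  if (anyDuplicated(gmap$subject) > 0) {
    stop("each subject must belong to exactly one group")
  }
  levels_all <- sort(unique(data$level))
  k <- length(levels_all)
  if (k < 2) stop("need at least 2 within-subject levels")
  cnt <- table(data$subject)
  complete <- names(cnt)[cnt == k]
  data <- data[data$subject %in% complete, ]
  gmap <- gmap[gmap$subject %in% complete, ]
  if (any(table(gmap$group) < 2) || length(unique(gmap$group)) < 2) {
    stop("need at least 2 complete subjects in each of at least 2 groups")
  }

  # pooled within-group covariance of the repeated measures, for epsilon
  wide <- stats::reshape(
    data[order(data$subject, data$level), ],
    idvar = "subject", timevar = "level", direction = "wide")
  ycols <- grep("^value\\.", names(wide))
  Y <- as.matrix(wide[, ycols])
  grp <- gmap$group[match(wide$subject, gmap$subject)]
  centred <- Y
  for (g in unique(grp)) {
    rows <- grp == g
    centred[rows, ] <- sweep(Y[rows, , drop = FALSE], 2,
                             colMeans(Y[rows, , drop = FALSE]))
  }
  S <- crossprod(centred) / (nrow(Y) - length(unique(grp)))
  eps <- if (sum(S * S) == 0) 1 else gg_epsilon(S)

  d <- data.frame(y = data$value, g = factor(data$group),
                  l = factor(data$level), s = factor(data$subject))
  fit <- stats::aov(y ~ g * l + Error(s), data = d)
  sm <- summary(fit)
  btab <- sm[["Error: s"]][[1]]
  wtab <- sm[["Error: Within"]][[1]]
  pick <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    c(df = tab[i, "Df"], ss = tab[i, "Sum Sq"],
      ms = tab[i, "Mean Sq"], F = tab[i, "F value"])
  }
  gb <- pick(btab, "g"); rb <- pick(btab, "Residuals")
  wl <- pick(wtab, "l"); wi <- pick(wtab, "g:l"); rw <- pick(wtab, "Residuals")

  tiny <- 1e-10 * (1 + mean(data$value^2))  # numerically-zero mean squares
  row <- function(effect, ef, er, use_gg) {
    Fv <- ef[["ms"]] / er[["ms"]]
    if (is.na(Fv) || (er[["ms"]] < tiny && ef[["ms"]] < tiny)) Fv <- NaN
    note <- ""
    if (!is.finite(Fv)) note <- "degenerate: zero denominator mean square"
    p <- if (is.finite(Fv)) {
      stats::pf(Fv, ef[["df"]], er[["df"]], lower.tail = FALSE)
    } else NA_real_
    pg <- if (use_gg && is.finite(Fv)) {
      stats::pf(Fv, eps * ef[["df"]], eps * er[["df"]], lower.tail = FALSE)
    } else p
    data.frame(effect = effect, F = Fv, df_num = ef[["df"]], df_den = er[["df"]],
               gg_epsilon = if (use_gg) eps else NA_real_,
               p_value = p, p_gg = pg, note = note)
  }
  out <- rbind(row("group", gb, rb, FALSE),
               row("within", wl, rw, TRUE),
               row("interaction", wi, rw, TRUE))
  rownames(out) <- NULL
  attr(out, "n_subjects") <- nrow(Y)
  attr(out, "k_levels") <- k
  out
}
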