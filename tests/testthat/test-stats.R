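test_that("natural-log transform and its group-ratio identity", {
  expect_equal(ln_transform(c(1, exp(1), exp(2))), c(0, 1, 2))
  expect_error(ln_transform(c(1, 0)), "positive")
  expect_error(ln_transform(c(2, -1)), "positive")
  # ratio of geometric means equals the exponentiated mean log difference
  set.seed(2)
  x <- rlnorm(20); y <- rlnorm(20)
  expect_equal(exp(mean(ln_transform(y)) - mean(ln_transform(x))),
               exp(mean(log(y))) / exp(mean(log(x))))
})

test_that("pooled t-test reproduces the hand-computed example", {
  res <- t_test_independent(c(1, 2, 3), c(4, 5, 6), equal_var = TRUE)
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.0214, tolerance = 1e-2)
  # swapping the groups negates t and keeps p
  swp <- t_test_independent(c(4, 5, 6), c(1, 2, 3), equal_var = TRUE)
  expect_equal(swp$t, -res$t)
  expect_equal(swp$p_value, res$p_value)
  # identical groups: t = 0, p = 1
  idn <- t_test_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idn$t, 0)
  expect_equal(idn$p_value, 1)
  expect_error(t_test_independent(c(2, 2), c(3, 3)), "zero variance")
})

test_that("Mann-Whitney exact enumeration matches complete separation", {
  x <- 1:9; y <- 11:19
  res <- mann_whitney(x, y)
  expect_equal(res$U, 0)
  expect_equal(res$U_prime, 81)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 2 / choose(18, 9))
  # label swap reflects U and keeps p
  swp <- mann_whitney(y, x)
  expect_equal(swp$U, 81)
  expect_equal(swp$p_value, res$p_value)
})

test_that("Mann-Whitney handles ties through midranks", {
  res <- mann_whitney(1, 1)
  expect_equal(res$U, 0.5)
  expect_equal(res$U_prime, 0.5)
})

test_that("exact Mann-Whitney agrees with the reference implementation", {
  set.seed(8)
  for (i in 1:12) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1))
    mine <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("normal approximation tracks the exact branch at n = 9 vs 9", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(9); y <- rnorm(9, mean = runif(1, 0, 1.5))
    exact <- mann_whitney(x, y)
    # force the approximate branch by scaling beyond the enumeration limit
    approx_p <- local({
      n1 <- 9; n2 <- 9; U <- exact$U; mu <- n1 * n2 / 2
      sig2 <- n1 * n2 * (n1 + n2 + 1) / 12
      z <- max(0, (abs(U - mu) - 0.5) / sqrt(sig2))
      min(1, 2 * pnorm(-z))
    })
    expect_lt(abs(exact$p_value - approx_p), 0.01)
  }
})

test_that("Greenhouse-Geisser epsilon respects its bounds", {
  # k = 2 forces epsilon = 1 exactly
  set.seed(10)
  S2 <- crossprod(matrix(rnorm(20), 10, 2))
  expect_equal(gg_epsilon(S2), 1)
  # arbitrary covariance matrices stay inside [1/(k-1), 1]
  for (k in 3:6) {
    for (i in 1:10) {
      S <- crossprod(matrix(rnorm(3 * k * k), ncol = k))
      e <- gg_epsilon(S)
      expect_gte(e, 1 / (k - 1))
      expect_lte(e, 1)
    }
  }
  # compound symmetry is spherical: epsilon near 1 for a large sample
  set.seed(11)
  k <- 5
  Sigma <- 0.6 * diag(k) + 0.4
  X <- matrix(rnorm(4000 * k), ncol = k) %*% chol(Sigma)
  expect_gt(gg_epsilon(stats::cov(X)), 0.97)
})

mk_long <- function(Y, groups, levels = seq_len(ncol(Y))) {
  do.call(rbind, lapply(seq_len(nrow(Y)), function(i)
    data.frame(subject = sprintf("s%02d", i), group = groups[i],
               level = levels, value = Y[i, ])))
}

test_that("mixed ANOVA matches an explicit sums-of-squares computation", {
  set.seed(12)
  n <- 6; k <- 4
  Y <- rbind(matrix(rnorm(n * k, 10), n, k) + outer(rep(1, n), c(0, 1, 2, 3)),
             matrix(rnorm(n * k, 12), n, k) + outer(rep(1, n), c(0, 2, 4, 6)))
  groups <- rep(c("ctl", "trt"), each = n)
  res <- mixed_anova(mk_long(Y, groups))

  # independent cell-means computation
  N <- nrow(Y); G <- 2
  m <- mean(Y)
  mg <- tapply(rowMeans(Y), groups, mean)[unique(groups)]
  ms <- rowMeans(Y)
  tl <- colMeans(Y)
  cell <- rbind(colMeans(Y[1:n, ]), colMeans(Y[(n + 1):(2 * n), ]))
  ss_group <- k * n * sum((mg - m)^2)
  ss_subj <- k * sum((ms - rep(mg, each = n))^2)
  ss_level <- N * sum((tl - m)^2)
  ss_int <- n * sum((cell - outer(mg, rep(1, k)) -
                       outer(rep(1, G), tl) + m)^2)
  ss_err <- sum((Y - cell[rep(1:G, each = n), ] - ms + rep(mg, each = n))^2)
  F_group <- (ss_group / (G - 1)) / (ss_subj / (N - G))
  F_level <- (ss_level / (k - 1)) / (ss_err / ((N - G) * (k - 1)))
  F_int <- (ss_int / ((G - 1) * (k - 1))) / (ss_err / ((N - G) * (k - 1)))
  expect_equal(res$F, c(F_group, F_level, F_int), tolerance = 1e-8)
  expect_equal(res$df_num, c(1, k - 1, k - 1))
  expect_equal(res$df_den, c(N - 2, (N - 2) * (k - 1), (N - 2) * (k - 1)))
  # adjusted p from the same F at epsilon-scaled df
  eps <- res$gg_epsilon[2]
  expect_equal(res$p_gg[3],
               pf(F_int, eps * (k - 1), eps * (N - 2) * (k - 1),
                  lower.tail = FALSE), tolerance = 1e-10)
})

test_that("mixed ANOVA agrees with the multivariate reference route", {
  set.seed(13)
  n <- 9; k <- 5
  Y <- matrix(rnorm(2 * n * k), 2 * n, k)
  Y[(n + 1):(2 * n), ] <- Y[(n + 1):(2 * n), ] +
    outer(rep(1, n), seq(0, 1, length.out = k))
  groups <- rep(c("a", "b"), each = n)
  res <- mixed_anova(mk_long(Y, groups))

  dfr <- data.frame(group = factor(groups))
  mlm <- stats::lm(Y ~ group, data = dfr)
  idata <- data.frame(level = factor(seq_len(k)))
  av <- car::Anova(mlm, idata = idata, idesign = ~level, type = 2)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  adj <- s$pval.adjustments
  expect_equal(res$gg_epsilon[2], unname(adj["level", "GG eps"]),
               tolerance = 1e-8)
  expect_equal(res$p_gg[2], unname(adj["level", "Pr(>F[GG])"]),
               tolerance = 1e-8)
  expect_equal(res$p_gg[3], unname(adj["group:level", "Pr(>F[GG])"]),
               tolerance = 1e-8)
})

test_that("degenerate and malformed designs are handled explicitly", {
  Y <- matrix(5, 6, 3)
  res <- mixed_anova(mk_long(Y, rep(c("a", "b"), each = 3)))
  expect_true(all(!is.finite(res$F)))
  expect_true(all(grepl("degenerate", res$note)))
  d <- mk_long(matrix(rnorm(12), 4, 3), rep(c("a", "b"), each = 2))
  expect_error(mixed_anova(rbind(d, d[1, ])), "at most once")
  expect_error(mixed_anova(d[d$level == 1, ]), "2 within-subject levels")
  # listwise deletion removes subjects missing a level
  d2 <- mk_long(matrix(rnorm(18), 6, 3), rep(c("a", "b"), each = 3))
  d2 <- d2[!(d2$subject == "s01" & d2$level == 2), ]
  res2 <- mixed_anova(d2)
  expect_equal(attr(res2, "n_subjects"), 5)
})
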