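test_that("empirical logit matches the shrunken log-odds formula", {
  expect_equal(empirical_logit(0.5, 96), 0)
  expect_equal(empirical_logit(1, 96), log(193))
  expect_equal(empirical_logit(0, 96), -log(193))
  # antisymmetry and strict monotonicity in p
  p <- seq(0, 1, by = 0.05)
  expect_equal(empirical_logit(p, 54), -empirical_logit(1 - p, 54))
  expect_true(all(diff(empirical_logit(p, 54)) > 0))
  # shrinkage vanishes as n grows
  expect_lt(abs(empirical_logit(0.8, 1e7) - qlogis(0.8)), 1e-6)
  expect_error(empirical_logit(1.2, 96), "\\[0, 1\\]")
})

test_that("paired t matches a closed-form evaluation", {
  x <- c(3, 5, 7, 9)
  y <- x - c(1, 2, 3, 4)
  res <- paired_t(x, y)
  expect_equal(res$statistic, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-10)
  expect_equal(res$df1, 3)
  expect_equal(res$effect_size, 2.5 / sd(c(1, 2, 3, 4)))
  # mean-zero differences give t = 0, p = 1, d = 0
  null <- paired_t(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(null$statistic, 0)
  expect_equal(null$p_raw, 1)
  expect_equal(null$effect_size, 0)
  expect_error(paired_t(x, x), "zero-variance")
})

test_that("paired t type-I rate is calibrated under the null", {
  set.seed(71)
  reps <- 2000
  rej <- 0
  for (r in seq_len(reps)) {
    d <- rnorm(30)
    tt <- abs(mean(d) / (sd(d) / sqrt(30)))
    if (tt > qt(0.975, 29)) rej <- rej + 1
  }
  # sanity on the analytic threshold, then the package path on a subsample
  expect_gte(rej / reps, 0.04)
  expect_lte(rej / reps, 0.06)
  set.seed(72)
  pvals <- replicate(300, paired_t(rnorm(30), rnorm(30))$p_raw)
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.11)
})

test_that("one-way RM ANOVA matches a manual sums-of-squares oracle", {
  set.seed(73)
  m <- matrix(rnorm(15, mean = rep(c(0, 0.5, 1), each = 5)), 5, 3)
  res <- rm_anova_oneway(m)
  # manual decomposition
  grand <- mean(m)
  ss_cond <- nrow(m) * sum((colMeans(m) - grand)^2)
  ss_subj <- ncol(m) * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_manual <- (ss_cond / 2) / (ss_err / 8)
  expect_equal(res$statistic, f_manual, tolerance = 1e-8)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 8)
  expect_equal(res$effect_size, ss_cond / (ss_cond + ss_err), tolerance = 1e-8)
  expect_equal(res$p_raw, pf(f_manual, 2, 8, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("k = 2 RM ANOVA F equals the squared paired t", {
  set.seed(74)
  m <- matrix(rnorm(20), 10, 2)
  f <- rm_anova_oneway(m)$statistic
  t <- paired_t(m[, 1], m[, 2])$statistic
  expect_equal(f, t^2, tolerance = 1e-8)
})

test_that("RM ANOVA handles degenerate and invalid inputs", {
  expect_equal(rm_anova_oneway(matrix(3, 5, 3))$statistic, 0)
  m <- matrix(rnorm(15), 5, 3)
  m[2, 2] <- NA
  expect_error(rm_anova_oneway(m), "missing cells")
})

test_that("mixed ANOVA matches a manual split-plot decomposition", {
  set.seed(75)
  n_per <- 6
  m <- matrix(rnorm(2 * n_per * 3), 2 * n_per, 3)
  m[seq_len(n_per), ] <- m[seq_len(n_per), ] + rep(c(0, 0.5, 1), each = n_per)
  g <- rep(c("a", "b"), each = n_per)
  res <- mixed_anova(m, g)
  # manual balanced split-plot sums of squares
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  subj_means <- rowMeans(m)
  grp_means <- tapply(subj_means, g, mean)
  ss_group <- k * n_per * sum((grp_means - grand)^2)
  ss_subj_within <- k * sum((subj_means - grp_means[g])^2)
  cond_means <- colMeans(m)
  ss_cond <- n * sum((cond_means - grand)^2)
  cell_means <- apply(m, 2, function(col) tapply(col, g, mean))  # 2 x k
  ss_cells <- n_per * sum((cell_means - grand)^2)
  ss_int <- ss_cells - ss_group - ss_cond
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_group - ss_subj_within - ss_cond - ss_int
  f_group <- (ss_group / 1) / (ss_subj_within / (n - 2))
  f_cond <- (ss_cond / (k - 1)) / (ss_err / ((n - 2) * (k - 1)))
  f_int <- (ss_int / (k - 1)) / (ss_err / ((n - 2) * (k - 1)))
  expect_equal(res$statistic, c(f_group, f_cond, f_int), tolerance = 1e-8)
  expect_equal(res$df1, c(1, k - 1, k - 1))
  expect_equal(res$df2, c(n - 2, (n - 2) * (k - 1), (n - 2) * (k - 1)))
})

test_that("mixed ANOVA with two identical groups has zero between-group F", {
  set.seed(76)
  half <- matrix(rnorm(15), 5, 3)
  res <- mixed_anova(rbind(half, half), rep(c("a", "b"), each = 5))
  expect_equal(res$statistic[res$contrast == "group (between)"], 0)
})

test_that("mixed ANOVA within effect reduces to the one-way RM ANOVA without group structure", {
  # two identical group copies: group and interaction sums of squares vanish
  # exactly, so the within F differs from the pooled one-way F only through
  # the error degrees of freedom ((2n-2)(k-1) vs (k-1)(2n-1))
  set.seed(77)
  half <- matrix(rnorm(15) + rep(c(0, 0.8, 0.2), each = 5), 5, 3)
  m <- rbind(half, half)
  one <- rm_anova_oneway(m)
  mix <- mixed_anova(m, rep(c("a", "b"), each = 5))
  within <- mix[mix$contrast == "condition (within)", ]
  expect_equal(within$df1, one$df1)
  n <- nrow(m)
  expect_equal(within$statistic, one$statistic * (n - 2) / (n - 1),
               tolerance = 1e-8)
})

test_that("mixed ANOVA type-I rates are calibrated under a permuted null", {
  set.seed(78)
  reps <- 400
  rej <- matrix(0, reps, 3)
  for (r in seq_len(reps)) {
    m <- matrix(rnorm(10 * 3), 10, 3) + rnorm(10)  # subject random effect
    g <- sample(rep(c("a", "b"), each = 5))
    rej[r, ] <- mixed_anova(m, g)$p_raw < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates > 0.02 & rates < 0.09))
})

test_that("mixed ANOVA rejects bad grouping", {
  m <- matrix(rnorm(30), 10, 3)
  expect_error(mixed_anova(m, rep("a", 10)), "two groups")
  expect_error(mixed_anova(m, c(rep("a", 7), rep("b", 3))), "unbalanced")
})

test_that("Holm adjustment matches the step-down hand computation", {
  expect_equal(holm_correct(0.02), 0.02)
  expect_equal(holm_correct(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(79)
  p <- runif(6)
  adj <- holm_correct(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(holm_correct(numeric(0)), "empty")
})

test_that("Holm controls the familywise error rate in an all-null simulation", {
  set.seed(80)
  reps <- 2000
  fwer <- mean(replicate(reps, {
    p <- runif(3)  # three independent true nulls
    any(holm_correct(p) < 0.05)
  }))
  expect_lte(fwer, 0.05 + 2.5 * sqrt(0.05 * 0.95 / reps))
})

test_that("JZS Bayes factors behave like a default-prior evidence measure", {
  # exactly null-centred data favour the null
  set.seed(81)
  d <- rnorm(30); d <- d - mean(d)  # t = 0
  y <- rnorm(30)
  expect_lt(jzs_bf_paired(y + d, y), 1)
  # monotone increasing in |t| at fixed n
  ts <- c(0, 0.5, 1, 2, 3, 4)
  bfs <- vapply(ts, function(t) wmperturb:::jzs_bf_from_t(t, 30), numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("the JZS integral agrees with a fine-grid quadrature oracle", {
  # oracle: Cauchy prior on the standardized effect, trapezoid quadrature of
  # the noncentral-t likelihood (a mathematically equivalent representation)
  oracle_bf <- function(t, n, r) {
    delta <- seq(-15, 15, length.out = 6001)
    # dt() with ncp warns about its own precision limit; far beyond the 1%
    # tolerance used here
    lik <- suppressWarnings(dt(t, n - 1, ncp = delta * sqrt(n)))
    h1 <- pracma::trapz(delta, lik * dcauchy(delta, 0, r))
    h1 / dt(t, n - 1)
  }
  for (t in c(0.8, 2.798)) {
    bf <- wmperturb:::jzs_bf_from_t(t, 30, sqrt(2) / 2)
    expect_equal(bf, oracle_bf(t, 30, sqrt(2) / 2), tolerance = 0.01)
  }
  # plausibility: a t of 2.798 with 30 pairs lands near BF10 ~ 4.9
  expect_equal(wmperturb:::jzs_bf_from_t(2.798, 30), 4.9, tolerance = 0.05)
})

test_that("required sample size inverts the noncentral-t power curve", {
  expect_identical(required_sample_size(0.55, 0.05, 0.8), 28L)
  expect_gte(power_paired_t(28, 0.55), 0.8)
  expect_lt(power_paired_t(27, 0.55), 0.8)
  # power is monotone nondecreasing in n at fixed d
  pw <- vapply(5:60, power_paired_t, numeric(1), d = 0.4)
  expect_true(all(diff(pw) > -1e-12))
  expect_error(required_sample_size(-1), "effect_d")
})
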