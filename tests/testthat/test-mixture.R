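test_that("response error wraps on the 180-degree space with a half-open convention", {
  expect_equal(response_error(45, 45), 0)
  expect_equal(response_error(10, 170), 20)
  expect_equal(response_error(135, 45), -90)  # boundary maps to -90, not +90
  expect_equal(response_error(c(0, 90, 179), c(179, 0, 0)), c(1, -90, -1))
  expect_error(response_error(180, 90), "\\[0, 180\\)")
})

test_that("negative log-likelihood matches closed forms and a summation oracle", {
  tr <- simulate_cell(10, 0.8, 0.1, 15, seed = 51)
  # pure guessing: density 1/(2*pi) per trial on the doubled circle
  expect_equal(mixture_negloglik(0, 0, 5, tr), 10 * log(2 * pi))
  # all responses at targets with p_target = 1: n * -log(vm(0; 0, kappa))
  tr0 <- tr
  tr0$response_deg <- tr0$target_deg
  kappa <- 4
  expect_equal(mixture_negloglik(1, 0, kappa, tr0),
               -10 * log(exp(kappa) / (2 * pi * besselI(kappa, 0))),
               tolerance = 1e-10)
  # random parameter points vs an independent term-by-term oracle
  tr30 <- simulate_cell(30, 0.7, 0.2, 18, set_size = 3, seed = 52)
  set.seed(53)
  for (i in 1:5) {
    w <- runif(3); w <- w / sum(w)
    k <- runif(1, 0.5, 40)
    expect_equal(mixture_negloglik(w[1], w[2], k, tr30),
                 oracle_negloglik(w[1], w[2], k, tr30), tolerance = 1e-10)
  }
  expect_error(mixture_negloglik(0.5, 0.2, 5, tr[0, ]), "empty")
})

test_that("the EM optimum is at least as good as a dense brute-force grid", {
  tr <- simulate_cell(40, 0.75, 0.15, 16, seed = 54)
  fit <- fit_mixture(tr, n_starts = 10, seed = 55)
  best_grid <- grid_best_negloglik(tr)
  expect_lte(-fit$log_likelihood, best_grid + 1e-3)
})

test_that("fits satisfy the simplex constraint and dominate the nested uniform model", {
  tr <- simulate_cell(96, 0.85, 0.1, 14, seed = 56)
  fit <- fit_mixture(tr, n_starts = 10, seed = 57)
  expect_equal(fit$p_target + fit$p_nontarget + fit$p_guess, 1,
               tolerance = 1e-8)
  expect_true(all(c(fit$p_target, fit$p_nontarget, fit$p_guess) >= 0))
  expect_gte(fit$log_likelihood, -96 * log(2 * pi))
  expect_equal(fit$sd_deg, kappa_to_sd_deg(fit$kappa))
  expect_true(fit$converged)
})

test_that("pure-uniform data are recovered as guessing", {
  tr <- simulate_cell(5000, 0, 0, 15, seed = 58)  # p_guess = 1
  fit <- fit_mixture(tr, n_starts = 20, seed = 59)
  expect_gte(fit$p_guess, 0.95)
  # nested-model sanity: never below the pure-guess log-likelihood
  expect_gte(fit$log_likelihood, -5000 * log(2 * pi))
})

test_that("parameters are recovered within tolerance at large n", {
  tr <- simulate_cell(10000, 0.9, 0.05, 12, seed = 60)
  fit <- fit_mixture(tr, n_starts = 5, seed = 61)
  expect_lt(abs(fit$p_target - 0.9), 0.02)
  expect_lt(abs(fit$p_nontarget - 0.05), 0.02)
  expect_lt(abs(fit$p_guess - 0.05), 0.02)
  expect_lt(abs(fit$sd_deg - 12), 1)
})

test_that("fit guards reject unusable inputs", {
  tr <- simulate_cell(10, 0.8, 0.1, 15, seed = 62)
  expect_error(fit_mixture(tr), "at least 20 trials")
  tr2 <- simulate_cell(30, 0.8, 0.1, 15, seed = 63)
  tr2$response_deg <- tr2$target_deg
  expect_error(fit_mixture(tr2), "degenerate")
})

test_that("precision equals the reciprocal circular SD with known limits", {
  # Bessel-ratio closed form: von Mises kappa = 4 on the doubled circle
  set.seed(64)
  kappa <- 4
  e <- wmperturb:::double_rad_to_deg(wmperturb:::rvonmises(1e5, 0, kappa))
  p <- precision(e)
  expect_equal(p$circ_sd_rad,
               sqrt(-2 * log(besselI(kappa, 1) / besselI(kappa, 0))),
               tolerance = 0.01)
  expect_equal(p$precision, 1 / p$circ_sd_rad)
  # uniform limit: the resultant length decays like 1/sqrt(n), so the
  # circular SD grows like sqrt(log n) and precision sinks toward zero
  # (about 1/sqrt(-2 log(1/sqrt(n))) ~ 0.33 at n = 10,000)
  set.seed(65)
  u <- precision(runif(10000, -90, 90))
  expect_lt(u$precision, 0.4)
  # monotonicity: widening dispersion strictly decreases precision
  set.seed(66)
  base <- rnorm(500, 0, 2)
  expect_gt(precision(base)$precision, precision(base * 4)$precision)
  expect_error(precision(rep(1, 10)), "distinct")
})

test_that("sd_deg <-> kappa conversion is a consistent bijection", {
  for (sd in c(5, 12, 20, 35)) {
    expect_equal(kappa_to_sd_deg(sd_deg_to_kappa(sd)), sd, tolerance = 1e-6)
  }
})

test_that("per-condition fits produce one row per subject x condition cell", {
  tr <- simulate_responses(build_design(1, 2, seed = 67),
                           default_generative_params(1), seed = 68)
  fits <- fit_by_condition(tr, n_starts = 3, seed = 69)
  expect_equal(nrow(fits), 4)
  expect_true(all(fits$n_trials == 96))
  expect_setequal(names(fits),
                  c("subject_id", "condition", "p_target", "p_nontarget",
                    "p_guess", "sd_deg", "precision", "n_trials", "converged"))
})

test_that("precision and fitted p_target track the generating p_target together", {
  grid <- expand.grid(p_t = c(0.6, 0.75, 0.9), rep = 1:3)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    tr <- simulate_cell(96, grid$p_t[i], 0.05, 15, seed = 700 + i)
    fit <- fit_mixture(tr, n_starts = 4, seed = 800 + i)
    prec <- precision(response_error(tr$response_deg, tr$target_deg))
    data.frame(gen = grid$p_t[i], p_hat = fit$p_target,
               prec = prec$precision)
  }))
  expect_gt(cor(res$gen, res$p_hat, method = "spearman"), 0)
  expect_gt(cor(res$gen, res$prec, method = "spearman"), 0)
})
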