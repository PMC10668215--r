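# Shared fixtures: small simulated trial tables and an independent
# brute-force evaluator of the mixture log-likelihood used as an oracle.

# Simulate n trials for one subject/condition directly (bypasses the design
# machinery so mixture tests do not depend on it).
simulate_cell <- function(n, p_target, p_nontarget, sd_deg, set_size = 2,
                          seed = 1) {
  set.seed(seed)
  kappa <- sd_deg_to_kappa(sd_deg)
  target <- runif(n, 0, 180)
  nts <- matrix(runif(n * (set_size - 1), 0, 180), nrow = n)
  comp <- sample(c("t", "n", "g"), n, replace = TRUE,
                 prob = c(p_target, p_nontarget, 1 - p_target - p_nontarget))
  noise <- wmperturb:::double_rad_to_deg(wmperturb:::rvonmises(n, 0, kappa))
  resp <- ifelse(comp == "t", target + noise,
                 ifelse(comp == "n", nts[cbind(seq_len(n),
                                               sample(set_size - 1, n, TRUE))] + noise,
                        runif(n, 0, 180)))
  df <- data.frame(subject_id = 1, experiment_id = 1,
                   trial_index = seq_len(n), condition = "Leader",
                   target_deg = target, nontarget1_deg = nts[, 1])
  if (set_size == 3) df$nontarget2_deg <- nts[, 2]
  df$response_deg = resp %% 180
  df
}

# Term-by-term log-likelihood oracle, written independently of the package's
# vectorized evaluator: plain loops, direct von Mises density.
oracle_negloglik <- function(p_t, p_nt, kappa, trials) {
  nt_cols <- grep("^nontarget", names(trials), value = TRUE)
  m <- length(nt_cols)
  total <- 0
  for (i in seq_len(nrow(trials))) {
    dvm <- function(resp, centre) {
      x <- 2 * (resp - centre) * pi / 180
      exp(kappa * cos(x)) / (2 * pi * besselI(kappa, 0))
    }
    d <- p_t * dvm(trials$response_deg[i], trials$target_deg[i])
    for (col in nt_cols) {
      d <- d + (p_nt / m) * dvm(trials$response_deg[i], trials[[col]][i])
    }
    d <- d + (1 - p_t - p_nt) / (2 * pi)
    total <- total - log(d)
  }
  total
}

# Best point on a dense brute-force grid over (p_target, p_nontarget, kappa):
# independent oracle for the optimizer.
grid_best_negloglik <- function(trials, n_p = 21, kappas = NULL) {
  if (is.null(kappas)) kappas <- exp(seq(log(0.5), log(60), length.out = 25))
  ps <- seq(0, 1, length.out = n_p)
  best <- Inf
  for (pt in ps) for (pn in ps) {
    if (pt + pn > 1) next
    for (k in kappas) {
      v <- mixture_negloglik(pt, pn, k, trials)
      if (v < best) best <- v
    }
  }
  best
}
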