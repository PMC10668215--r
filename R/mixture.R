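# Three-component circular mixture model for continuous report.
#
# A response is modelled as coming from one of three sources: the target item
# (von Mises noise around the true orientation), one of the nontarget items
# (the same noise around a wrong item — a swap error), or a uniform random
# guess. Target and nontarget components share a single concentration kappa;
# the guess component is uniform on the doubled circle. Fitting is by
# maximum likelihood via multi-start EM.

#' Signed circular response error
#'
#' Error between a reported and a true orientation on the 180-degree-periodic
#' space, in degrees within `[-90, 90)`:
#' `((response - target + 90) mod 180) - 90`.
#'
#' @param response_deg,target_deg Orientations in `[0, 180)` (vectorized).
#' @return Signed errors in degrees.
#' @export
response_error <- function(response_deg, target_deg) {
  if (any(response_deg < 0 | response_deg >= 180, na.rm = TRUE) ||
      any(target_deg < 0 | target_deg >= 180, na.rm = TRUE)) {
    stop("orientations must lie in [0, 180)")
  }
  ((response_deg - target_deg + 90) %% 180) - 90
}

# Doubled-circle error matrix for a trial table: column 1 is the
# response-target error, remaining columns the response-nontarget errors,
# all in radians on the doubled circle.
trial_errors_rad <- function(trials) {
  nt_cols <- grep("^nontarget[0-9]+_deg$", names(trials), value = TRUE)
  if (!all(c("response_deg", "target_deg") %in% names(trials))) {
    stop("trials must carry response_deg and target_deg")
  }
  e_t <- deg_to_double_rad(response_error(trials$response_deg, trials$target_deg))
  e_nt <- vapply(nt_cols, function(col) {
    deg_to_double_rad(response_error(trials$response_deg, trials[[col]]))
  }, numeric(nrow(trials)))
  cbind(target = e_t, matrix(e_nt, nrow = nrow(trials),
                             dimnames = list(NULL, nt_cols)))
}

#' Negative log-likelihood of the mixture model
#'
#' Per-trial density on the doubled circle:
#' `p_target * vm(e_t; kappa) + (p_nontarget / m) * sum_j vm(e_nt_j; kappa) +
#' p_guess / (2 pi)`, where `m` is the number of nontargets and `p_guess =
#' 1 - p_target - p_nontarget`.
#'
#' @param p_target,p_nontarget Mixture weights (with implied `p_guess`).
#' @param kappa von Mises concentration (> 0) shared by target and nontarget
#'   components.
#' @param trials Trial table with `response_deg`, `target_deg` and nontarget
#'   columns.
#' @return The negative sum of log densities.
#' @export
mixture_negloglik <- function(p_target, p_nontarget, kappa, trials) {
  if (nrow(trials) == 0) stop("empty trial list")
  p_guess <- 1 - p_target - p_nontarget
  if (p_target < 0 || p_nontarget < 0 || p_guess < -1e-12) {
    stop("invalid mixture weights")
  }
  p_guess <- max(p_guess, 0)
  stopifnot(kappa > 0)
  e <- trial_errors_rad(trials)
  m <- ncol(e) - 1
  dens <- p_target * vm_density(e[, 1], kappa) +
    (p_nontarget / m) * rowSums(matrix(vm_density(e[, -1, drop = FALSE], kappa),
                                       nrow = nrow(e))) +
    p_guess / (2 * pi)
  -sum(log(dens))
}

#' Fit the mixture model by multi-start EM
#'
#' Expectation-maximization on the complete-data likelihood: the E-step
#' computes per-trial component responsibilities, the M-step updates the
#' weights to the mean responsibilities and the shared concentration from the
#' responsibility-weighted mean resultant length of the component-centred
#' errors. Several random restarts protect against local optima; the best
#' local optimum is returned.
#'
#' @param trials Trial table (all trials must have the same set size).
#' @param n_starts Number of random restarts (default 20).
#' @param seed Optional seed controlling the restarts.
#' @param kappa_bounds Concentration bounds, default `c(0.05, 200)`, keeping
#'   the noise component away from degenerate spikes.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood improves
#'   by less than `tol` (default 1e-8) or after `max_iter` (default 500)
#'   iterations.
#' @param min_trials Reject fits on fewer trials than this floor (default 20).
#' @return An object of class `mixture_fit`: `p_target`, `p_nontarget`,
#'   `p_guess`, `kappa`, `sd_deg`, `log_likelihood`, `n_trials`, `converged`,
#'   `n_starts_used`.
#' @examples
#' stubs <- build_design(1, n_subjects = 1, seed = 3)
#' trials <- simulate_responses(stubs, default_generative_params(1), seed = 4)
#' fit_mixture(trials, n_starts = 5, seed = 5)
#' @export
fit_mixture <- function(trials, n_starts = 20, seed = NULL,
                        kappa_bounds = c(0.05, 200), max_iter = 500,
                        tol = 1e-8, min_trials = 20) {
  if (nrow(trials) < min_trials) {
    stop("need at least ", min_trials, " trials to fit the mixture model; ",
         "got ", nrow(trials), ". Pool more trials or lower min_trials.")
  }
  e <- trial_errors_rad(trials)
  if (stats::var(e[, 1]) < .Machine$double.eps) {
    stop("degenerate fit: all response errors identical")
  }
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(e) - 1
  n <- nrow(e)
  cos_e <- cos(e)
  sin_e <- sin(e)

  best <- NULL
  for (s in seq_len(n_starts)) {
    w <- stats::runif(3)
    w <- w / sum(w)
    kappa <- sd_deg_to_kappa(stats::runif(1, 6, 30))
    ll_old <- -Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      # E-step: responsibilities over target, m nontargets, guess.
      f <- vm_density(e, kappa)                       # n x (1+m)
      comp <- cbind(w[1] * f[, 1],
                    (w[2] / m) * f[, -1, drop = FALSE],
                    w[3] / (2 * pi))
      tot <- rowSums(comp)
      ll <- sum(log(tot))
      r <- comp / tot
      # M-step: weights.
      r_t <- r[, 1]
      r_nt <- rowSums(r[, 1 + seq_len(m), drop = FALSE])
      w <- c(mean(r_t), mean(r_nt), mean(r[, ncol(r)]))
      # M-step: shared kappa from the responsibility-weighted resultant of
      # the component-centred errors.
      wts <- cbind(r_t, r[, 1 + seq_len(m), drop = FALSE])
      mass <- sum(wts)
      if (mass > 1e-10) {
        C <- sum(wts * cos_e)
        S <- sum(wts * sin_e)
        R <- min(sqrt(C^2 + S^2) / mass, 1 - 1e-12)
        kappa <- min(max(vm_a1_inv(R), kappa_bounds[1]), kappa_bounds[2])
      }
      if (ll - ll_old < tol && iter > 1) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    cand <- list(w = w, kappa = kappa, ll = ll, converged = converged)
    if (is.null(best) || cand$ll > best$ll) best <- cand
  }

  # The pure-guess model is nested in the mixture, so the fitted likelihood
  # must never fall below it; fall back to it if every start ended on a worse
  # ridge (possible when kappa collapses to its near-flat lower bound).
  ll_uniform <- -n * log(2 * pi)
  if (best$ll < ll_uniform) {
    best <- list(w = c(0, 0, 1), kappa = kappa_bounds[1], ll = ll_uniform,
                 converged = TRUE)
  }

  structure(
    list(
      p_target = best$w[1],
      p_nontarget = best$w[2],
      p_guess = best$w[3],
      kappa = best$kappa,
      sd_deg = kappa_to_sd_deg(best$kappa),
      log_likelihood = best$ll,
      n_trials = n,
      converged = best$converged,
      n_starts_used = n_starts
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("<mixture_fit> n = %d trials\n",
                     "  p_target = %.3f, p_nontarget = %.3f, p_guess = %.3f\n",
                     "  kappa = %.2f (sd = %.1f deg), logLik = %.2f, converged = %s\n"),
              x$n_trials, x$p_target, x$p_nontarget, x$p_guess,
              x$kappa, x$sd_deg, x$log_likelihood, x$converged))
  invisible(x)
}

#' Memory precision as reciprocal circular SD
#'
#' Response errors are doubled and converted to radians; the circular SD is
#' `sqrt(-2 log R)` with `R` the mean resultant length, and precision is its
#' reciprocal (units: 1/radian on the doubled circle).
#'
#' @param errors_deg Signed response errors in degrees (`[-90, 90)`), at
#'   least two distinct values.
#' @return A list of class `precision_estimate`: `precision`, `circ_sd_rad`,
#'   `n_trials`.
#' @export
precision <- function(errors_deg) {
  errors_deg <- errors_deg[!is.na(errors_deg)]
  if (length(unique(errors_deg)) < 2) {
    stop("need at least 2 distinct error values (zero dispersion gives infinite precision)")
  }
  e <- deg_to_double_rad(errors_deg)
  R <- sqrt(mean(cos(e))^2 + mean(sin(e))^2)
  if (R >= 1 - 1e-14) stop("zero dispersion: precision is unbounded")
  circ_sd <- sqrt(-2 * log(R))
  structure(
    list(precision = 1 / circ_sd, circ_sd_rad = circ_sd,
         n_trials = length(errors_deg)),
    class = "precision_estimate"
  )
}

#' @export
print.precision_estimate <- function(x, ...) {
  cat(sprintf("<precision_estimate> precision = %.3f (circular SD %.3f rad), n = %d\n",
              x$precision, x$circ_sd_rad, x$n_trials))
  invisible(x)
}

#' Per-subject, per-condition mixture fits and precision
#'
#' Mirrors how subject-level condition values are reported: one mixture fit
#' and one precision estimate per subject x condition cell (96 trials per
#' cell in two-item designs, 54 in three-item ones).
#'
#' @param trials Trial table with responses.
#' @param n_starts,seed,... Passed to [fit_mixture()].
#' @return A data frame: `subject_id`, `condition`, `p_target`,
#'   `p_nontarget`, `p_guess`, `sd_deg`, `precision`, `n_trials`,
#'   `converged`.
#' @export
fit_by_condition <- function(trials, n_starts = 20, seed = NULL, ...) {
  cells <- unique(trials[, c("subject_id", "condition")])
  cells <- cells[order(cells$subject_id, cells$condition), ]
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  seeds <- derive_seeds(seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$subject_id == cells$subject_id[i] &
                    trials$condition == cells$condition[i], ]
    fit <- fit_mixture(sub, n_starts = n_starts, seed = seeds[i], ...)
    prec <- precision(response_error(sub$response_deg, sub$target_deg))
    data.frame(
      subject_id = cells$subject_id[i],
      condition = cells$condition[i],
      p_target = fit$p_target,
      p_nontarget = fit$p_nontarget,
      p_guess = fit$p_guess,
      sd_deg = fit$sd_deg,
      precision = prec$precision,
      n_trials = fit$n_trials,
      converged = fit$converged
    )
  })
  do.call(rbind, rows)
}
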