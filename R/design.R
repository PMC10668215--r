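# Experiment designs and the generative behavioral simulator.
#
# Four designs are supported. Experiments 1 and 2 are two-item tasks (192
# trials, conditions Leader and Follower1 at lags 0/200 ms); experiments 3 and
# 4 are three-item tasks (162 trials, conditions Leader, Follower1, Follower2
# at lags 0/150/300 ms). Odd-numbered experiments make the tagged feature
# (color) task relevant; even-numbered ones make it irrelevant. A trial's
# condition is the sequence role of the probed item.

#' Design specification for one experiment
#'
#' @param experiment_id Integer 1-4.
#' @param n_subjects Number of subjects (default 30, the per-experiment cohort
#'   after exclusions).
#' @return A list of class `design_spec`: trial counts, set size, ordered
#'   condition labels, per-condition lags (ms), and whether the tagged color
#'   feature is task relevant.
#' @export
design_spec <- function(experiment_id, n_subjects = 30) {
  if (!experiment_id %in% 1:4) stop("unknown experiment_id: ", experiment_id)
  two_item <- experiment_id %in% c(1, 2)
  structure(
    list(
      experiment_id = as.integer(experiment_id),
      n_subjects = as.integer(n_subjects),
      n_trials = if (two_item) 192L else 162L,
      set_size = if (two_item) 2L else 3L,
      conditions = if (two_item) c("Leader", "Follower1")
                   else c("Leader", "Follower1", "Follower2"),
      lags_ms = if (two_item) c(Leader = 0, Follower1 = 200)
                else c(Leader = 0, Follower1 = 150, Follower2 = 300),
      task_relevant_color = experiment_id %in% c(1, 3)
    ),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> experiment %d: %d subjects x %d trials, set size %d\n",
              x$experiment_id, x$n_subjects, x$n_trials, x$set_size))
  cat("  conditions:", paste(sprintf("%s (%g ms)", x$conditions,
                                     x$lags_ms[x$conditions]), collapse = ", "), "\n")
  invisible(x)
}

# Rejection-sample set_size orientations in [0, 180) with all pairwise
# circular distances >= min_sep degrees. Cheap and exact at set sizes 2-3.
sample_orientations <- function(set_size, min_sep = 10, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    th <- stats::runif(set_size, 0, 180)
    d <- outer(th, th, circ_dist_orientation)
    if (all(d[upper.tri(d)] >= min_sep)) return(th)
  }
  stop("failed to sample orientations with minimum separation ", min_sep,
       " degrees after ", max_tries, " tries")
}

#' Build a counterbalanced trial table (no responses)
#'
#' Per subject: exact per-condition trial counts (96/96 for two-item designs,
#' 54/54/54 for three-item ones), condition order randomized, orientations
#' drawn uniformly with at least `min_sep` degrees between any two, and
#' condition assignment independent of the orientation values.
#'
#' @param experiment_id Integer 1-4.
#' @param n_subjects Number of subjects.
#' @param seed Master seed; per-subject streams are derived deterministically
#'   from it.
#' @param min_sep Minimum pairwise circular separation in degrees (default 10).
#' @return A data frame of trial stubs: `subject_id`, `experiment_id`,
#'   `trial_index`, `condition`, `target_deg`, `nontarget1_deg`
#'   (`nontarget2_deg` for three-item designs) and `response_deg` (all `NA`).
#' @examples
#' stubs <- build_design(1, n_subjects = 2, seed = 1)
#' table(stubs$subject_id, stubs$condition)
#' @export
build_design <- function(experiment_id, n_subjects = 30, seed = NULL,
                         min_sep = 10) {
  spec <- design_spec(experiment_id, n_subjects)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  seeds <- derive_seeds(seed, n_subjects)
  per_cond <- spec$n_trials %/% length(spec$conditions)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    set.seed(seeds[s])
    cond <- sample(rep(spec$conditions, per_cond))
    th <- t(vapply(seq_len(spec$n_trials),
                   function(i) sample_orientations(spec$set_size, min_sep),
                   numeric(spec$set_size)))
    df <- data.frame(
      subject_id = s,
      experiment_id = spec$experiment_id,
      trial_index = seq_len(spec$n_trials),
      condition = cond,
      target_deg = th[, 1],
      nontarget1_deg = th[, 2]
    )
    if (spec$set_size == 3) df$nontarget2_deg <- th[, 3]
    df$response_deg <- NA_real_
    out[[s]] <- df
  }
  res <- do.call(rbind, out)
  attr(res, "design") <- spec
  attr(res, "seed") <- seed
  res
}

#' Generative mixture parameters
#'
#' Per-condition mixture weights and the shared report-noise dispersion used
#' to simulate responses: with probability `p_target` the response is the
#' target plus von Mises noise of circular SD `sd_deg` (doubled-angle
#' convention); with `p_nontarget`, a uniformly chosen nontarget plus the same
#' noise; with `p_guess`, uniform on `[0, 180)`.
#'
#' @param condition Character vector of condition labels.
#' @param p_target,p_nontarget,p_guess Mixture weights per condition; each row
#'   must sum to 1.
#' @param sd_deg Shared circular SD of the report noise, in orientation
#'   degrees.
#' @return A data frame of class `generative_params`.
#' @export
generative_params <- function(condition, p_target, p_nontarget, p_guess,
                              sd_deg) {
  df <- data.frame(condition = condition, p_target = p_target,
                   p_nontarget = p_nontarget, p_guess = p_guess,
                   sd_deg = sd_deg)
  bad <- abs(df$p_target + df$p_nontarget + df$p_guess - 1) > 1e-8 |
    df$p_target < 0 | df$p_nontarget < 0 | df$p_guess < 0
  if (any(bad)) stop("mixture weights must be nonnegative and sum to 1")
  if (any(df$sd_deg <= 0)) stop("sd_deg must be positive")
  class(df) <- c("generative_params", "data.frame")
  df
}

#' Default generative presets per experiment
#'
#' Condition-wise target probabilities back-solved from the published
#' subject-level condition means of the normalized (empirical-logit) target
#' probability, with the leftover mass split between nontarget and guess
#' responses and a dispersion in the range implied by the printed precision
#' means. These presets are approximations used to exercise the pipeline at a
#' realistic operating point; they are not ground truth for any dataset.
#'
#' @param experiment_id Integer 1-4.
#' @return A `generative_params` data frame.
#' @export
default_generative_params <- function(experiment_id) {
  presets <- list(
    `1` = list(cond = c("Leader", "Follower1"),
               p_t = c(0.979, 0.958), sd = 15),
    `2` = list(cond = c("Leader", "Follower1"),
               p_t = c(0.974, 0.964), sd = 14),
    `3` = list(cond = c("Leader", "Follower1", "Follower2"),
               p_t = c(0.964, 0.939, 0.932), sd = 19),
    `4` = list(cond = c("Leader", "Follower1", "Follower2"),
               p_t = c(0.984, 0.964, 0.941), sd = 16)
  )
  p <- presets[[as.character(experiment_id)]]
  if (is.null(p)) stop("unknown experiment_id: ", experiment_id)
  rest <- 1 - p$p_t
  generative_params(
    condition = p$cond,
    p_target = p$p_t,
    p_nontarget = rest / 2,
    p_guess = rest / 2,
    sd_deg = p$sd
  )
}

#' Simulate continuous-report responses
#'
#' Fills the `response_deg` column of a trial-stub table by component
#' sampling from the generative mixture: target report with von Mises noise,
#' swap to a random nontarget with the same noise, or a uniform guess.
#'
#' @param stubs Trial table from [build_design()] (or with the same columns).
#' @param params A `generative_params` table covering every condition present,
#'   or a per-subject list of such tables (names = subject ids) to simulate
#'   subject heterogeneity.
#' @param seed Master seed; per-subject streams derived from it.
#' @return The trial table with `response_deg` filled, in `[0, 180)`.
#' @examples
#' stubs <- build_design(1, n_subjects = 1, seed = 1)
#' trials <- simulate_responses(stubs, default_generative_params(1), seed = 2)
#' head(trials$response_deg)
#' @export
simulate_responses <- function(stubs, params, seed = NULL) {
  nt_cols <- grep("^nontarget[0-9]+_deg$", names(stubs), value = TRUE)
  if (!all(c("subject_id", "condition", "target_deg") %in% names(stubs)) ||
      length(nt_cols) == 0) {
    stop("stubs must carry subject_id, condition, target_deg and nontarget columns")
  }
  if (anyNA(stubs$target_deg) || anyNA(stubs[nt_cols])) {
    stop("stubs without orientations cannot be simulated")
  }
  per_subject <- is.list(params) && !inherits(params, "data.frame")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  subjects <- sort(unique(stubs$subject_id))
  seeds <- derive_seeds(seed, length(subjects))
  out <- stubs
  for (si in seq_along(subjects)) {
    set.seed(seeds[si])
    rows <- which(stubs$subject_id == subjects[si])
    par <- if (per_subject) params[[as.character(subjects[si])]] else params
    par <- as.data.frame(par)
    par$kappa <- sd_deg_to_kappa(par$sd_deg)
    for (i in rows) {
      p <- par[par$condition == stubs$condition[i], ]
      if (nrow(p) != 1) stop("no generative parameters for condition ",
                             stubs$condition[i])
      kappa <- p$kappa
      u <- stats::runif(1)
      if (u < p$p_target) {
        centre <- stubs$target_deg[i]
        resp <- centre + double_rad_to_deg(rvonmises(1, 0, kappa))
      } else if (u < p$p_target + p$p_nontarget) {
        nts <- unlist(stubs[i, nt_cols], use.names = FALSE)
        centre <- nts[sample.int(length(nts), 1)]
        resp <- centre + double_rad_to_deg(rvonmises(1, 0, kappa))
      } else {
        resp <- stats::runif(1, 0, 180)
      }
      out$response_deg[i] <- wrap_orientation(resp)
    }
  }
  attr(out, "design") <- attr(stubs, "design")
  out
}
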