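# End-to-end orchestration: design -> simulate (or ingest) -> exclude ->
# fit -> summarize -> test. A run is reproducible from its config and seed
# alone; every artifact is stamped with the config fingerprint and seed.

#' Run configuration
#'
#' @param experiment_id Integer 1-4.
#' @param n_subjects Number of simulated subjects (ignored when ingesting).
#' @param master_seed Seed driving every random stage.
#' @param params Generative parameters (default
#'   [default_generative_params()]); ignored when `input_path` is given.
#' @param input_path Optional path to an existing trial table to ingest
#'   instead of simulating.
#' @param col_map,sep Column mapping and separator for ingestion (see
#'   [read_trials()]).
#' @param exclusion_multiplier Subjects whose mean absolute response error
#'   deviates from the group mean by more than this many group SDs are
#'   excluded (default 2.5).
#' @param n_starts Mixture-fit restarts per subject x condition cell.
#' @param kappa_bounds Concentration bounds for the fits.
#' @param alpha Significance level for the inference stage.
#' @param prior_scale JZS Cauchy prior scale for Bayes factors.
#' @return A list of class `run_config`.
#' @export
run_config <- function(experiment_id, n_subjects = 30, master_seed = 1,
                       params = NULL, input_path = NULL, col_map = NULL,
                       sep = "\t", exclusion_multiplier = 2.5, n_starts = 20,
                       kappa_bounds = c(0.05, 200), alpha = 0.05,
                       prior_scale = sqrt(2) / 2) {
  spec <- design_spec(experiment_id, n_subjects)  # validates the id
  if (is.null(params)) params <- default_generative_params(experiment_id)
  structure(
    list(experiment_id = spec$experiment_id, n_subjects = n_subjects,
         master_seed = master_seed, params = params, input_path = input_path,
         col_map = col_map, sep = sep,
         exclusion_multiplier = exclusion_multiplier, n_starts = n_starts,
         kappa_bounds = kappa_bounds, alpha = alpha,
         prior_scale = prior_scale),
    class = "run_config"
  )
}

# Polynomial rolling hash over the deparsed config (exact in double
# arithmetic below 2^53): a short stable fingerprint for stamping artifacts,
# with no external hashing dependency.
config_fingerprint <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 127 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Exclude subjects with extreme memory performance
#'
#' Flags subjects whose exclusion statistic (by default the overall mean
#' absolute response error) deviates from the group mean by more than
#' `multiplier` group standard deviations.
#'
#' @param subject_stats Data frame with `subject_id` and `stat` columns
#'   (>= 3 subjects).
#' @param multiplier Deviation threshold in group SDs (default 2.5;
#'   `Inf` disables exclusion).
#' @return A list: `retained` subject ids, `excluded` data frame
#'   (`subject_id`, `stat`, `z`), and the `bounds` used.
#' @export
exclude_subjects <- function(subject_stats, multiplier = 2.5) {
  stopifnot(all(c("subject_id", "stat") %in% names(subject_stats)))
  if (nrow(subject_stats) < 3) stop("need at least 3 subjects")
  mu <- mean(subject_stats$stat)
  sigma <- stats::sd(subject_stats$stat)
  z <- if (sigma > 0) (subject_stats$stat - mu) / sigma else rep(0, nrow(subject_stats))
  out <- abs(z) > multiplier
  if (all(out)) stop("exclusion rule removed every subject")
  list(
    retained = subject_stats$subject_id[!out],
    excluded = data.frame(subject_id = subject_stats$subject_id[out],
                          stat = subject_stats$stat[out], z = z[out]),
    bounds = c(lower = mu - multiplier * sigma, upper = mu + multiplier * sigma)
  )
}

#' Subject x condition summaries for inference
#'
#' Joins the per-cell mixture fits with the empirical-logit normalized
#' target probability (`n` = trials per cell).
#'
#' @param fits Output of [fit_by_condition()].
#' @return The fit table with a `logit_p_target` column appended.
#' @export
summarize_conditions <- function(fits) {
  fits$logit_p_target <- empirical_logit(fits$p_target, fits$n_trials)
  fits
}

# Wide subject x condition matrix for one measure, conditions in design order.
measure_matrix <- function(summaries, measure, conditions) {
  subjects <- sort(unique(summaries$subject_id))
  mat <- sapply(conditions, function(cond) {
    rows <- summaries[summaries$condition == cond, ]
    rows[match(subjects, rows$subject_id), measure]
  })
  rownames(mat) <- subjects
  mat
}

#' Inference battery on condition summaries
#'
#' For each measure (`precision` and `logit_p_target`): with two conditions,
#' a paired t test (Leader vs Follower) with Cohen's d and JZS Bayes factor;
#' with three, a one-way repeated-measures ANOVA followed by all three
#' Holm-corrected post hoc paired contrasts, each with its (uncorrected)
#' Bayes factor.
#'
#' @param summaries Output of [summarize_conditions()].
#' @param conditions Ordered condition labels (default: those present, in
#'   design order Leader, Follower1, Follower2).
#' @param prior_scale JZS prior scale.
#' @param measures Measures to analyze.
#' @return A tidy results table: `measure`, `test_name`, `contrast`,
#'   `statistic`, `df1`, `df2`, `p_raw`, `p_holm`, `effect_size`, `bf10`.
#' @export
analyze_summaries <- function(summaries,
                              conditions = intersect(
                                c("Leader", "Follower1", "Follower2"),
                                unique(summaries$condition)),
                              prior_scale = sqrt(2) / 2,
                              measures = c("precision", "logit_p_target")) {
  out <- lapply(measures, function(measure) {
    mat <- measure_matrix(summaries, measure, conditions)
    if (length(conditions) == 2) {
      row <- paired_t(mat[, 1], mat[, 2],
                      contrast = paste(conditions, collapse = " vs "))
      row$bf10 <- jzs_bf_from_t(row$statistic, nrow(mat), prior_scale)
      res <- row
    } else {
      omnibus <- rm_anova_oneway(mat, contrast = "perturbation")
      pairs <- utils::combn(seq_along(conditions), 2, simplify = FALSE)
      posthoc <- do.call(rbind, lapply(pairs, function(ij) {
        row <- paired_t(mat[, ij[1]], mat[, ij[2]],
                        contrast = paste(conditions[ij], collapse = " vs "))
        row$bf10 <- jzs_bf_from_t(row$statistic, nrow(mat), prior_scale)
        row
      }))
      posthoc$p_holm <- holm_correct(posthoc$p_raw)
      res <- rbind(omnibus, posthoc)
    }
    cbind(measure = measure, res)
  })
  do.call(rbind, out)
}

#' Run the full pipeline
#'
#' Stage order: build or ingest the trial table, compute per-subject mean
#' absolute response error and apply the exclusion rule, fit the mixture
#' model per subject x condition, summarize (precision, target probability,
#' normalized target probability), and run the inference battery. When `out`
#' is given, artifacts are written there as tab-delimited text plus a
#' structured log, each stamped with the config fingerprint and seed.
#'
#' @param config A [run_config()].
#' @param out Optional output directory.
#' @return A list of class `pipeline_result`: `trials`, `exclusions`,
#'   `fits`, `summaries`, `stats`, `log` (character vector),
#'   `fingerprint`.
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(1, n_subjects = 8, master_seed = 1,
#'                                n_starts = 5))
#' res$stats
#' }
#' @export
run_pipeline <- function(config, out = NULL) {
  stopifnot(inherits(config, "run_config"))
  fp <- config_fingerprint(config)
  log <- character()
  note <- function(...) {
    line <- sprintf("[%s seed=%d] %s", fp, config$master_seed, sprintf(...))
    log <<- c(log, line)
    line
  }
  seeds <- derive_seeds(config$master_seed, 4)

  if (is.null(config$input_path)) {
    stubs <- build_design(config$experiment_id, config$n_subjects,
                          seed = seeds[1])
    trials <- simulate_responses(stubs, config$params, seed = seeds[2])
    note("simulate: experiment %d, %d subjects x %d trials",
         config$experiment_id, config$n_subjects, nrow(trials) / config$n_subjects)
  } else {
    trials <- read_trials(config$input_path, col_map = config$col_map,
                          sep = config$sep)
    note("ingest: %s (%d rows, %d subjects)", config$input_path, nrow(trials),
         length(unique(trials$subject_id)))
  }

  err <- abs(response_error(trials$response_deg, trials$target_deg))
  subject_stats <- stats::aggregate(err, list(subject_id = trials$subject_id),
                                    mean)
  names(subject_stats)[2] <- "stat"
  excl <- exclude_subjects(subject_stats, config$exclusion_multiplier)
  if (nrow(excl$excluded) > 0) {
    for (i in seq_len(nrow(excl$excluded))) {
      note("exclude: subject %s, mean |error| = %.2f deg (z = %.2f, multiplier %.1f)",
           excl$excluded$subject_id[i], excl$excluded$stat[i],
           excl$excluded$z[i], config$exclusion_multiplier)
    }
  } else {
    note("exclude: none beyond %.1f SD", config$exclusion_multiplier)
  }
  kept <- trials[trials$subject_id %in% excl$retained, ]

  fits <- fit_by_condition(kept, n_starts = config$n_starts, seed = seeds[3],
                           kappa_bounds = config$kappa_bounds)
  note("fit: %d subject x condition cells, %d converged", nrow(fits),
       sum(fits$converged))
  summaries <- summarize_conditions(fits)
  stats_tab <- analyze_summaries(summaries, prior_scale = config$prior_scale)
  note("analyze: %d test rows", nrow(stats_tab))

  res <- structure(
    list(trials = trials, exclusions = excl, fits = fits,
         summaries = summaries, stats = stats_tab, log = log,
         fingerprint = fp),
    class = "pipeline_result"
  )
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("# config %s seed %d", fp, config$master_seed)
    wt <- function(df, file) {
      path <- file.path(out, file)
      con <- file(path, "w")
      writeLines(stamp, con)
      utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
      close(con)
    }
    wt(trials, "trials.tsv")
    wt(fits, "fits.tsv")
    wt(summaries, "summaries.tsv")
    wt(stats_tab, "stats.tsv")
    writeLines(log, file.path(out, "run_log.txt"))
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s: %d trials, %d fits, %d excluded subjects\n",
              x$fingerprint, nrow(x$trials), nrow(x$fits),
              nrow(x$exclusions$excluded)))
  print(x$stats, digits = 4)
  invisible(x)
}
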