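# Measurement transform and the inferential battery.
#
# Subject-level condition summaries (precision, target probability and its
# empirical-logit normalization) feed paired t tests with Cohen's d, one-way
# repeated-measures or mixed-design ANOVA with partial eta squared, Holm
# correction for post hoc contrasts, default-prior (JZS) Bayes factors for
# paired contrasts, and a-priori power analysis for paired designs.

#' Empirical logit transform
#'
#' Finite-sample log-odds of a proportion:
#' `ln((p + 1/(2n)) / (1 - p + 1/(2n)))`. The `1/(2n)` shrinkage keeps the
#' transform finite at `p = 0` and `p = 1`, and vanishes as `n` grows. Used
#' to normalize fitted target probabilities (which are skewed near 1) before
#' parametric tests.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @param n Number of observations behind each proportion (>= 1); here the
#'   per-cell trial count (96 for two-item designs, 54 for three-item ones).
#' @return The transformed value(s).
#' @export
empirical_logit <- function(p, n) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  if (any(n < 1)) stop("n must be >= 1")
  log((p + 1 / (2 * n)) / (1 - p + 1 / (2 * n)))
}

# Tidy one-row results table shared by all tests.
stat_row <- function(test_name, contrast, statistic, df1, df2 = NA_real_,
                     p_raw, effect_size, bf10 = NA_real_) {
  data.frame(test_name = test_name, contrast = contrast,
             statistic = statistic, df1 = df1, df2 = df2, p_raw = p_raw,
             p_holm = NA_real_, effect_size = effect_size, bf10 = bf10)
}

#' Two-sided paired t test with Cohen's d
#'
#' @param x,y Paired per-subject values (equal length >= 3).
#' @param contrast Label for the results row.
#' @return A one-row data frame: `test_name`, `contrast`, `statistic`
#'   (t), `df1`, `p_raw`, `effect_size` (Cohen's d for paired data,
#'   `mean(x - y) / sd(x - y)`).
#' @export
paired_t <- function(x, y, contrast = "x vs y") {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must be paired vectors of equal length >= 3")
  }
  d <- x - y
  if (stats::sd(d) < .Machine$double.eps) {
    stop("zero-variance differences: paired t test undefined")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  stat_row("paired_t", contrast, unname(tt$statistic), unname(tt$parameter),
           NA_real_, tt$p.value, mean(d) / stats::sd(d))
}

# Long-format helper for ANOVA: a complete subject x condition matrix.
check_matrix <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells: complete data required (no imputation)")
  if (ncol(values) < 2 || nrow(values) < 3) {
    stop("need >= 2 conditions and >= 3 subjects")
  }
  values
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject F test with `(k - 1, (k - 1)(n - 1))` degrees of freedom,
#' fitted via `stats::aov` with a subject error stratum, plus partial eta
#' squared `SS_effect / (SS_effect + SS_error)`. With two conditions the F
#' statistic equals the square of the paired t statistic.
#'
#' @param values Complete numeric subject x condition matrix.
#' @param contrast Label for the results row.
#' @return A one-row data frame with `statistic` (F), `df1`, `df2`, `p_raw`
#'   and `effect_size` (partial eta squared).
#' @export
rm_anova_oneway <- function(values, contrast = "condition") {
  values <- check_matrix(values)
  n <- nrow(values)
  k <- ncol(values)
  long <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    condition = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(y ~ condition + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ss_eff <- tab["condition", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  if (ss_eff < 1e-12 && ss_err < 1e-12) {
    # all cells equal: no condition variance at all
    return(stat_row("rm_anova", contrast, 0, k - 1, (k - 1) * (n - 1), 1, 0))
  }
  stat_row("rm_anova", contrast, tab["condition", "F value"],
           tab["condition", "Df"], tab["Residuals", "Df"],
           tab["condition", "Pr(>F)"], ss_eff / (ss_eff + ss_err))
}

#' Mixed-design (split-plot) ANOVA
#'
#' Two-group between factor crossed with a within-subject condition factor on
#' a balanced design: the between effect is tested against the
#' between-subject residual, the within effect and the interaction against
#' the within-subject residual. Partial eta squared accompanies each F.
#'
#' @param values Complete subject x condition matrix (subjects from both
#'   groups stacked).
#' @param group Per-subject group labels (exactly two levels).
#' @return A three-row data frame: between effect, within effect,
#'   interaction.
#' @export
mixed_anova <- function(values, group) {
  values <- check_matrix(values)
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (length(group) != nrow(values)) stop("one group label per subject required")
  if (length(unique(table(group))) != 1) {
    stop("unbalanced groups rejected: equal group sizes required")
  }
  n <- nrow(values)
  k <- ncol(values)
  long <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n), times = k)),
    condition = factor(rep(seq_len(k), each = n)),
    group = rep(group, times = k)
  )
  fit <- stats::aov(y ~ group * condition + Error(subject), data = long)
  s <- summary(fit)
  btab <- s[["Error: subject"]][[1]]
  wtab <- s[["Error: Within"]][[1]]
  peta <- function(tab, term) {
    ss <- tab[term, "Sum Sq"]
    ss / (ss + tab["Residuals", "Sum Sq"])
  }
  fv <- function(tab, term) {
    if (tab[term, "Sum Sq"] < 1e-12) 0 else tab[term, "F value"]
  }
  pv <- function(tab, term) {
    if (tab[term, "Sum Sq"] < 1e-12) 1 else tab[term, "Pr(>F)"]
  }
  rbind(
    stat_row("mixed_anova", "group (between)", fv(btab, "group"),
             btab["group", "Df"], btab["Residuals", "Df"],
             pv(btab, "group"), peta(btab, "group")),
    stat_row("mixed_anova", "condition (within)", fv(wtab, "condition"),
             wtab["condition", "Df"], wtab["Residuals", "Df"],
             pv(wtab, "condition"), peta(wtab, "condition")),
    stat_row("mixed_anova", "group x condition", fv(wtab, "group:condition"),
             wtab["group:condition", "Df"], wtab["Residuals", "Df"],
             pv(wtab, "group:condition"), peta(wtab, "group:condition"))
  )
}

#' Holm step-down correction
#'
#' Step-down familywise-error adjustment (via `stats::p.adjust`); order is
#' preserved, tied raw p values receive identical adjusted values, and
#' adjusted values never fall below the raw ones.
#'
#' @param p_values Raw p values in `[0, 1]`.
#' @return Adjusted p values in the input order.
#' @export
holm_correct <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value list")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}

# JZS Bayes factor from a t statistic (Rouder et al. default prior: Cauchy
# with scale r on standardized effect size, i.e. g ~ InverseGamma(1/2, r^2/2)
# on the Zellner-Siow g). BF10 = marginal likelihood under H1 / under H0.
jzs_bf_from_t <- function(t, n, prior_scale = sqrt(2) / 2) {
  nu <- n - 1
  h0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      (prior_scale^2 / 2)^(1 / 2) / gamma(1 / 2) *
      g^(-3 / 2) * exp(-prior_scale^2 / (2 * g))
  }
  h1 <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)
  if (!is.finite(h1$value) || h1$value <= 0) {
    stop("JZS integral failed: value = ", h1$value,
         ", abs.error = ", h1$abs.error)
  }
  h1$value / h0
}

#' JZS Bayes factor for a paired contrast
#'
#' Default-prior Bayes factor `BF10` for the paired t contrast: a Cauchy
#' prior with scale `prior_scale` on the standardized effect size under the
#' alternative, computed by numerical integration over the Zellner-Siow `g`.
#' `BF10 > 1` favours the presence of the effect; `BF10 < 1` favours the
#' null.
#'
#' @param x,y Paired samples, as in [paired_t()].
#' @param prior_scale Cauchy prior scale (default `sqrt(2)/2`, the common
#'   software default).
#' @return The Bayes factor `BF10` (a positive scalar).
#' @export
jzs_bf_paired <- function(x, y, prior_scale = sqrt(2) / 2) {
  res <- paired_t(x, y)
  jzs_bf_from_t(res$statistic, length(x), prior_scale)
}

#' Power of the two-sided paired t test
#'
#' Exact power from the noncentral t distribution: with `n` pairs and
#' standardized effect `d`, the test statistic is noncentral t with
#' noncentrality `d * sqrt(n)` and `n - 1` degrees of freedom.
#'
#' @param n Number of pairs (>= 2).
#' @param d Cohen's d for the paired differences.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
power_paired_t <- function(n, d, alpha = 0.05) {
  stopifnot(n >= 2)
  tc <- stats::qt(1 - alpha / 2, df = n - 1)
  ncp <- d * sqrt(n)
  1 - stats::pt(tc, df = n - 1, ncp = ncp) +
    stats::pt(-tc, df = n - 1, ncp = ncp)
}

#' A-priori sample size for a paired design
#'
#' Smallest number of pairs for which the two-sided paired t test reaches the
#' target power at the given effect size, from the noncentral t power curve.
#'
#' @param effect_d Cohen's d (> 0).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param n_max Search cap; exceeding it raises an error.
#' @return The minimal `n` (integer).
#' @examples
#' required_sample_size(0.55, 0.05, 0.8)  # 28
#' @export
required_sample_size <- function(effect_d, alpha = 0.05, power = 0.8,
                                 n_max = 1e6) {
  stopifnot(effect_d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in 2:n_max) {
    if (power_paired_t(n, effect_d, alpha) >= power) return(as.integer(n))
  }
  stop("target power ", power, " not attainable within n <= ", n_max)
}
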