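#' Group summary of a per-patient percentage endpoint
#'
#' @param n Patient count (>= 2).
#' @param mean Endpoint mean (%).
#' @param sd Endpoint standard deviation (%).
#' @return A list of class `group_summary`.
#' @export
#' @examples
#' group_summary(11, 84.53, 11.05)
group_summary <- function(n, mean, sd) {
  if (!is.numeric(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' Summarize a raw per-patient endpoint vector
#'
#' @param x Per-patient endpoint percentages.
#' @return A [group_summary()].
#' @export
summarize_arm <- function(x) {
  if (length(x) < 2) stop("arm needs >= 2 patients", call. = FALSE)
  group_summary(length(x), mean(x), stats::sd(x))
}

#' Pooled-variance two-sample confidence interval from summaries
#'
#' Student's two-sample t interval with pooled variance, computed directly
#' from `(n, mean, sd)` summaries:
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`,
#' `se = sp * sqrt(1/n1 + 1/n2)`, `df = n1+n2-2`,
#' `CI = diff +/- t_{(1+level)/2, df} * se`. Identical to
#' `t.test(var.equal = TRUE)` on any raw samples with the same moments.
#'
#' @param a,b [group_summary()] objects (difference is `a - b`).
#' @param level Two-sided confidence level. Default 0.95.
#' @return List with `diff`, `se`, `df`, `ci_lower`, `ci_upper`, `level`.
#' @export
#' @examples
#' pooled_t_ci(group_summary(11, 8.67, 5.87), group_summary(9, 20.62, 16.39))
pooled_t_ci <- function(a, b, level = 0.95) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$n < 2 || b$n < 2) stop("both groups need n >= 2", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2) * sqrt(1 / a$n + 1 / b$n)
  diff <- a$mean - b$mean
  tc <- stats::qt((1 + level) / 2, df)
  list(diff = diff, se = se, df = df,
       ci_lower = diff - tc * se, ci_upper = diff + tc * se, level = level)
}

#' Non-inferiority t test from group summaries
#'
#' Shifts the null hypothesis by the margin in the unfavorable direction and
#' applies a one-sided pooled-variance t test. For a higher-is-better
#' endpoint the test arm is non-inferior when its deficit is demonstrably
#' smaller than the margin: `t = (diff + margin) / se` with
#' `diff = test - reference`, one-sided p from the t distribution on
#' `n1 + n2 - 2` degrees of freedom, rejection at one-sided alpha
#' `(1 - level) / 2` (0.025 at the default level), equivalently the
#' one-sided 97.5% lower confidence limit of `diff` exceeding `-margin`.
#' For lower-is-better endpoints the shift and tail are mirrored.
#'
#' @param a Test-arm [group_summary()].
#' @param b Reference-arm [group_summary()].
#' @param margin Non-inferiority margin (positive, percentage points).
#'   Default 10.
#' @param direction `"higher-is-better"` (e.g. adequate time) or
#'   `"lower-is-better"` (e.g. hypotension time).
#' @param level Two-sided confidence level of the reported CI. Default 0.95.
#' @return A list of class `noninferiority_result`: `difference`, `se`,
#'   `df`, `t_stat`, `p_one_sided`, `ci_lower`, `ci_upper`, `margin`,
#'   `direction`, `conclusion` (TRUE when non-inferior).
#' @export
#' @examples
#' noninferiority_test(group_summary(11, 84.53, 11.05),
#'                     group_summary(9, 72.45, 14.93), margin = 10)
noninferiority_test <- function(a, b, margin = 10,
                                direction = c("higher-is-better",
                                              "lower-is-better"),
                                level = 0.95) {
  direction <- match.arg(direction)
  if (!is.numeric(margin) || margin <= 0)
    stop("margin must be positive", call. = FALSE)
  ci <- pooled_t_ci(a, b, level)
  alpha <- (1 - level) / 2
  if (direction == "higher-is-better") {
    t_stat <- (ci$diff + margin) / ci$se
    p <- stats::pt(t_stat, ci$df, lower.tail = FALSE)
    concl <- ci$ci_lower > -margin
  } else {
    t_stat <- (ci$diff - margin) / ci$se
    p <- stats::pt(t_stat, ci$df)
    concl <- ci$ci_upper < margin
  }
  structure(list(difference = ci$diff, se = ci$se, df = ci$df,
                 t_stat = t_stat, p_one_sided = p,
                 ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
                 margin = margin, direction = direction,
                 conclusion = unname(concl), level = level),
            class = "noninferiority_result")
}

#' @export
print.noninferiority_result <- function(x, ...) {
  cat(sprintf(
    "Non-inferiority t test (pooled variance, df = %d, %s)\n", x$df,
    x$direction))
  cat(sprintf("  difference: %.2f%%  (%.0f%% CI %.2f to %.2f)\n",
              x$difference, 100 * x$level, x$ci_lower, x$ci_upper))
  cat(sprintf("  margin: %.1f%%  t = %.3f  one-sided p = %.4g\n",
              x$margin, x$t_stat, x$p_one_sided))
  cat(sprintf("  conclusion: %s\n",
              if (x$conclusion) "non-inferior" else "not demonstrated"))
  invisible(x)
}

#' Compare two arms from raw per-patient endpoints
#'
#' Summarizes each arm, runs [noninferiority_test()], and returns the
#' empirical cumulative-probability coordinates used for distribution plots.
#'
#' @param test,reference Per-patient endpoint percentages (length >= 2).
#' @param margin Non-inferiority margin. Default 10.
#' @param direction See [noninferiority_test()].
#' @param level Confidence level. Default 0.95.
#' @return List with `result` (a `noninferiority_result`), `summaries`
#'   (list of two [group_summary()]), and `cumprob` (data frame `arm, value,
#'   prob` of the per-arm empirical CDF).
#' @export
endpoint_compare <- function(test, reference, margin = 10,
                             direction = c("higher-is-better",
                                           "lower-is-better"),
                             level = 0.95) {
  direction <- match.arg(direction)
  if (length(test) < 2 || length(reference) < 2)
    stop("each arm needs >= 2 patients", call. = FALSE)
  a <- summarize_arm(test)
  b <- summarize_arm(reference)
  cp <- function(x, arm) {
    xs <- sort(x)
    data.frame(arm = arm, value = xs, prob = seq_along(xs) / length(xs))
  }
  list(result = noninferiority_test(a, b, margin, direction, level),
       summaries = list(test = a, reference = b),
       cumprob = rbind(cp(test, "test"), cp(reference, "reference")))
}

#' Normal-approximation sample size for a non-inferiority comparison
#'
#' The standard two-sample normal-approximation size per arm for a
#' non-inferiority t test,
#' `n = (z_{1-alpha} + z_{power})^2 * 2 * sd^2 / (margin + true_diff)^2`
#' (with `true_diff` signed so that 0 means truly equal arms), inflated for
#' dropout by `1 / (1 - dropout)` and rounded up. Requires the planner's
#' assumed SD and true difference; it is a planning aid, not a recovery of
#' any particular trial's enrolment.
#'
#' @param power Target power in (0, 1).
#' @param margin Non-inferiority margin (> 0).
#' @param sd Assumed common SD of the endpoint.
#' @param true_diff Assumed true difference (test - reference), default 0.
#' @param alpha One-sided significance level. Default 0.025.
#' @param dropout Expected dropout fraction in \\[0, 1). Default 0.
#' @return List with `n_per_arm`, `n_per_arm_inflated`, `n_total_inflated`
#'   and the assumptions echoed back.
#' @export
#' @examples
#' sample_size_note(power = 0.9, margin = 10, sd = 10, dropout = 0.2)
sample_size_note <- function(power, margin, sd, true_diff = 0,
                             alpha = 0.025, dropout = 0) {
  if (!is.numeric(power) || power <= 0 || power >= 1)
    stop("power must be in (0,1)", call. = FALSE)
  stopifnot(margin > 0, sd > 0, dropout >= 0, dropout < 1,
            alpha > 0, alpha < 1, margin + true_diff > 0)
  za <- stats::qnorm(1 - alpha)
  zb <- stats::qnorm(power)
  n <- (za + zb)^2 * 2 * sd^2 / (margin + true_diff)^2
  n_raw <- ceiling(n)
  n_infl <- ceiling(n / (1 - dropout))
  list(n_per_arm = n_raw, n_per_arm_inflated = n_infl,
       n_total_inflated = 2 * n_infl,
       assumptions = list(power = power, margin = margin, sd = sd,
                          true_diff = true_diff, alpha = alpha,
                          dropout = dropout))
}

#' Example group summaries from a clinical evaluation of automated versus
#' manual phenylephrine dosing
#'
#' Published per-arm summary statistics (n, mean %, SD %) for four
#' percentage-of-time endpoints from a 20-patient two-arm comparison of
#' automated lower-limit phenylephrine delivery against manual dosing:
#' adequate blood-pressure time (higher is better), abnormal-hypotension
#' time and hypertension time (lower is better), and adequate-anesthesia
#' time (higher is better). These are the canonical worked-example inputs
#' for [noninferiority_test()] and [pooled_t_ci()].
#'
#' @return Nested list: one element per endpoint, each holding `automated`
#'   and `manual` [group_summary()] objects plus the endpoint's `direction`.
#' @export
#' @examples
#' s <- example_trial_summaries()
#' noninferiority_test(s$adequate_bp$automated, s$adequate_bp$manual)
example_trial_summaries <- function() {
  list(
    adequate_bp = list(automated = group_summary(11, 84.53, 11.05),
                       manual = group_summary(9, 72.45, 14.93),
                       direction = "higher-is-better"),
    hypotension = list(automated = group_summary(11, 8.67, 5.87),
                       manual = group_summary(9, 20.62, 16.39),
                       direction = "lower-is-better"),
    hypertension = list(automated = group_summary(11, 6.80, 9.86),
                        manual = group_summary(9, 6.93, 8.22),
                        direction = "lower-is-better"),
    adequate_anesthesia = list(automated = group_summary(11, 87.35, 10.59),
                               manual = group_summary(9, 78.73, 17.72),
                               direction = "higher-is-better")
  )
}

#' Observed consecutive-hypotension run counts from the same evaluation
#'
#' Counts of maximal consecutive abnormal-hypotension runs by length
#' (single, double, triple, four-or-more) observed in each arm of the
#' clinical evaluation, for use with run-share arithmetic
#' (see [tabulate_runs()]).
#'
#' @return List with integer vectors `manual` and `automated`, each named
#'   `1`, `2`, `3`, `>=4`.
#' @export
#' @examples
#' example_run_counts()$manual
example_run_counts <- function() {
  list(manual = c(`1` = 29L, `2` = 13L, `3` = 3L, `>=4` = 8L),
       automated = c(`1` = 34L, `2` = 4L, `3` = 4L, `>=4` = 0L))
}

#' Run-share percentages from run counts
#'
#' Converts run counts by length into shares of all runs, exact and
#' round-half-up integer.
#'
#' @param counts Named integer vector of run counts (as from
#'   [tabulate_runs()]`$counts` or [example_run_counts()]).
#' @return List with `share_pct` and `share_pct_rounded`.
#' @export
#' @examples
#' run_shares(example_run_counts()$manual)
run_shares <- function(counts) {
  n <- sum(counts)
  if (n == 0) stop("no runs to share", call. = FALSE)
  share <- 100 * counts / n
  list(share_pct = share, share_pct_rounded = floor(share + 0.5))
}
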