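#' Paired two-sided t-test with effect size and Bayes factor
#'
#' Two-sided paired t-test on `scores_a - scores_b` with `df = n - 1`,
#' Cohen's d for paired data (mean difference divided by the standard
#' deviation of the differences), a 95% confidence interval for d obtained
#' by inverting the noncentral t distribution, and the default JZS Bayes
#' factor ([jzs_bayes_factor()]).
#'
#' @param scores_a,scores_b Numeric vectors of equal length (>= 2), paired
#'   by position.
#' @param bayes Compute the Bayes factor? (Set `FALSE` in tight simulation
#'   loops; the BF requires numerical integration.)
#' @return An object of class `game_test_result`: a list with
#'   `t_statistic`, `df`, `p_value`, `cohens_d`, `d_ci_low`, `d_ci_high`,
#'   `bf10`, `n` and `method`.
#' @export
paired_t <- function(scores_a, scores_b, bayes = TRUE) {
  if (length(scores_a) != length(scores_b)) {
    stop2("validation", "paired samples must have equal length")
  }
  n <- length(scores_a)
  if (n < 2L) stop2("validation", "need at least 2 pairs")
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    stop2("degenerate_input", "differences have zero variance; the paired t is undefined")
  }
  ht <- stats::t.test(scores_a, scores_b, paired = TRUE)
  tstat <- unname(ht$statistic)
  df <- unname(ht$parameter)
  cohen <- mean(d) / stats::sd(d)
  ci <- d_confidence_interval(tstat, df, scale = 1 / sqrt(n))
  new_test_result(tstat, df, unname(ht$p.value), cohen, ci,
                  bf10 = if (bayes) jzs_bayes_factor(tstat, n) else NA_real_,
                  n = n, method = "paired t")
}

#' Welch two-sample two-sided t-test
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees
#' of freedom (non-integer in general). Cohen's d uses the pooled standard
#' deviation; its confidence interval inverts the noncentral t with the
#' two-sample noncentrality scale, which is exact under equal variances
#' and approximate otherwise. The Bayes factor uses the effective sample
#' size `n1 * n2 / (n1 + n2)`.
#'
#' @inheritParams paired_t
#' @return A `game_test_result` (see [paired_t()]).
#' @export
welch_t <- function(scores_a, scores_b, bayes = TRUE) {
  n1 <- length(scores_a); n2 <- length(scores_b)
  if (n1 < 2L || n2 < 2L) stop2("validation", "need at least 2 observations per sample")
  if (stats::sd(scores_a) == 0 && stats::sd(scores_b) == 0) {
    stop2("degenerate_input", "both samples have zero variance")
  }
  ht <- stats::t.test(scores_a, scores_b, var.equal = FALSE)
  tstat <- unname(ht$statistic)
  df <- unname(ht$parameter)
  sp <- sqrt(((n1 - 1) * stats::var(scores_a) + (n2 - 1) * stats::var(scores_b)) /
               (n1 + n2 - 2))
  cohen <- (mean(scores_a) - mean(scores_b)) / sp
  scale <- sqrt(1 / n1 + 1 / n2)
  ci <- d_confidence_interval(cohen / scale, n1 + n2 - 2, scale = scale)
  neff <- n1 * n2 / (n1 + n2)
  new_test_result(tstat, df, unname(ht$p.value), cohen, ci,
                  bf10 = if (bayes) jzs_bayes_factor(tstat, neff, df = df) else NA_real_,
                  n = c(n1, n2), method = "Welch t")
}

new_test_result <- function(t, df, p, d, ci, bf10, n, method) {
  structure(list(t_statistic = t, df = df, p_value = p, cohens_d = d,
                 d_ci_low = ci[1], d_ci_high = ci[2], bf10 = bf10,
                 n = n, method = method),
            class = "game_test_result")
}

#' @export
print.game_test_result <- function(x, ...) {
  cat(sprintf("%s: t(%.4g) = %.3f, p = %.3g, d = %.3f [%.3f, %.3f]",
              x$method, x$df, x$t_statistic, x$p_value, x$cohens_d,
              x$d_ci_low, x$d_ci_high))
  if (is.finite(x$bf10)) cat(sprintf(", BF10 = %.3g", x$bf10))
  cat("\n")
  invisible(x)
}

# 95% CI for Cohen's d by inverting the noncentral t distribution:
# find noncentrality parameters whose upper/lower tail at the observed t
# equal 2.5%, then rescale (ncp = d / scale)
d_confidence_interval <- function(tstat, df, scale, level = 0.95) {
  alpha <- (1 - level) / 2
  pt_ncp <- function(ncp) suppressWarnings(stats::pt(tstat, df, ncp = ncp))
  bound <- function(target) {
    f <- function(ncp) pt_ncp(ncp) - target
    lo <- tstat - 10 - 10 * abs(tstat)
    hi <- tstat + 10 + 10 * abs(tstat)
    stats::uniroot(f, c(lo, hi), extendInt = "downX", tol = 1e-8)$root
  }
  c(bound(1 - alpha), bound(alpha)) * scale
}

#' Default JZS Bayes factor for a t statistic
#'
#' Evidence ratio BF10 of a two-sided Bayesian t-test with a
#' Jeffreys-Zellner-Siow prior: a Cauchy prior with scale `r` on the
#' standardized effect size and the Jeffreys prior on the variance. The
#' marginal likelihood under the alternative is the noncentral t density
#' averaged over the Cauchy prior, evaluated by adaptive quadrature
#' (relative tolerance `1e-6`); the null likelihood is the central t
#' density. The default scale is `sqrt(2)/2`.
#'
#' For a paired/one-sample design pass the number of pairs `n`
#' (`df = n - 1`); for two-sample designs pass the effective sample size
#' and the corresponding `df`.
#'
#' @param t_statistic Observed t statistic (finite).
#' @param n (Effective) sample size, >= 2.
#' @param scale Cauchy prior scale on the standardized effect.
#' @param df Degrees of freedom; defaults to `n - 1`.
#' @return BF10 (> 0): evidence for the alternative over the null.
#' @examples
#' jzs_bayes_factor(3.34, 288) # about 14.9
#' @export
jzs_bayes_factor <- function(t_statistic, n, scale = sqrt(2) / 2, df = n - 1) {
  if (!is.finite(t_statistic)) stop2("validation", "`t_statistic` must be finite")
  if (!is.numeric(n) || n < 2) stop2("validation", "`n` must be >= 2")
  marginal <- stats::integrate(
    function(delta) {
      suppressWarnings(stats::dt(t_statistic, df, ncp = delta * sqrt(n))) *
        stats::dcauchy(delta, 0, scale)
    },
    -Inf, Inf, rel.tol = 1e-6
  )$value
  marginal / stats::dt(t_statistic, df)
}

#' @rdname jzs_bayes_factor
#' @return For `jzs_bayes_factor_01`: BF01, the reciprocal evidence for
#'   the null over the alternative.
#' @export
jzs_bayes_factor_01 <- function(t_statistic, n, scale = sqrt(2) / 2, df = n - 1) {
  1 / jzs_bayes_factor(t_statistic, n, scale = scale, df = df)
}
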