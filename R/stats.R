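#' Cohen's d from group summaries, with 95% CI
#'
#' Pooled two-group convention: `d = (mean_a - mean_b) / sqrt((sd_a^2 +
#' sd_b^2) / 2)`.  The default confidence interval uses the large-sample
#' normal approximation `d +/- 1.96 * SE` with
#' `SE = sqrt((n_a + n_b)/(n_a n_b) + d^2 / (2 (n_a + n_b)))`; a
#' noncentral-t interval is available via `ci_method = "noncentral"` (the
#' two differ by ~1% for large d).
#'
#' @param mean_a,sd_a,mean_b,sd_b group summaries (`sd >= 0`).
#' @param n_a,n_b group sizes (>= 2); `n_b` defaults to `n_a`.
#' @param ci_method `"normal"` (default) or `"noncentral"`.
#' @return list: `d`, `ci` (length 2), `se` (normal method only).
#' @examples
#' cohens_d_pooled(23.1, 3.6, 21.5, 3.0, 15)$d  # 0.48
#' @export
cohens_d_pooled <- function(mean_a, sd_a, mean_b, sd_b, n_a, n_b = n_a,
                            ci_method = c("normal", "noncentral")) {
  ci_method <- match.arg(ci_method)
  stopifnot(sd_a >= 0, sd_b >= 0, n_a >= 2, n_b >= 2)
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  if (pooled == 0) {
    if (mean_a == mean_b) return(list(d = 0, ci = c(0, 0), se = 0))
    d <- sign(mean_a - mean_b) * Inf
    return(list(d = d, ci = c(d, d), se = Inf))
  }
  d <- (mean_a - mean_b) / pooled
  if (ci_method == "normal") {
    se <- sqrt((n_a + n_b) / (n_a * n_b) + d^2 / (2 * (n_a + n_b)))
    return(list(d = d, ci = d + c(-1, 1) * 1.96 * se, se = se))
  }
  # noncentral-t interval on the ncp of t = d * sqrt(n_a n_b / (n_a + n_b))
  mult <- sqrt(n_a * n_b / (n_a + n_b))
  df <- n_a + n_b - 2
  t_obs <- d * mult
  ncp_bound <- function(target_p) {
    # pt() flags reduced precision for noncentral tails; ~1e-6 is ample here
    f <- function(ncp) suppressWarnings(stats::pt(t_obs, df, ncp)) - target_p
    lo <- t_obs - 10 * (1 + abs(t_obs)); hi <- t_obs + 10 * (1 + abs(t_obs))
    stats::uniroot(f, c(lo, hi), extendInt = "downX", tol = 1e-9)$root
  }
  ci <- c(ncp_bound(0.975), ncp_bound(0.025)) / mult
  list(d = d, ci = ci, se = NA_real_)
}

#' Confidence interval of a mean difference (paired, t distribution)
#'
#' @param mean_diff,sd_diff summary of the paired differences.
#' @param n number of pairs (>= 2).
#' @param level confidence level (default 0.95).
#' @return length-2 interval.
#' @examples
#' paired_diff_ci(18.2, 3.0, 15)  # [16.5, 19.9]
#' @export
paired_diff_ci <- function(mean_diff, sd_diff, n, level = 0.95) {
  stopifnot(n >= 2, sd_diff >= 0)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  mean_diff + c(-1, 1) * tq * sd_diff / sqrt(n)
}

#' Paired comparison of two wear measures across the cohort
#'
#' Two-sided paired t-test on `a - b`, the t-based CI of the mean
#' difference, and Cohen's d (pooled two-group convention) with its 95% CI.
#' Degenerate all-equal pairs return difference 0, d = 0, p = 1.
#'
#' @param values_a,values_b equal-length paired numeric vectors (n >= 2);
#'   `a` is the control/reference group in the reported sign convention.
#' @param label_a,label_b group labels.
#' @param ci_method passed to [cohens_d_pooled()].
#' @return one-row data.frame of class `comparison_result`: group means and
#'   SDs, `mean_diff`, `sd_diff`, `diff_lo`, `diff_hi`, `d`, `d_lo`, `d_hi`,
#'   `p_value`, `n`.
#' @export
paired_comparison <- function(values_a, values_b, label_a = "A", label_b = "B",
                              ci_method = "normal") {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length")
  n <- length(values_a)
  if (n < 2) stop("need at least 2 pairs")
  stopifnot(all(is.finite(values_a)), all(is.finite(values_b)))
  diffs <- values_a - values_b
  mean_diff <- mean(diffs); sd_diff <- stats::sd(diffs)
  if (sd_diff == 0) {
    p <- if (mean_diff == 0) 1 else 0
    ci <- c(mean_diff, mean_diff)
  } else {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    p <- tt$p.value
    ci <- paired_diff_ci(mean_diff, sd_diff, n)
  }
  dd <- cohens_d_pooled(mean(values_a), stats::sd(values_a),
                        mean(values_b), stats::sd(values_b), n, n,
                        ci_method = ci_method)
  out <- data.frame(group_a = label_a, group_b = label_b,
                    mean_a = mean(values_a), sd_a = stats::sd(values_a),
                    mean_b = mean(values_b), sd_b = stats::sd(values_b),
                    mean_diff = mean_diff, sd_diff = sd_diff,
                    diff_lo = ci[1], diff_hi = ci[2],
                    d = dd$d, d_lo = dd$ci[1], d_hi = dd$ci[2],
                    p_value = p, n = n, stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over [stats::shapiro.test()] with the usual sample-size
#' limits and an explicit rejection of constant samples.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) stop("constant sample: zero variance")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Simple linear regression with coefficient of determination
#'
#' Ordinary least squares `y ~ x`; R2 equals the squared Pearson
#' correlation.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @param label optional descriptor carried into the output row.
#' @return one-row data.frame of class `regression_result`: `slope`,
#'   `intercept`, `r_squared`, `p_value` (slope), `n`, `label`.
#' @export
regress_r2 <- function(x, y, label = NA_character_) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  out <- data.frame(label = label,
                    slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    r_squared = sm$r.squared,
                    p_value = sm$coefficients[2, 4],
                    n = length(x), stringsAsFactors = FALSE)
  class(out) <- c("regression_result", "data.frame")
  out
}
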