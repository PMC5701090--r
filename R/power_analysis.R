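# Power of the two-sample independent t-test used for cohort sizing.

#' Power of a two-sample independent t-test
#'
#' Classical pooled-variance two-sided two-sample t-test power under the
#' noncentral t distribution: with `df = n_case + n_control - 2` and
#' noncentrality `ncp = mean_diff / (sd * sqrt(1/n_case + 1/n_control))`,
#' power is `P(|T| > t_{1-alpha/2, df})` for `T ~ t(df, ncp)`. A Welch
#' variant (Satterthwaite df under a common sd) is available; the
#' calculation is units-agnostic (mean difference and sd in the same
#' units, e.g. classifier score percent).
#'
#' @param n_case,n_control Group sizes (each >= 2).
#' @param mean_diff True difference in population means.
#' @param sd Common population standard deviation (> 0).
#' @param alpha Two-sided significance level (a 0.95 confidence level
#'   corresponds to `alpha = 0.05`).
#' @param method `"pooled"` (classical independent t) or `"welch"`.
#' @return Power in \[0, 1\].
#' @examples
#' t_test_power(30, 89, mean_diff = 30, sd = 15)  # > 0.99
#' @export
t_test_power <- function(n_case, n_control, mean_diff, sd, alpha = 0.05,
                         method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (n_case < 2 || n_control < 2) stop("group sizes must be >= 2")
  if (sd <= 0) stop("sd must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df <- if (method == "pooled") {
    n_case + n_control - 2
  } else {
    (1 / n_case + 1 / n_control)^2 /
      ((1 / n_case)^2 / (n_case - 1) + (1 / n_control)^2 / (n_control - 1))
  }
  ncp <- mean_diff / (sd * sqrt(1 / n_case + 1 / n_control))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp, lower.tail = TRUE)
}
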