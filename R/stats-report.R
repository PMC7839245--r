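#' Two-group power-analysis specification
#'
#' Planning defaults of the study design: detect a 20% between-group
#' difference assuming 15% interindividual variation, power 0.8, two-sided
#' alpha 0.05, with a 10% anticipated dropout. The standardized effect size
#' is `detect_diff / interindividual_cv`.
#'
#' @param detect_diff Between-group difference to detect (% of the mean).
#' @param interindividual_cv Interindividual variation (% of the mean).
#' @param power Target power, fraction in (0, 1).
#' @param alpha Two-sided type-I error, fraction in (0, 1).
#' @param dropout_rate Anticipated dropout, fraction in [0, 1).
#' @return Object of class `power_spec`.
#' @export
power_spec <- function(detect_diff = 20, interindividual_cv = 15,
                       power = 0.8, alpha = 0.05, dropout_rate = 0.10) {
  if (detect_diff <= 0 || interindividual_cv <= 0)
    pv_stop("detect_diff and interindividual_cv must be > 0")
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    pv_stop("power and alpha must be in (0, 1)")
  if (dropout_rate < 0 || dropout_rate >= 1)
    pv_stop("dropout_rate must be in [0, 1)")
  structure(
    list(detect_diff = detect_diff,
         interindividual_cv = interindividual_cv, power = power,
         alpha = alpha, dropout_rate = dropout_rate,
         effect_size = detect_diff / interindividual_cv),
    class = "power_spec"
  )
}

# Exact power of the two-sided two-sample t test at per-group size n and
# standardized effect d, via the noncentral t distribution.
two_sample_t_power <- function(n, d, alpha) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tc <- qt(1 - alpha / 2, df)
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}

#' Minimal per-group sample size for a two-group comparison
#'
#' Iterates the per-group size upward until the exact noncentral-t power of
#' the two-sided two-sample t test reaches the requested power. The
#' noncentral-t calculation (not the normal approximation, which
#' undercounts by one here) is the one that reproduces the study's plan of
#' 10 per group at effect size 20/15.
#'
#' @param spec A [power_spec()], or `NULL` to pass `effect_size` etc.
#' @param effect_size Standardized difference (Cohen's d); overrides spec.
#' @param power,alpha See [power_spec()].
#' @param n_max Safety cap on the search.
#' @return List: `n_per_group`, `achieved_power`, `effect_size`.
#' @export
#' @examples
#' sample_size_two_groups(power_spec())  # 10 per group
sample_size_two_groups <- function(spec = power_spec(), effect_size = NULL,
                                   power = NULL, alpha = NULL,
                                   n_max = 1e6) {
  if (!is.null(spec)) {
    effect_size <- effect_size %||% spec$effect_size
    power <- power %||% spec$power
    alpha <- alpha %||% spec$alpha
  }
  if (effect_size <= 0) pv_stop("effect size must be > 0")
  n <- 2L
  while (two_sample_t_power(n, effect_size, alpha) < power) {
    n <- n + 1L
    if (n > n_max) pv_stop("requested power unreachable", "pvvent_domain_error")
  }
  list(n_per_group = n, achieved_power = two_sample_t_power(n, effect_size,
                                                            alpha),
       effect_size = effect_size)
}

#' Inflate enrolment for anticipated dropout
#'
#' Multiplicative convention with round-half-up:
#' `round_half_up(n_total * (1 + dropout_rate))`. (The alternative
#' `n / (1 - rate)` convention gives 23 for 20 at 10% and does not match
#' the study's enrolment arithmetic of 22.)
#'
#' @param n_total Evaluable subjects needed (both groups), >= 1.
#' @param dropout_rate Fraction in [0, 1).
#' @return Integer number to enrol.
#' @export
#' @examples
#' inflate_for_dropout(20, 0.10)  # 22
inflate_for_dropout <- function(n_total, dropout_rate) {
  if (n_total < 1) pv_stop("n_total must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    pv_stop("dropout_rate must be in [0, 1)")
  as.integer(floor(n_total * (1 + dropout_rate) + 0.5))
}

#' Relative change versus baseline, in percent
#'
#' 100 * (value - baseline) / baseline. Note the asymmetry: swapping value
#' and baseline does not simply negate the result (only the log
#' approximation is antisymmetric).
#'
#' @param value,baseline Numeric; `baseline` nonzero.
#' @return Percent change.
#' @export
relative_change <- function(value, baseline) {
  if (any(baseline == 0)) pv_stop("zero baseline", "pvvent_argument_error")
  100 * (value - baseline) / baseline
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation and its two-sided p-value from the t
#' transform (delegated to [stats::cor.test()]), used for the
#' elastance-versus-oxygenation association.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List: `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) pv_stop("x and y must have equal length")
  if (length(x) < 3) pv_stop("need at least 3 pairs", "pvvent_argument_error")
  if (sd(x) == 0 || sd(y) == 0)
    pv_stop("zero variance in input", "pvvent_domain_error")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
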