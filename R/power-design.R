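# Design arithmetic for multiple-regression studies: Cohen's f^2 effect size
# from (adjusted) R^2, power of the overall F-test via the noncentral F
# distribution with noncentrality lambda = f^2 * n, required sample size, and
# multi-modality attrition compounding.

#' Cohen's f-squared from an R-squared value
#'
#' `f2 = R2 / (1 - R2)`. Here the input is conventionally the ADJUSTED
#' R^2 of the fitted model, so the effect size inherits its complexity
#' correction.
#'
#' @param adj_r2 (Adjusted) R^2, strictly below 1.
#' @return Cohen's f^2 (>= 0 for nonnegative input).
#' @examples
#' cohens_f2_from_adj_r2(0.4753)  # 0.906
#' cohens_f2_from_adj_r2(0.6339)  # 1.731
#' @export
cohens_f2_from_adj_r2 <- function(adj_r2) {
  stopifnot(is.numeric(adj_r2))
  if (any(adj_r2 >= 1)) stop("adj_r2 must be < 1", call. = FALSE)
  adj_r2 / (1 - adj_r2)
}

#' Inverse map: R-squared implied by a Cohen's f-squared
#' @param f2 Cohen's f^2 (>= 0).
#' @return `f2 / (1 + f2)`.
#' @export
adj_r2_from_cohens_f2 <- function(f2) {
  stopifnot(all(f2 >= 0))
  f2 / (1 + f2)
}

#' Power of the overall multiple-regression F-test
#'
#' `power = P(F'(u, n-u-1, lambda = f2 * n) > F_crit(1-alpha; u, n-u-1))`
#' where u is the number of covariates and F' the noncentral F
#' distribution. The noncentrality convention `lambda = f2 * n` is the
#' standard one for multiple-regression power analysis.
#'
#' @param n Total sample size (may be non-integer for the continuous
#'   solution; must exceed u + 1 so the denominator df is positive).
#' @param u Numerator df (number of covariates), >= 1.
#' @param f2 Cohen's f^2, >= 0.
#' @param alpha Significance level in (0, 1).
#' @return Achieved power. Equals `alpha` when `f2 = 0`.
#' @export
regression_f_power <- function(n, u, f2, alpha = 0.05) {
  stopifnot(u >= 1, f2 >= 0, alpha > 0, alpha < 1)
  if (any(n <= u + 1)) {
    stop("need n > u + 1 for a positive denominator df", call. = FALSE)
  }
  v <- n - u - 1
  stats::pf(stats::qf(1 - alpha, u, v), u, v, ncp = f2 * n,
            lower.tail = FALSE)
}

#' Required sample size for the multiple-regression F-test
#'
#' Solves `regression_f_power(n, u, f2, alpha) = target_power` in continuous
#' n and rounds the solution to an integer. The default `"nearest"` rounding
#' reports the integer closest to the continuous solution;
#' `"ceiling"` returns the smallest integer n whose integer-n power actually
#' reaches the target (conservative).
#'
#' @param u Number of covariates.
#' @param f2 Cohen's f^2, > 0.
#' @param target_power Target power in (0, 1), default 0.90.
#' @param alpha Significance level, default 0.05.
#' @param rounding `"nearest"` (default) or `"ceiling"`.
#' @return Integer sample size (>= u + 2).
#' @examples
#' required_sample_size(10, 0.906)  # 33
#' required_sample_size(10, 1.731)  # 23
#' @export
required_sample_size <- function(u, f2, target_power = 0.9, alpha = 0.05,
                                 rounding = c("nearest", "ceiling")) {
  rounding <- match.arg(rounding)
  stopifnot(f2 > 0, target_power > 0, target_power < 1)
  lo <- u + 1 + 1e-6
  hi <- u + 2
  while (regression_f_power(hi, u, f2, alpha) < target_power) {
    hi <- hi * 2
    if (hi > 1e7) stop("required sample size exceeds 1e7", call. = FALSE)
  }
  n_cont <- stats::uniroot(
    function(n) regression_f_power(n, u, f2, alpha) - target_power,
    lower = lo, upper = hi, tol = 1e-9)$root
  if (rounding == "nearest") {
    max(round(n_cont), u + 2)
  } else {
    n <- max(ceiling(n_cont), u + 2)
    while (regression_f_power(n, u, f2, alpha) < target_power) n <- n + 1L
    as.integer(n)
  }
}

#' Cumulative subject loss under per-modality attrition
#'
#' A study requiring complete data across `n_modalities` independent data
#' domains loses `1 - (1 - rate)^n_modalities` of its subjects when each
#' domain independently drops a fraction `rate`.
#'
#' @param rate Per-modality attrition rate in [0, 1).
#' @param n_modalities Number of required data domains, >= 1.
#' @return Fraction of subjects lost.
#' @examples
#' cumulative_attrition(0.05, 9)  # ~0.37
#' @export
cumulative_attrition <- function(rate, n_modalities) {
  stopifnot(rate >= 0, rate < 1, n_modalities >= 1)
  1 - (1 - rate)^n_modalities
}

#' Percent reduction between two required sample sizes
#'
#' @param n_large Baseline required sample size (> 0).
#' @param n_small Reduced required sample size.
#' @return `100 * (n_large - n_small) / n_large`.
#' @examples
#' sample_size_reduction(33, 23)  # 30.3
#' @export
sample_size_reduction <- function(n_large, n_small) {
  stopifnot(n_large > 0)
  100 * (n_large - n_small) / n_large
}
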