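# Marginal feature screening: per-feature Welch two-sample t-test between the
# PWH and control groups at baseline, with a liberal ("soft") selection
# threshold that keeps weakly associated features for the downstream model.

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic
#' \eqn{t = (\bar x - \bar y) / \sqrt{s_x^2/n_x + s_y^2/n_y}} with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. Sample
#' variances use the n-1 denominator.
#'
#' When both samples are constant with equal means the test is degenerate and
#' the convention `t = 0, p = 1` is returned (the feature carries no group
#' signal), so screening is total over real tables; both constant with
#' unequal means returns `t = +/-Inf, p = 0`. In either degenerate case the
#' pooled df `n_x + n_y - 2` is reported.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4, p ~ 0.0213
#' @export
welch_t_test <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  res <- welch_stats(cbind(x), cbind(y))
  list(t = res$t[1L], df = res$df[1L], p = res$p[1L])
}

# vectorised Welch test over the columns of two matrices (same columns,
# different subject groups); returns per-column t, df, p
welch_stats <- function(X, Y) {
  nx <- nrow(X); ny <- nrow(Y)
  mx <- colMeans(X); my <- colMeans(Y)
  vx <- apply(X, 2L, stats::var)
  vy <- apply(Y, 2L, stats::var)
  se2 <- vx / nx + vy / ny
  t <- ifelse(se2 > 0, (mx - my) / sqrt(se2),
              ifelse(mx == my, 0, sign(mx - my) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)),
               nx + ny - 2)
  p <- ifelse(is.finite(t), 2 * stats::pt(abs(t), df, lower.tail = FALSE),
              0)
  p[se2 == 0 & mx == my] <- 1
  list(t = unname(t), df = unname(df), p = unname(p))
}

#' Screen features by group difference
#'
#' Runs a Welch two-sample t-test per feature between the two cohort groups
#' on the baseline table and flags features with two-sided `p < threshold` as
#' selected. The liberal default threshold 0.2 deliberately retains features
#' with weak marginal association; no multiple-testing correction is applied.
#'
#' @param tab A [feature_table()] covering the screening cohort.
#' @param outcomes Outcome table with `subject_id` and `group` covering every
#'   subject of `tab`; both groups need at least 2 subjects.
#' @param threshold Selection threshold on the p-value (default 0.2).
#' @return `data.frame` with one row per feature (original column order):
#'   `feature_id`, `t_stat`, `welch_df`, `p_value`, `selected`, plus
#'   attributes `threshold` and `region_counts` (selected count per region).
#' @export
screen_features <- function(tab, outcomes, threshold = 0.2) {
  stopifnot(inherits(tab, "feature_table"), threshold >= 0, threshold <= 1)
  grp <- outcomes$group[match(tab$subject_ids, outcomes$subject_id)]
  if (anyNA(grp)) {
    stop("no group label for subject(s): ",
         paste(tab$subject_ids[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  if (sum(grp == "PWH") < 2L || sum(grp == "control") < 2L) {
    stop("both groups need at least 2 subjects for screening", call. = FALSE)
  }
  res <- welch_stats(tab$values[grp == "PWH", , drop = FALSE],
                     tab$values[grp == "control", , drop = FALSE])
  out <- data.frame(feature_id = tab$descriptors$feature_id,
                    t_stat = res$t, welch_df = res$df, p_value = res$p,
                    selected = res$p < threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "region_counts") <-
    table(factor(tab$descriptors$region[out$selected],
                 levels = c("cor", "sub", "wm")))
  out
}
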