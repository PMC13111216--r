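# Ordinary least squares with an intercept, the Gaussian AIC, deterministic
# bidirectional stepwise selection, and goodness-of-fit metrics
# (adjusted R^2, residual standard error, fitted-vs-observed correlation).

AIC_TIE_TOL <- 1e-10

#' Least-squares fit with intercept
#'
#' QR-based OLS of `y` on the labelled columns of `design` plus an intercept.
#' Rank deficiency (at the QR tolerance) is an error naming the collinear
#' terms.
#'
#' @param design n x k numeric matrix with column labels (may have 0
#'   columns).
#' @param y Numeric outcome vector.
#' @param candidate_ids Full candidate label set for bookkeeping (defaults to
#'   the design columns).
#' @return A `regression_fit`: list with `term_ids`, `beta0_hat`, `beta_hat`
#'   (named), `n`, `sse`, `aic`, `fitted`, `residuals`, `candidate_ids`.
#' @export
ols_fit <- function(design, y, candidate_ids = colnames(design)) {
  if (is.null(design)) design <- matrix(numeric(0), length(y), 0L)
  stopifnot(is.matrix(design), nrow(design) == length(y))
  k <- ncol(design)
  n <- length(y)
  if (n < k + 2L) {
    stop("need n >= k + 2 observations (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  sse <- sum(resid^2)
  fit <- structure(
    list(term_ids = colnames(design), beta0_hat = unname(beta[1L]),
         beta_hat = beta[-1L], n = n, sse = sse, aic = NA_real_,
         fitted = fitted, residuals = resid,
         candidate_ids = candidate_ids),
    class = "regression_fit"
  )
  fit$aic <- model_aic(fit)
  fit
}

#' Gaussian AIC of a linear model
#'
#' `AIC = n * log(SSE / n) + 2 * (k + 1)` with k the number of retained
#' predictors excluding the intercept. Additive constants are dropped: only
#' AIC differences drive model selection (this matches the criterion used by
#' [stats::extractAIC()] for `lm` fits). A perfect fit (SSE = 0) returns
#' `-Inf`: a saturated model dominates every competitor.
#'
#' @param fit A `regression_fit`, or a list with `n`, `sse`, `term_ids`.
#' @return AIC value (possibly `-Inf`).
#' @export
model_aic <- function(fit) {
  n <- fit$n
  k <- length(fit$term_ids)
  if (fit$sse <= 0) return(-Inf)
  n * log(fit$sse / n) + 2 * (k + 1)
}

#' Bidirectional stepwise selection under AIC
#'
#' From the starting model (full candidate set by default, or intercept-only
#' with `start = "null"`), repeatedly evaluates every single-term deletion
#' and every single-term addition from the candidate set, takes the move with
#' the lowest AIC if it improves on the current model, and stops otherwise.
#' The returned model is locally AIC-optimal: no single add or drop lowers
#' the criterion.
#'
#' Ties (within 1e-10) are broken deterministically: deletion is preferred
#' over addition, and among moves of the same kind the term with the lowest
#' candidate index wins. A defensive guard aborts after
#' `2 * length(candidates)^2` accepted moves (cycling is impossible under
#' strict improvement).
#'
#' @param design n x m candidate matrix with labels.
#' @param y Outcome vector.
#' @param start `"full"` or `"null"`.
#' @return A `regression_fit` with an `aic_trace` attribute (`data.frame`
#'   with one row per accepted move: `move`, `term`, `aic`).
#' @export
stepwise_aic <- function(design, y, start = c("full", "null")) {
  start <- match.arg(start)
  stopifnot(is.matrix(design))
  cands <- colnames(design)
  if (is.null(cands) && ncol(design) > 0L) {
    stop("candidate design must have column labels", call. = FALSE)
  }
  n <- length(y)
  if (start == "full" && ncol(design) > n - 2L) {
    stop("full starting model infeasible: ", ncol(design),
         " candidates but only n = ", n,
         " observations; reduce dimension first (e.g. PCA) or use ",
         "start = \"null\"", call. = FALSE)
  }
  current <- if (start == "full") cands else character(0L)
  refit <- function(terms) {
    ols_fit(design[, terms, drop = FALSE], y, candidate_ids = cands)
  }
  fit <- refit(current)
  trace <- data.frame(move = "start", term = NA_character_, aic = fit$aic,
                      stringsAsFactors = FALSE)
  guard <- 2L * max(1L, length(cands))^2
  for (iter in seq_len(guard + 1L)) {
    if (iter > guard) {
      stop("stepwise iteration guard exceeded (internal error)",
           call. = FALSE)
    }
    moves <- rbind(
      if (length(current) > 0L)
        data.frame(move = "drop", term = current, stringsAsFactors = FALSE),
      if (length(setdiff(cands, current)) > 0L)
        data.frame(move = "add", term = setdiff(cands, current),
                   stringsAsFactors = FALSE)
    )
    if (is.null(moves) || nrow(moves) == 0L) break
    moves$aic <- vapply(seq_len(nrow(moves)), function(i) {
      terms <- if (moves$move[i] == "drop") setdiff(current, moves$term[i])
               else c(current, moves$term[i])
      terms <- cands[cands %in% terms]            # stable candidate order
      if (length(terms) > n - 2L) return(Inf)
      tryCatch(refit(terms)$aic, error = function(e) Inf)
    }, numeric(1L))
    best_aic <- min(moves$aic)
    if (!(best_aic < fit$aic - AIC_TIE_TOL)) break
    tied <- which(moves$aic <= best_aic + AIC_TIE_TOL)
    tied <- tied[order(moves$move[tied] != "drop",
                       match(moves$term[tied], cands))]
    pick <- tied[1L]
    current <- if (moves$move[pick] == "drop") {
      setdiff(current, moves$term[pick])
    } else {
      cands[cands %in% c(current, moves$term[pick])]
    }
    fit <- refit(current)
    trace <- rbind(trace, data.frame(move = moves$move[pick],
                                     term = moves$term[pick], aic = fit$aic,
                                     stringsAsFactors = FALSE))
  }
  attr(fit, "aic_trace") <- trace
  fit
}

#' Goodness-of-fit metrics
#'
#' Adjusted `R^2 = 1 - (SSE/(n-p-1)) / (SST/(n-1))` and residual standard
#' error `RSE = sqrt(SSE/(n-p-1))`, with p the number of predictors excluding
#' the intercept, plus the Pearson correlation between observed and fitted
#' values and its two-sided p-value (from `t = r * sqrt((n-2)/(1-r^2))`).
#' For models comparing the same outcome SST/(n-1) is shared, so the
#' adjusted-R^2 ranking is exactly the reverse of the RSE ranking.
#'
#' @param y Observed outcome.
#' @param y_hat Fitted values.
#' @param p_used Number of retained predictors (excluding intercept).
#' @return List with `sse`, `sst`, `adj_r2`, `rse`, `pearson_r`,
#'   `pearson_p`, `n`, `p_used`. The correlation is `NA` for a constant
#'   fitted vector (e.g. intercept-only model).
#' @export
fit_metrics <- function(y, y_hat, p_used) {
  n <- length(y)
  stopifnot(length(y_hat) == n, p_used >= 0)
  if (n <= p_used + 1L) {
    stop("residual degrees of freedom must be >= 1", call. = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("constant outcome: SST = 0", call. = FALSE)
  sse <- sum((y - y_hat)^2)
  adj_r2 <- 1 - (sse / (n - p_used - 1)) / (sst / (n - 1))
  rse <- sqrt(sse / (n - p_used - 1))
  if (stats::sd(y_hat) > 0) {
    ct <- stats::cor.test(y, y_hat)
    r <- unname(ct$estimate); pv <- ct$p.value
  } else {
    r <- NA_real_; pv <- NA_real_
  }
  list(sse = sse, sst = sst, adj_r2 = adj_r2, rse = rse,
       pearson_r = r, pearson_p = pv, n = n, p_used = p_used)
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("<regression_fit> n = ", x$n, ", retained ", length(x$term_ids),
      " of ", length(x$candidate_ids), " candidate terms, AIC = ",
      format(x$aic, digits = 6), "\n", sep = "")
  if (length(x$term_ids) > 0L) {
    cat("  terms: ", paste(x$term_ids, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Export a fit report as JSON
#'
#' Candidate and retained term ids, coefficients and the accepted-move AIC
#' trace.
#'
#' @param fit A `regression_fit` (usually from [stepwise_aic()]).
#' @param path Output path.
#' @export
fit_to_json <- function(fit, path) {
  tr <- attr(fit, "aic_trace")
  obj <- list(candidate_ids = fit$candidate_ids, term_ids = fit$term_ids,
              beta0_hat = fit$beta0_hat,
              beta_hat = as.list(fit$beta_hat), n = fit$n, sse = fit$sse,
              aic = fit$aic,
              aic_trace = if (is.null(tr)) NULL else tr)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
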