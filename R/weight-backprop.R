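# Equivalent weight back-propagation: the PC-space regression
# yhat_i = b0 + sum_l PC_il b_l is rewritten exactly as a feature-space model
# yhat_i = b0~ + sum_j X_ij b~_j through the stack's affine map, and each
# feature's coefficient is then standardized by its sample SD into the
# adjusted weight w_j = sd_j * b~_j: the change in predicted outcome per one
# SD change in feature j, invariant under any rescaling of that feature.

#' Back-propagate PC-space coefficients to feature space
#'
#' With `(A, c)` the stack's affine map and `beta` the coefficient vector
#' over ALL stack scores (zero for stepwise-dropped components), the
#' equivalent feature-space model is `beta_tilde = A %*% beta`,
#' `beta0_tilde = beta0 + sum(c * beta)`; predictions agree with the
#' PC-space model exactly. Adjusted weights multiply each coefficient by the
#' feature's training-sample SD (n-1 denominator, computed on the modelling
#' cohort the stack was fitted on).
#'
#' @param stack A fitted `pca_stack`.
#' @param fit A `regression_fit` whose retained terms are stack score
#'   labels.
#' @return An `equivalent_weights` object: `data.frame` with columns
#'   `feature_id`, `beta_tilde` (unadjusted weight), `sigma_hat`, `mean`,
#'   `w` (adjusted weight), `screened_out` (all `FALSE` here), plus
#'   attribute `beta0_tilde`.
#' @export
backpropagate_weights <- function(stack, fit) {
  stopifnot(inherits(stack, "pca_stack"), inherits(fit, "regression_fit"))
  unknown <- setdiff(fit$term_ids, stack$score_labels)
  if (length(unknown) > 0L) {
    stop("fit term(s) not among stack scores: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  beta <- stats::setNames(numeric(stack$final_dim), stack$score_labels)
  beta[fit$term_ids] <- fit$beta_hat
  beta_tilde <- drop(stack$affine_A %*% beta)
  beta0_tilde <- fit$beta0_hat + sum(stack$affine_c * beta)
  out <- data.frame(feature_id = stack$feature_ids,
                    beta_tilde = unname(beta_tilde),
                    sigma_hat = unname(stack$feature_sd),
                    mean = unname(stack$feature_mu),
                    w = unname(stack$feature_sd * beta_tilde),
                    screened_out = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "beta0_tilde") <- beta0_tilde
  class(out) <- c("equivalent_weights", "data.frame")
  out
}

#' Expand a weight set over a full feature grid
#'
#' Features eliminated at screening are reported with zero weights and a
#' `screened_out` flag (rather than omitted), so reports over the complete
#' feature grid are possible.
#'
#' @param weights An `equivalent_weights` object.
#' @param grid Full feature-grid `data.frame` (see [build_feature_grid()]).
#' @return `equivalent_weights` over all grid rows, grid order.
#' @export
expand_weights <- function(weights, grid) {
  idx <- match(grid$feature_id, weights$feature_id)
  out <- data.frame(feature_id = grid$feature_id,
                    beta_tilde = ifelse(is.na(idx), 0,
                                        weights$beta_tilde[idx]),
                    sigma_hat = ifelse(is.na(idx), NA_real_,
                                       weights$sigma_hat[idx]),
                    mean = ifelse(is.na(idx), NA_real_, weights$mean[idx]),
                    w = ifelse(is.na(idx), 0, weights$w[idx]),
                    screened_out = is.na(idx),
                    stringsAsFactors = FALSE)
  attr(out, "beta0_tilde") <- attr(weights, "beta0_tilde")
  class(out) <- c("equivalent_weights", "data.frame")
  out
}

#' Rank features by adjusted weight and apply the reporting cutoff
#'
#' Rows are sorted by `|w|` descending (ties broken by feature id,
#' lexicographic) and only rows with `|w| >= w_min` are retained; columns
#' follow the standard weight-report layout (feature, adjusted weight,
#' unadjusted weight, mean, SD).
#'
#' @param weights An `equivalent_weights` object.
#' @param w_min Reporting threshold on `|w|` (default 0.5).
#' @return `data.frame` with columns `feature_id`, `adjusted_weight`,
#'   `unadjusted_weight`, `mean`, `sd`.
#' @export
rank_and_select <- function(weights, w_min = 0.5) {
  ord <- order(-abs(weights$w), weights$feature_id)
  r <- weights[ord, , drop = FALSE]
  r <- r[abs(r$w) >= w_min, , drop = FALSE]
  data.frame(feature_id = r$feature_id,
             adjusted_weight = r$w,
             unadjusted_weight = r$beta_tilde,
             mean = r$mean,
             sd = r$sigma_hat,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Verify the exact prediction equivalence of the two model forms
#'
#' Evaluates every training subject along both paths -- PC-space
#' (`b0 + scores %*% beta`) and feature-space
#' (`beta0_tilde + X %*% beta_tilde`) -- and returns the maximum absolute
#' gap together with a pass flag against `tol * range(prediction)`.
#'
#' @param tab The [feature_table()] the stack and fit were trained on.
#' @param stack Fitted `pca_stack`.
#' @param fit Fitted `regression_fit` over the stack scores.
#' @param weights The back-propagated `equivalent_weights`.
#' @param tol Relative tolerance (default 1e-10).
#' @return List with `max_gap`, `scale` (prediction range), `pass`.
#' @export
verify_equivalence <- function(tab, stack, fit, weights, tol = 1e-10) {
  scores <- stack_scores(stack, tab$values)
  beta <- stats::setNames(numeric(stack$final_dim), stack$score_labels)
  beta[fit$term_ids] <- fit$beta_hat
  pred_pc <- fit$beta0_hat + drop(scores %*% beta)
  bt <- weights$beta_tilde[match(stack$feature_ids, weights$feature_id)]
  pred_ft <- attr(weights, "beta0_tilde") + drop(tab$values %*% bt)
  gap <- max(abs(pred_pc - pred_ft))
  scale <- max(diff(range(pred_pc)), .Machine$double.eps)
  list(max_gap = gap, scale = scale, pass = gap < tol * scale)
}

#' Export a weight audit as JSON
#'
#' @param weights An `equivalent_weights` object.
#' @param path Output path.
#' @param equivalence Optional result of [verify_equivalence()].
#' @export
weights_to_json <- function(weights, path, equivalence = NULL) {
  obj <- list(beta0_tilde = attr(weights, "beta0_tilde"),
              features = weights[, c("feature_id", "beta_tilde", "sigma_hat",
                                     "mean", "w", "screened_out")],
              equivalence = equivalence)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
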