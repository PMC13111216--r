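# Orchestration of the named analyses: the multimodality Model 1 / Model 2
# pipelines (screen -> layered correlation PCA -> stepwise AIC -> metrics ->
# equivalent weights), the eight unimodality models (one imaging metric each,
# screened, no PCA), the seventeen modality-region models (one metric in one
# region, unscreened), and adjusted-R^2 model comparison.

# modelling cohort and outcome vector for a given outcome choice:
# Z uses every subject with a baseline score; deltaZ uses only PWH rows with
# a defined change score
modeling_outcome <- function(tab, outcomes, outcome = c("Z", "deltaZ")) {
  outcome <- match.arg(outcome)
  outcomes <- compute_delta_z(outcomes)
  rows <- outcomes[outcomes$subject_id %in% tab$subject_ids, , drop = FALSE]
  if (outcome == "Z") {
    ids <- rows$subject_id
    y <- rows$z_baseline
  } else {
    keep <- rows$group == "PWH" & !is.na(rows$delta_z)
    ids <- rows$subject_id[keep]
    y <- rows$delta_z[keep]
  }
  if (length(ids) < 3L) {
    stop("fewer than 3 modelling subjects for outcome ", outcome,
         call. = FALSE)
  }
  list(ids = ids, y = stats::setNames(y, ids), outcome = outcome)
}

new_model_report <- function(label, spec, screening, stack, fit, metrics,
                             weights = NULL, equivalence = NULL, y = NULL,
                             features = NULL, status = "ok") {
  structure(
    list(label = label, spec = spec, screening = screening,
         features = features, stack = stack, fit = fit, metrics = metrics,
         weights = weights, equivalence = equivalence, y = y,
         status = status),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> ", x$label, " [", x$status, "]\n", sep = "")
  if (!is.null(x$metrics)) {
    cat(sprintf("  n = %d, p = %d, adj R^2 = %.4f, RSE = %.4f\n",
                x$metrics$n, x$metrics$p_used, x$metrics$adj_r2,
                x$metrics$rse))
  }
  if (!is.null(x$fit) && length(x$fit$term_ids) > 0L) {
    cat("  terms: ", paste(x$fit$term_ids, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Run a multimodality model (Model 1 or Model 2)
#'
#' End-to-end pipeline: Welch screening on the full baseline cohort (both
#' groups), restriction to the selected features, layered correlation PCA on
#' the modelling cohort (two layers for Model 1, one for Model 2),
#' bidirectional stepwise AIC over the retained component scores, fit
#' metrics, and exact equivalent-weight back-propagation with SD-adjusted
#' weights expanded over the full feature grid.
#'
#' @param tab Full [feature_table()] (screening uses every subject).
#' @param outcomes Outcome table (`subject_id`, `group`, `z_baseline`,
#'   optional `z_followup`).
#' @param variant `"model2"` (single PCA layer, default) or `"model1"`
#'   (second global layer).
#' @param outcome `"Z"` (baseline score, all subjects) or `"deltaZ"` (change
#'   score, PWH with follow-up).
#' @param pve PVE retention threshold (conventional choices 0.8 or 0.9).
#' @param grouping First-layer grouping, `"by_region"` (default) or
#'   `"by_metric"`.
#' @param screen Apply the Welch screen (default `TRUE`).
#' @param threshold Screening p-value threshold.
#' @param w_min Reporting cutoff on `|w|` for the ranked weight report.
#' @param start Stepwise starting model (`"full"` default).
#' @param pca_cohort Fit the PCA on the `"modeling"` cohort (default) or on
#'   `"all"` subjects.
#' @return A `model_report` with the screening table, fitted stack, stepwise
#'   fit, metrics, equivalent weights (full grid), ranked report and
#'   equivalence check.
#' @export
run_multimodal <- function(tab, outcomes,
                           variant = c("model2", "model1"),
                           outcome = c("Z", "deltaZ"),
                           pve = 0.9, grouping = "by_region",
                           screen = TRUE, threshold = 0.2, w_min = 0.5,
                           start = "full",
                           pca_cohort = c("modeling", "all")) {
  variant <- match.arg(variant)
  outcome <- match.arg(outcome)
  pca_cohort <- match.arg(pca_cohort)
  mo <- modeling_outcome(tab, outcomes, outcome)
  scr <- NULL
  feats <- tab$descriptors$feature_id
  if (screen) {
    scr <- screen_features(tab, outcomes, threshold)
    feats <- scr$feature_id[scr$selected]
    if (length(feats) == 0L) {
      stop("screening selected no features at threshold ", threshold,
           call. = FALSE)
    }
  }
  fit_ids <- if (pca_cohort == "modeling") mo$ids else tab$subject_ids
  subtab <- subset_feature_table(tab, subjects = fit_ids, features = feats)
  stack <- fit_stack(subtab, grouping = grouping, pve = pve,
                     two_layer = (variant == "model1"))
  scores <- if (pca_cohort == "modeling") stack$scores else
    stack_scores(stack,
                 subset_feature_table(tab, subjects = mo$ids,
                                      features = feats)$values)
  fit <- stepwise_aic(scores, unname(mo$y), start = start)
  metrics <- fit_metrics(unname(mo$y), fit$fitted, length(fit$term_ids))
  w <- backpropagate_weights(stack, fit)
  eq <- verify_equivalence(
    subset_feature_table(tab, subjects = mo$ids, features = feats),
    stack, fit, w)
  w_full <- expand_weights(w, tab$descriptors)
  spec <- list(variant = variant, outcome = outcome, pve = pve,
               grouping = grouping, screen = screen, threshold = threshold,
               w_min = w_min, start = start, pca_cohort = pca_cohort)
  rep <- new_model_report(
    label = sprintf("%s (pve %.2g, %s)", variant, pve, outcome),
    spec = spec, screening = scr, stack = stack, fit = fit,
    metrics = metrics, weights = w_full, equivalence = eq, y = mo$y,
    features = feats)
  rep$ranked <- rank_and_select(w_full, w_min)
  rep
}

# shared worker for the raw-feature (no PCA) suites
fit_raw_model <- function(tab, ids, y, feats, label, spec, scr = NULL,
                          start = "full") {
  if (length(feats) == 0L) {
    fit <- ols_fit(matrix(numeric(0), length(ids), 0L,
                          dimnames = list(ids, NULL)), unname(y))
    metrics <- fit_metrics(unname(y), fit$fitted, 0L)
    return(new_model_report(label, spec, scr, NULL, fit, metrics, y = y,
                            features = character(0L),
                            status = "no screened features"))
  }
  subtab <- subset_feature_table(tab, subjects = ids, features = feats)
  fit <- stepwise_aic(subtab$values, unname(y), start = start)
  metrics <- fit_metrics(unname(y), fit$fitted, length(fit$term_ids))
  status <- if (length(fit$term_ids) == 0L) "no informative features" else "ok"
  new_model_report(label, spec, scr, NULL, fit, metrics, y = y,
                   features = feats, status = status)
}

#' Run the eight unimodality models
#'
#' One model per imaging metric (Vol, CT, FD, FW, FA, MD, CBF, CVR), each
#' restricted to the Welch-screened features of that metric across all
#' regions. These candidate sets are small, so no PCA step is used; stepwise
#' AIC selects the informative features directly. Models whose stepwise
#' selection returns the intercept-only model are flagged
#' `"no informative features"`.
#'
#' @inheritParams run_multimodal
#' @param start Stepwise start; `"full"` requires fewer candidates than
#'   n - 2 in every metric cell.
#' @return List of exactly 8 `model_report`s in canonical metric order.
#' @export
run_unimodality_suite <- function(tab, outcomes, outcome = "deltaZ",
                                  threshold = 0.2, start = "full") {
  mo <- modeling_outcome(tab, outcomes, outcome)
  scr <- screen_features(tab, outcomes, threshold)
  sel <- scr$feature_id[scr$selected]
  lapply(all_metrics(), function(m) {
    feats <- intersect(sel,
      tab$descriptors$feature_id[tab$descriptors$metric == m])
    fit_raw_model(tab, mo$ids, mo$y, feats, label = m,
                  spec = list(variant = "unimodality", metric = m,
                              outcome = mo$outcome, threshold = threshold),
                  scr = scr, start = start)
  })
}

#' Run the seventeen modality-region models
#'
#' One model per admissible metric-region cell (7 cortical + 7 subcortical +
#' 3 white matter). Each cell holds at most one feature per ROI, so the
#' screening step is deliberately skipped: these models capture the general
#' association between a localized marker family and the outcome, not only
#' the group-status-related part.
#'
#' @inheritParams run_multimodal
#' @return List of exactly 17 `model_report`s, region-major order.
#' @export
run_modality_region_suite <- function(tab, outcomes, outcome = "deltaZ",
                                      start = "full") {
  mo <- modeling_outcome(tab, outcomes, outcome)
  rms <- region_metric_sets()
  cells <- do.call(rbind, lapply(names(rms), function(rg) {
    data.frame(region = rg, metric = rms[[rg]], stringsAsFactors = FALSE)
  }))
  lapply(seq_len(nrow(cells)), function(i) {
    rg <- cells$region[i]; m <- cells$metric[i]
    feats <- tab$descriptors$feature_id[
      tab$descriptors$metric == m & tab$descriptors$region == rg]
    fit_raw_model(tab, mo$ids, mo$y, feats,
                  label = paste0(m, "/", rg),
                  spec = list(variant = "modality_region", metric = m,
                              region = rg, outcome = mo$outcome),
                  start = start)
  })
}

#' Compare fitted models by adjusted R-squared
#'
#' Ranks a set of `model_report`s sharing one outcome vector by adjusted
#' R^2 (descending) and asserts that the residual-standard-error ordering is
#' the exact reverse, which holds whenever the models target the same
#' outcome (SST/(n-1) is shared).
#'
#' @param reports List of `model_report`s.
#' @return `data.frame` with columns `model`, `status`, `n`, `p_used`,
#'   `adj_r2`, `rse`, `aic`, sorted by `adj_r2` descending.
#' @export
compare_models <- function(reports) {
  stopifnot(length(reports) >= 1L)
  y0 <- reports[[1L]]$y
  for (r in reports) {
    if (!isTRUE(all.equal(unname(r$y), unname(y0), tolerance = 0))) {
      stop("mixed outcomes: model comparison requires a shared outcome ",
           "vector", call. = FALSE)
    }
  }
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(model = r$label, status = r$status, n = r$metrics$n,
               p_used = r$metrics$p_used, adj_r2 = r$metrics$adj_r2,
               rse = r$metrics$rse, aic = r$fit$aic,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(-df$adj_r2, df$model), , drop = FALSE]
  rownames(df) <- NULL
  if (!all(diff(df$rse) >= -1e-12 * pmax(abs(df$rse[-1L]), 1))) {
    # adjusted R^2 is a monotone decreasing function of RSE at fixed outcome
    stop("internal inconsistency: RSE ordering is not the reverse of the ",
         "adjusted-R^2 ordering", call. = FALSE)
  }
  df
}

#' Percentile bootstrap interval for a multimodality model's adjusted R-squared
#'
#' Resamples the modelling subjects with replacement `B` times, refits the
#' PCA stack and the stepwise regression on each replicate (the screening
#' decision is held fixed at the original-sample result) and returns the
#' percentile interval of the replicate adjusted R^2 values. Replicates with
#' a degenerate design (e.g. a resampled constant feature) are skipped and
#' counted. Fully reproducible given the seed.
#'
#' @inheritParams run_multimodal
#' @param B Number of bootstrap replicates (>= 200 recommended).
#' @param seed Integer RNG seed (mandatory).
#' @param level Interval coverage (default 0.95).
#' @return List with `lower`, `upper`, `level`, `B_used`, `B_skipped`,
#'   `replicates`.
#' @export
bootstrap_adj_r2_ci <- function(tab, outcomes, B = 200L, seed,
                                variant = "model2", outcome = "deltaZ",
                                pve = 0.9, grouping = "by_region",
                                screen = TRUE, threshold = 0.2,
                                start = "full", level = 0.95) {
  stopifnot(B >= 2L, !missing(seed))
  mo <- modeling_outcome(tab, outcomes, outcome)
  feats <- tab$descriptors$feature_id
  if (screen) {
    scr <- screen_features(tab, outcomes, threshold)
    feats <- scr$feature_id[scr$selected]
  }
  base <- subset_feature_table(tab, subjects = mo$ids, features = feats)
  n <- length(mo$ids)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  reps <- rep(NA_real_, B)
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- base$values[idx, , drop = FALSE]
    rownames(v) <- make.unique(rownames(v))
    reps[b] <- tryCatch({
      bt <- feature_table(v, base$descriptors)
      st <- fit_stack(bt, grouping = grouping, pve = pve,
                      two_layer = (variant == "model1"))
      ft <- stepwise_aic(st$scores, unname(mo$y)[idx], start = start)
      fit_metrics(unname(mo$y)[idx], ft$fitted, length(ft$term_ids))$adj_r2
    }, error = function(e) {
      skipped <<- skipped + 1L
      NA_real_
    })
  }
  ok <- reps[!is.na(reps)]
  a <- (1 - level) / 2
  q <- stats::quantile(ok, probs = c(a, 1 - a), names = FALSE, type = 7)
  list(lower = q[1L], upper = q[2L], level = level,
       B_used = length(ok), B_skipped = skipped, replicates = ok)
}
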