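# Layered correlation-matrix PCA.  Layer 1 is fitted separately per feature
# group (by brain region, by imaging metric, or one global group); an optional
# layer 2 reduces the concatenated layer-1 scores once more.  Components are
# retained by cumulative proportion of variance explained (PVE), and the whole
# stack collapses to one exact affine map from feature space to score space,
# which is what makes the downstream weight back-propagation exact.

EIG_ZERO_TOL <- 1e-12

#' Fit a correlation-matrix PCA layer
#'
#' Standardizes each column by its sample mean and SD (n-1 denominator),
#' eigendecomposes the sample Pearson correlation matrix, orients each
#' eigenvector so that its largest-magnitude entry is positive (ties broken
#' by lowest input index) and retains the smallest k whose cumulative
#' eigenvalue share reaches `pve`. Working on the correlation rather than the
#' covariance matrix prevents any one imaging modality's natural scale from
#' dominating the leading components.
#'
#' The PVE denominator is the exact trace (the number of inputs).
#' Numerically zero eigenvalues (< 1e-12) are never retained, so under rank
#' deficiency (n - 1 < p) retention is capped at the number of positive
#' eigenvalues.
#'
#' @param X Numeric matrix (n >= 3 rows, named columns, no constant column).
#' @param pve Proportion of variance explained to retain, in (0, 1].
#' @param group_key Label for the layer (e.g. region code or `"global"`).
#' @return A `pca_layer`: list with `group_key`, `input_ids`, `mu`, `sigma`,
#'   `eigenvalues` (all p, descending), `loadings` (p x k retained), `k_retained`,
#'   `pve`, and `scores` (training scores, n x k).
#' @export
fit_correlation_pca <- function(X, pve, group_key = "global") {
  stopifnot(is.matrix(X), is.numeric(X))
  if (nrow(X) < 3L) stop("correlation PCA requires n >= 3", call. = FALSE)
  if (!(pve > 0 && pve <= 1)) stop("pve must lie in (0, 1]", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  mu <- colMeans(X)
  sigma <- apply(X, 2L, stats::sd)
  if (any(sigma == 0)) {
    stop("constant column (zero SD): ",
         paste(colnames(X)[sigma == 0], collapse = ", "), call. = FALSE)
  }
  p <- ncol(X)
  R <- stats::cor(X)
  ed <- eigen(R, symmetric = TRUE)
  lambda <- pmax(ed$values, 0)
  V <- ed$vectors
  # deterministic sign: largest |entry| positive, ties -> lowest index
  for (j in seq_len(p)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  n_pos <- sum(lambda > EIG_ZERO_TOL)
  k <- which(cumsum(lambda) / p >= pve - 1e-12)[1L]
  if (is.na(k)) k <- n_pos
  k <- min(k, n_pos)
  k <- max(k, 1L)
  Vk <- V[, seq_len(k), drop = FALSE]
  rownames(Vk) <- colnames(X)
  scores <- scale(X, center = mu, scale = sigma) %*% Vk
  colnames(scores) <- paste0(group_key, ".PC", seq_len(k))
  structure(
    list(group_key = group_key, input_ids = colnames(X), mu = mu,
         sigma = sigma, eigenvalues = lambda, loadings = Vk,
         k_retained = k, pve = pve, scores = scores),
    class = "pca_layer"
  )
}

#' Project data through a fitted PCA layer
#'
#' @param layer A `pca_layer` from [fit_correlation_pca()].
#' @param X Matrix with the training columns, in training order.
#' @return n x k score matrix.
#' @export
pca_transform <- function(layer, X) {
  stopifnot(inherits(layer, "pca_layer"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L,
                                dimnames = list(NULL, layer$input_ids))
  if (ncol(X) != length(layer$input_ids)) {
    stop("column count mismatch: layer expects ", length(layer$input_ids),
         " inputs, got ", ncol(X), call. = FALSE)
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), layer$input_ids)) {
    stop("column order mismatch with training inputs", call. = FALSE)
  }
  s <- scale(X, center = layer$mu, scale = layer$sigma) %*% layer$loadings
  colnames(s) <- colnames(layer$scores)
  s
}

#' Fit a layered PCA stack on a feature table
#'
#' Layer 1 runs one correlation PCA per feature group; the concatenated
#' retained scores either feed one global second-layer correlation PCA
#' (`two_layer = TRUE`, the "Model 1" reduction) or are used directly as the
#' final scores (`two_layer = FALSE`, "Model 2"). The composite affine map
#' `scores = X %*% A + c` is computed in closed form and cached.
#'
#' @param tab A [feature_table()] restricted to the modelling cohort and the
#'   candidate features.
#' @param grouping `"by_region"` (default), `"by_metric"` or
#'   `"single_group"`.
#' @param pve PVE retention threshold, applied to every layer.
#' @param two_layer Add the global second layer.
#' @return A `pca_stack`: list with `layers` (layer 1 list, optional
#'   `layer2`), `grouping`, `pve`, `feature_ids`, `feature_mu`, `feature_sd`,
#'   `score_labels`, `final_dim`, `affine_A` (p x L), `affine_c` (L), and
#'   training `scores`.
#' @export
fit_stack <- function(tab, grouping = c("by_region", "by_metric",
                                        "single_group"),
                      pve = 0.9, two_layer = FALSE) {
  stopifnot(inherits(tab, "feature_table"))
  grouping <- match.arg(grouping)
  d <- tab$descriptors
  keys <- switch(grouping,
    by_region = factor(d$region, levels = c("cor", "sub", "wm")),
    by_metric = factor(d$metric, levels = all_metrics()),
    single_group = factor(rep("all", nrow(d)))
  )
  keys <- droplevels(keys)
  layer1 <- lapply(levels(keys), function(k) {
    fit_correlation_pca(tab$values[, keys == k, drop = FALSE], pve = pve,
                        group_key = k)
  })
  names(layer1) <- levels(keys)
  s1 <- do.call(cbind, lapply(layer1, `[[`, "scores"))

  p <- ncol(tab$values)
  # layer-1 affine map: block structure over groups in original column order
  A1 <- matrix(0, nrow = p, ncol = ncol(s1),
               dimnames = list(d$feature_id, colnames(s1)))
  off <- 0L
  for (k in levels(keys)) {
    ly <- layer1[[k]]
    idx <- which(keys == k)
    cols <- off + seq_len(ly$k_retained)
    A1[idx, cols] <- (1 / ly$sigma) * ly$loadings
    off <- off + ly$k_retained
  }
  mu_full <- numeric(p)
  for (k in levels(keys)) {
    mu_full[keys == k] <- layer1[[k]]$mu
  }
  c1 <- -as.numeric(mu_full %*% A1)

  layer2 <- NULL
  if (two_layer) {
    layer2 <- fit_correlation_pca(s1, pve = pve, group_key = "global")
    D2V <- (1 / layer2$sigma) * layer2$loadings
    A <- A1 %*% D2V
    cc <- as.numeric((c1 - layer2$mu) %*% D2V)
    scores <- layer2$scores
  } else {
    A <- A1
    cc <- c1
    scores <- s1
  }
  sd_full <- numeric(p)
  for (k in levels(keys)) sd_full[keys == k] <- layer1[[k]]$sigma
  structure(
    list(layers = layer1, layer2 = layer2, grouping = grouping, pve = pve,
         feature_ids = d$feature_id, descriptors = d,
         feature_mu = stats::setNames(mu_full, d$feature_id),
         feature_sd = stats::setNames(sd_full, d$feature_id),
         score_labels = colnames(scores), final_dim = ncol(scores),
         affine_A = A, affine_c = cc, scores = scores),
    class = "pca_stack"
  )
}

#' @export
print.pca_stack <- function(x, ...) {
  k1 <- vapply(x$layers, `[[`, integer(1L), "k_retained")
  cat("<pca_stack> ", length(x$feature_ids), " features -> ",
      x$final_dim, " scores (", if (is.null(x$layer2)) "one layer"
      else "two layers", ", pve = ", x$pve, ")\n", sep = "")
  cat("  layer 1 retained: ",
      paste(sprintf("%s=%d", names(k1), k1), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Final scores of a stack for new data
#'
#' @param stack A fitted `pca_stack`.
#' @param X Matrix (or single row) with the training feature columns.
#' @param use_affine Evaluate via the cached affine map (default) rather than
#'   sequentially through the layers; the two routes agree to numerical
#'   precision.
#' @return n x final_dim score matrix.
#' @export
stack_scores <- function(stack, X, use_affine = TRUE) {
  stopifnot(inherits(stack, "pca_stack"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L,
                                dimnames = list(NULL, stack$feature_ids))
  if (ncol(X) != length(stack$feature_ids)) {
    stop("column count mismatch with training features", call. = FALSE)
  }
  if (use_affine) {
    s <- X %*% stack$affine_A +
      matrix(stack$affine_c, nrow(X), stack$final_dim, byrow = TRUE)
  } else {
    s <- do.call(cbind, lapply(stack$layers, function(ly) {
      pca_transform(ly, X[, match(ly$input_ids, stack$feature_ids),
                          drop = FALSE])
    }))
    if (!is.null(stack$layer2)) s <- pca_transform(stack$layer2, s)
  }
  colnames(s) <- stack$score_labels
  s
}

#' Extract the exact composite affine feature-to-score map
#'
#' @param stack A fitted `pca_stack`.
#' @return List with `A` (p x L) and `c` (length L), so that
#'   `scores = X %*% A + rep(c, each = n)`.
#' @export
stack_affine_map <- function(stack) {
  if (!inherits(stack, "pca_stack")) {
    stop("not a fitted pca_stack", call. = FALSE)
  }
  list(A = stack$affine_A, c = stack$affine_c)
}

#' Serialize / restore a PCA stack as JSON
#'
#' Full-precision dump of every layer (means, SDs, loadings, eigenvalues,
#' retention) and the composite affine map, for audit and exact reuse.
#'
#' @param stack A fitted `pca_stack`.
#' @param path Output path.
#' @export
stack_to_json <- function(stack, path) {
  ser_layer <- function(ly) {
    list(group_key = ly$group_key, input_ids = ly$input_ids,
         mu = unname(ly$mu), sigma = unname(ly$sigma),
         eigenvalues = ly$eigenvalues, loadings = unname(ly$loadings),
         k_retained = ly$k_retained, pve = ly$pve)
  }
  obj <- list(grouping = stack$grouping, pve = stack$pve,
              feature_ids = stack$feature_ids,
              score_labels = stack$score_labels,
              layer1 = lapply(unname(stack$layers), ser_layer),
              layer2 = if (is.null(stack$layer2)) NULL
                       else ser_layer(stack$layer2),
              affine_A = unname(stack$affine_A), affine_c = stack$affine_c)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
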