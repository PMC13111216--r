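# Shared fixture builders: all synthetic, generated in code under fixed seeds.

# small valid feature grid: 2 cortical, 2 subcortical, 1 WM ROI -> 31 features
small_grid <- function() {
  build_feature_grid(c("FRP", "PUC"), c("Amyg", "PUT"), c("PLIC"))
}

# random feature table over a grid, with mild cross-feature correlation
rand_feature_table <- function(n, grid = small_grid(), seed = 1) {
  set.seed(seed)
  p <- nrow(grid)
  shared <- matrix(rnorm(n * 2), n, 2)
  load <- matrix(runif(p * 2, -0.5, 0.5), p, 2)
  X <- shared %*% t(load) + matrix(rnorm(n * p), n, p)
  X <- sweep(sweep(X, 2, runif(p, 0.5, 2), `*`), 2, runif(p, -1, 4), `+`)
  dimnames(X) <- list(sprintf("S%03d", seq_len(n)), grid$feature_id)
  feature_table(X, grid)
}

# cohort table matching a feature table's subjects
rand_outcomes <- function(tab, n_pwh = floor(nrow(tab$values) / 2),
                          seed = 2) {
  set.seed(seed)
  n <- nrow(tab$values)
  grp <- c(rep("PWH", n_pwh), rep("control", n - n_pwh))
  z0 <- rnorm(n)
  z1 <- ifelse(grp == "PWH", z0 + rnorm(n), NA_real_)
  compute_delta_z(data.frame(subject_id = tab$subject_ids, group = grp,
                             z_baseline = z0, z_followup = z1,
                             stringsAsFactors = FALSE))
}

# exhaustive minimum-AIC subset search (brute-force oracle for stepwise)
exhaustive_best_aic <- function(design, y) {
  cands <- colnames(design)
  best <- NULL
  for (m in 0:length(cands)) {
    for (s in if (m == 0) list(character(0)) else
         asplit(utils::combn(cands, m), 2)) {
      s <- as.character(s)
      if (length(s) > length(y) - 2) next
      aic <- ols_fit(design[, s, drop = FALSE], y)$aic
      if (is.null(best) || aic < best$aic - 1e-10) {
        best <- list(terms = s, aic = aic)
      }
    }
  }
  best
}

# assert a stepwise result is locally AIC-optimal (no single add/drop helps)
expect_locally_optimal <- function(fit, design, y) {
  cur <- fit$term_ids
  for (t in cur) {
    alt <- ols_fit(design[, setdiff(cur, t), drop = FALSE], y)$aic
    expect_gte(alt, fit$aic - 1e-10)
  }
  for (t in setdiff(colnames(design), cur)) {
    if (length(cur) + 1 > length(y) - 2) next
    alt <- ols_fit(design[, c(cur, t), drop = FALSE], y)$aic
    expect_gte(alt, fit$aic - 1e-10)
  }
}
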