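test_that("correlation PCA matches an independent decomposition", {
  set.seed(21)
  X <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, paste0("f", 1:4)))
  layer <- fit_correlation_pca(X, pve = 1)

  # oracle: standardize by hand, form the correlation matrix explicitly,
  # eigendecompose
  Z <- scale(X)
  R <- crossprod(Z) / (nrow(X) - 1)
  ev <- eigen(R, symmetric = TRUE)
  expect_equal(layer$eigenvalues, pmax(ev$values, 0), tolerance = 1e-10)
  expect_equal(sum(layer$eigenvalues), 4, tolerance = 1e-8)

  # independent SVD route via prcomp on the standardized data
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  expect_equal(layer$eigenvalues[1:4], unname(pc$sdev^2), tolerance = 1e-10)
  for (k in seq_len(layer$k_retained)) {
    expect_equal(abs(layer$scores[, k]), abs(unname(pc$x[, k])),
                 tolerance = 1e-8)
  }

  # loadings orthonormal; training scores centred with variance lambda
  V <- layer$loadings
  expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(colMeans(layer$scores), rep(0, layer$k_retained),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(apply(layer$scores, 2, var),
               layer$eigenvalues[seq_len(layer$k_retained)],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PVE truncation rule and degenerate geometries", {
  # p = 1: single unit eigenvalue, score is the z-scored column
  x <- matrix(c(1, 4, 2, 7), 4, 1, dimnames = list(NULL, "a"))
  ly <- fit_correlation_pca(x, pve = 0.8)
  expect_equal(ly$k_retained, 1L)
  expect_equal(ly$eigenvalues, 1)
  expect_equal(drop(ly$scores), drop(scale(x)), tolerance = 1e-12,
               ignore_attr = TRUE)

  # exactly proportional columns: eigenvalues (2, 0), one retained,
  # score = (z1 + z2)/sqrt(2)
  x1 <- c(0.2, 1.5, -0.7, 2.2, 0.4)
  X <- cbind(a = x1, b = 2 * x1)
  ly <- fit_correlation_pca(X, pve = 0.8)
  expect_equal(ly$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(ly$k_retained, 1L)
  z1 <- drop(scale(x1))
  expect_equal(drop(ly$scores), 2 * z1 / sqrt(2), tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(fit_correlation_pca(cbind(a = rep(1, 5), b = rnorm(5)),
                                   pve = 0.9), "constant column.*a")
  expect_error(fit_correlation_pca(X, pve = 0), "pve")
  expect_error(fit_correlation_pca(X, pve = 1.2), "pve")

  # PVE monotonicity of retention
  set.seed(33)
  Y <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, paste0("f", 1:8)))
  expect_gte(fit_correlation_pca(Y, 0.9)$k_retained,
             fit_correlation_pca(Y, 0.8)$k_retained)
})

test_that("transform is affine-consistent, row-independent and centred", {
  set.seed(5)
  X <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("f", 1:5)))
  ly <- fit_correlation_pca(X, pve = 0.9)
  expect_equal(pca_transform(ly, X), ly$scores, tolerance = 1e-12)
  expect_equal(pca_transform(ly, X[3, , drop = FALSE]),
               ly$scores[3, , drop = FALSE], tolerance = 1e-12)
  mu_rows <- matrix(ly$mu, 4, 5, byrow = TRUE,
                    dimnames = list(NULL, colnames(X)))
  expect_equal(max(abs(pca_transform(ly, mu_rows))), 0, tolerance = 1e-12)
  expect_error(pca_transform(ly, X[, 1:3]), "column count")
})

test_that("stacks compose exactly into their cached affine map", {
  grid <- small_grid()
  tab <- rand_feature_table(20, grid, seed = 44)

  # single feature, single group: closed-form map
  one <- tab$values[, 1, drop = FALSE]
  tab1 <- feature_table(one, tab$descriptors[1, , drop = FALSE])
  st1 <- fit_stack(tab1, grouping = "single_group", pve = 1)
  m <- stack_affine_map(st1)
  expect_equal(drop(m$A), 1 / sd(one), tolerance = 1e-12)
  expect_equal(m$c, -mean(one) / sd(one), tolerance = 1e-12)

  # one-layer, by-region stack: final dim is the sum of per-group retention
  st2 <- fit_stack(tab, grouping = "by_region", pve = 0.9,
                   two_layer = FALSE)
  expect_equal(st2$final_dim,
               sum(vapply(st2$layers, `[[`, integer(1), "k_retained")))

  # two-layer stack: affine map equals sequential evaluation on probe rows
  st3 <- fit_stack(tab, grouping = "by_region", pve = 0.9, two_layer = TRUE)
  set.seed(9)
  probes <- matrix(rnorm(100 * nrow(grid)), 100,
                   dimnames = list(NULL, grid$feature_id))
  expect_equal(stack_scores(st3, probes, use_affine = TRUE),
               stack_scores(st3, probes, use_affine = FALSE),
               tolerance = 1e-10)
  # training scores reproduced through the map at strict tolerance
  rel <- max(abs(stack_scores(st3, tab$values) - st3$scores)) /
    max(abs(st3$scores))
  expect_lt(rel, 1e-10)
})

test_that("correlation PCA is invariant to positive feature rescaling", {
  grid <- small_grid()
  tab <- rand_feature_table(18, grid, seed = 55)
  st <- fit_stack(tab, pve = 0.9)
  v2 <- tab$values
  set.seed(6)
  scl <- runif(ncol(v2), 0.01, 50)
  v2 <- sweep(v2, 2, scl, `*`)
  st2 <- fit_stack(feature_table(v2, grid), pve = 0.9)
  expect_equal(vapply(st2$layers, `[[`, integer(1), "k_retained"),
               vapply(st$layers, `[[`, integer(1), "k_retained"))
  for (g in names(st$layers)) {
    expect_equal(st2$layers[[g]]$eigenvalues, st$layers[[g]]$eigenvalues,
                 tolerance = 1e-8)
  }
  expect_equal(st2$scores, st$scores, tolerance = 1e-8)
})

test_that("permuting feature order permutes affine rows, predictions fixed", {
  grid <- small_grid()
  tab <- rand_feature_table(15, grid, seed = 66)
  st <- fit_stack(tab, grouping = "single_group", pve = 0.9)
  set.seed(3)
  perm <- sample(nrow(grid))
  tabp <- feature_table(tab$values[, perm], grid[perm, ])
  stp <- fit_stack(tabp, grouping = "single_group", pve = 0.9)
  expect_equal(stack_scores(stp, tabp$values),
               stack_scores(st, tab$values), tolerance = 1e-8)
  expect_equal(stp$affine_A[grid$feature_id[perm], ],
               st$affine_A[grid$feature_id[perm], ], tolerance = 1e-8)
})

test_that("stack serialization writes a complete JSON document", {
  tab <- rand_feature_table(12, seed = 77)
  st <- fit_stack(tab, pve = 0.8, two_layer = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  stack_to_json(st, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$pve, 0.8)
  expect_equal(doc$feature_ids, st$feature_ids)
  expect_equal(unname(doc$affine_A), unname(st$affine_A),
               tolerance = 1e-12, ignore_attr = TRUE)
})
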