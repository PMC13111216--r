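# helper: fit a stack + stepwise model on a fixture and back-propagate
fit_pipeline <- function(tab, y, two_layer = FALSE, pve = 0.9,
                         grouping = "by_region") {
  st <- fit_stack(tab, grouping = grouping, pve = pve,
                  two_layer = two_layer)
  fit <- stepwise_aic(st$scores, y)
  list(stack = st, fit = fit,
       weights = backpropagate_weights(st, fit))
}

test_that("single-feature closed form: adjusted weight equals PC coefficient", {
  set.seed(90)
  x <- rnorm(20, mean = 5, sd = 2)
  tab <- feature_table(matrix(x, 20, 1,
                              dimnames = list(sprintf("S%02d", 1:20),
                                              "Amyg.CBF.sub")))
  y <- 1 + 0.7 * scale(x)[, 1] + rnorm(20, sd = 0.1)
  st <- fit_stack(tab, grouping = "single_group", pve = 1)
  fit <- ols_fit(st$scores, y)
  w <- backpropagate_weights(st, fit)
  b1 <- unname(fit$beta_hat[1])
  expect_equal(w$beta_tilde, b1 / sd(x), tolerance = 1e-10)
  expect_equal(w$w, b1, tolerance = 1e-10)   # w = sigma * beta_tilde
})

test_that("adjusted weight is the product of SD and unadjusted weight", {
  # worked example at printed precision: unadjusted 1.873, SD 0.396
  expect_equal(round(1.873 * 0.396, 3), 0.742)
  # and the stored invariant holds exactly on a fitted pipeline
  tab <- rand_feature_table(30, seed = 91)
  set.seed(91)
  y <- rnorm(30)
  pl <- fit_pipeline(tab, y)
  expect_identical(pl$weights$w, pl$weights$sigma_hat * pl$weights$beta_tilde)
})

test_that("back-propagation is prediction-equivalent on one- and two-layer stacks", {
  for (seed in c(12, 13)) {
    tab <- rand_feature_table(30, seed = seed)
    set.seed(seed + 100)
    y <- drop(scale(tab$values[, 3]) * 0.8 + scale(tab$values[, 17]) * 0.5 +
                rnorm(30, sd = 0.6))
    for (two_layer in c(FALSE, TRUE)) {
      pl <- fit_pipeline(tab, y, two_layer = two_layer)
      eq <- verify_equivalence(tab, pl$stack, pl$fit, pl$weights)
      expect_lt(eq$max_gap, 1e-10 * eq$scale)
      expect_true(eq$pass)
    }
  }
})

test_that("fault injection breaks the equivalence detectably", {
  tab <- rand_feature_table(25, seed = 14)
  set.seed(14)
  y <- rnorm(25)
  pl <- fit_pipeline(tab, y)
  w <- pl$weights
  # zero one retained coefficient in the feature-space path only
  jmax <- which.max(abs(w$beta_tilde))
  w$beta_tilde[jmax] <- 0
  eq <- verify_equivalence(tab, pl$stack, pl$fit, w)
  expect_false(eq$pass)
  expect_gt(eq$max_gap, 0)
})

test_that("adjusted weights are invariant under positive feature rescaling", {
  tab <- rand_feature_table(28, seed = 15)
  set.seed(15)
  y <- drop(scale(tab$values[, 5]) + rnorm(28, sd = 0.8))
  pl <- fit_pipeline(tab, y)

  set.seed(16)
  scl <- runif(ncol(tab$values), 0.02, 40)
  tab2 <- feature_table(sweep(tab$values, 2, scl, `*`), tab$descriptors)
  pl2 <- fit_pipeline(tab2, y)
  expect_equal(pl2$weights$w, pl$weights$w, tolerance = 1e-8)
  # while the raw coefficients scale inversely
  expect_equal(pl2$weights$beta_tilde, pl$weights$beta_tilde / scl,
               tolerance = 1e-8)
})

test_that("one-SD perturbation of feature j moves the prediction by w_j", {
  tab <- rand_feature_table(22, seed = 18)
  set.seed(18)
  y <- rnorm(22)
  pl <- fit_pipeline(tab, y, two_layer = TRUE)
  w <- pl$weights
  predict_ft <- function(X) {
    attr(w, "beta0_tilde") + drop(X %*% w$beta_tilde)
  }
  base <- predict_ft(tab$values)
  for (j in c(1, 7, 20)) {
    pert <- tab$values
    pert[4, j] <- pert[4, j] + w$sigma_hat[j]
    expect_equal(unname(predict_ft(pert)[4] - base[4]), w$w[j],
                 tolerance = 1e-10)
  }
})

test_that("weights are invariant to eigenvector sign flips", {
  tab <- rand_feature_table(26, seed = 19)
  set.seed(19)
  y <- rnorm(26)
  pl <- fit_pipeline(tab, y)
  st <- pl$stack
  # flip signs of alternating loading columns in every layer and rebuild the
  # affine map by hand; refit the regression in the flipped score basis
  flip <- rep(c(1, -1), length.out = st$final_dim)
  A <- sweep(st$affine_A, 2, flip, `*`)
  cc <- st$affine_c * flip
  scores <- sweep(st$scores, 2, flip, `*`)
  st2 <- st
  st2$affine_A <- A; st2$affine_c <- cc; st2$scores <- scores
  fit2 <- stepwise_aic(scores, y)
  w2 <- backpropagate_weights(st2, fit2)
  expect_equal(w2$w, pl$weights$w, tolerance = 1e-8)
  expect_equal(attr(w2, "beta0_tilde"), attr(pl$weights, "beta0_tilde"),
               tolerance = 1e-8)
})

test_that("ranking reproduces the published weight-report layout", {
  # printed adjusted-weight columns of the two study weight tables
  t2 <- data.frame(
    feature_id = c("Amyg.CBF.sub", "PUC.CVR.cor", "GP.Vol.sub",
                   "PUT.FW.sub", "CN.MD.sub", "GP.FA.sub", "AccN.CBF.sub",
                   "CN.Vol.sub"),
    w = c(-0.864, 0.742, -0.718, 0.699, 0.568, -0.541, 0.501, 0.501),
    stringsAsFactors = FALSE)
  below <- data.frame(feature_id = c("TH.CVR.sub", "FRP.CT.cor"),
                      w = c(0.43, -0.21), stringsAsFactors = FALSE)
  mk_weights <- function(df) {
    out <- data.frame(feature_id = df$feature_id, beta_tilde = df$w / 0.5,
                      sigma_hat = 0.5, mean = 1, w = df$w,
                      screened_out = FALSE, stringsAsFactors = FALSE)
    attr(out, "beta0_tilde") <- 0
    class(out) <- c("equivalent_weights", "data.frame")
    out
  }
  shuffled <- rbind(t2[c(3, 1, 5, 8, 2, 7, 4, 6), ], below)
  rep2 <- rank_and_select(mk_weights(shuffled), w_min = 0.5)
  expect_equal(nrow(rep2), 8L)
  expect_equal(rep2$feature_id[1], "Amyg.CBF.sub")
  expect_equal(abs(rep2$adjusted_weight[1]), 0.864)
  # |w| ties broken lexicographically by feature id
  tie_rows <- rep2$feature_id[abs(rep2$adjusted_weight) == 0.501]
  expect_equal(tie_rows, sort(tie_rows))
  expect_equal(colnames(rep2),
               c("feature_id", "adjusted_weight", "unadjusted_weight",
                 "mean", "sd"))

  t3_w <- c(4.338, -1.798, 1.704, -1.494, -1.284, -1.211, -1.058, -0.960,
            0.953, -0.916, -0.867, -0.850, 0.818, -0.816, -0.803, 0.735,
            -0.714, 0.701, -0.700, 0.661, 0.603, 0.595)
  t3 <- data.frame(feature_id = sprintf("F%02d.FW.wm", seq_along(t3_w)),
                   w = t3_w, stringsAsFactors = FALSE)
  t3$feature_id[1] <- "ALIC.FW.wm"
  rep3 <- rank_and_select(mk_weights(t3[sample(nrow(t3)), ]), w_min = 0.5)
  expect_equal(nrow(rep3), 22L)
  expect_equal(rep3$feature_id[1], "ALIC.FW.wm")
  expect_equal(rep3$adjusted_weight[1], 4.338)

  # all-zero weights produce an empty report
  zero <- mk_weights(data.frame(feature_id = "A.FA.wm", w = 0))
  expect_equal(nrow(rank_and_select(zero)), 0L)
})

test_that("screened-out features are reported with zero weights", {
  tab <- rand_feature_table(24, seed = 20)
  keep <- tab$descriptors$feature_id[seq(1, 31, by = 2)]
  sub <- feature_table(tab$values[, keep],
                       tab$descriptors[match(keep,
                                             tab$descriptors$feature_id), ])
  set.seed(20)
  y <- rnorm(24)
  pl <- fit_pipeline(sub, y)
  full <- expand_weights(pl$weights, tab$descriptors)
  expect_equal(nrow(full), 31L)
  dropped <- !full$feature_id %in% keep
  expect_true(all(full$screened_out[dropped]))
  expect_true(all(full$w[dropped] == 0))
  expect_true(all(full$beta_tilde[dropped] == 0))
  expect_equal(full$w[!dropped],
               pl$weights$w[match(full$feature_id[!dropped],
                                  pl$weights$feature_id)])
})
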