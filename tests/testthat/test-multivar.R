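test_that("PCA agrees with an eigendecomposition oracle", {
  ft <- make_ft(n_per_group = 6, n_features = 10, seed = 31)
  X <- pareto_scale(ft$intensities)$matrix
  pca <- fit_pca(X, n_components = 3)
  ev <- eigen(crossprod(X), symmetric = TRUE)
  expect_equal(pca$explained, (ev$values / sum(ev$values))[1:3],
               tolerance = 1e-10)
  for (j in 1:3) {   # loadings match eigenvectors up to sign
    expect_equal(abs(drop(crossprod(pca$loadings[, j], ev$vectors[, j]))), 1,
                 tolerance = 1e-8)
  }
  # scores reproduce the projection of X on the loadings
  expect_equal(pca$scores, X %*% pca$loadings, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PCA sign convention is deterministic", {
  ft <- make_ft(n_per_group = 5, n_features = 8, seed = 13)
  X <- pareto_scale(ft$intensities)$matrix
  p1 <- fit_pca(X)
  p2 <- fit_pca(X[, rev(colnames(X))])
  expect_equal(p1$explained, p2$explained)
  for (j in 1:2) {
    expect_gt(p1$loadings[which.max(abs(p1$loadings[, j])), j], 0)
  }
})

test_that("OPLS predictive weights match the power-iteration oracle", {
  ft <- make_ft(n_per_group = 6, n_features = 12, n_effect = 3, fold = 4,
                seed = 17)
  X <- pareto_scale(sum_normalize(ft))$matrix
  m <- fit_oplsda(X, ft$group, n_orthogonal = 0, cv_folds = 3)
  y <- metaboflow:::class_response(ft$group)$y
  # with no orthogonal removal the predictive weight is proportional to X'y,
  # the dominant eigenvector of the rank-one matrix (X'y)(X'y)'
  oracle <- power_iteration(tcrossprod(crossprod(X, y)))
  w <- unname(m$weights)
  expect_equal(abs(sum(w * oracle)), 1, tolerance = 1e-8)
  expect_equal(w, drop(crossprod(X, y)) / sqrt(sum(crossprod(X, y)^2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the mean of squared VIP scores is exactly one", {
  ft <- make_ft(n_per_group = 7, n_features = 25, n_effect = 5, seed = 23)
  X <- pareto_scale(sum_normalize(ft))$matrix
  for (no in 0:2) {
    m <- fit_oplsda(X, ft$group, n_orthogonal = no, cv_folds = 3)
    expect_equal(mean(m$vip^2), 1, tolerance = 1e-12)
  }
  mt <- fit_oplsda(X, ft$group, n_orthogonal = 2, cv_folds = 3,
                   vip_mode = "total")
  expect_equal(mean(mt$vip^2), 1, tolerance = 1e-12)
})

test_that("Q2 never exceeds R2Y and both are high for separable groups", {
  ft <- make_ft(n_per_group = 9, n_features = 30, n_effect = 8, fold = 4,
                seed = 29)
  X <- pareto_scale(sum_normalize(ft))$matrix
  m <- fit_oplsda(X, ft$group, n_orthogonal = "auto", cv_folds = 7)
  expect_lte(m$Q2, m$R2Y)
  expect_gt(m$Q2, 0.5)
  expect_lte(m$R2Y, 1)
})

test_that("orthogonal scores are uncorrelated with the class response", {
  ft <- make_ft(n_per_group = 8, n_features = 20, n_effect = 4, seed = 37)
  X <- pareto_scale(sum_normalize(ft))$matrix
  m <- fit_oplsda(X, ft$group, n_orthogonal = 2, cv_folds = 4)
  for (to in m$ortho_scores) {
    expect_lt(abs(stats::cor(to, m$y)), 1e-8)
  }
})

test_that("stratified folds preserve both classes and respect group sizes", {
  labels <- rep(c("NC", "HFD"), each = 9)
  folds <- metaboflow:::make_stratified_folds(labels, 7, seed = 1)
  expect_length(folds, 18)
  for (f in 1:7) {
    expect_true(all(c("NC", "HFD") %in% labels[folds != f]))
  }
  expect_error(metaboflow:::make_stratified_folds(rep(c("NC", "HFD"), 3), 7, 1),
               "exceeds the smallest group")
})

test_that("permutation p-values are one-sided, add-one, and never zero", {
  ft <- make_ft(n_per_group = 6, n_features = 15, n_effect = 5, fold = 5,
                seed = 41)
  X <- pareto_scale(sum_normalize(ft))$matrix
  pt <- permutation_test(X, ft$group, n_permutations = 39, seed = 1,
                         folds = 3)
  expect_gt(pt$p_Q2, 0)
  expect_lte(pt$p_Q2, 1)
  expect_equal(pt$p_Q2, (1 + sum(pt$permuted[, "Q2"] >=
                                   pt$observed[["Q2"]] - 1e-12)) / 40)
  expect_lt(pt$p_Q2, 0.1)   # strongly separable: near the resolution floor
  expect_error(permutation_test(X, ft$group, n_permutations = 5),
               ">= 20")
})

test_that("model fits are deterministic in their seed and restore the RNG", {
  ft <- make_ft(n_per_group = 6, n_features = 10, n_effect = 2, seed = 43)
  X <- pareto_scale(sum_normalize(ft))$matrix
  set.seed(99); before <- runif(3); set.seed(99)
  m1 <- fit_oplsda(X, ft$group, cv_folds = 3, seed = 7)
  after <- runif(3)
  expect_identical(before, after)   # with_seed left the caller's RNG alone
  m2 <- fit_oplsda(X, ft$group, cv_folds = 3, seed = 7)
  expect_identical(m1$Q2, m2$Q2)
  expect_identical(m1$vip, m2$vip)
})

test_that("the class response is a centered two-level contrast", {
  resp <- metaboflow:::class_response(rep(c("NC", "HFD"), each = 4))
  expect_equal(mean(resp$y), 0)
  expect_equal(sort(unique(resp$raw)), c(-1, 1))
  expect_equal(resp$levels, c("HFD", "NC"))
  expect_error(metaboflow:::class_response(rep("NC", 5)), "two classes")
})
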