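tiny_fm <- function(...) {
  d <- data.frame(...)
  class(d) <- c("feature_matrix", "data.frame")
  d
}

test_that("standardization centres and scales with population sd", {
  fm <- tiny_fm(a = c(2, 4, 6), label = c(1L, 1L, 2L))
  std <- fit_standardizer(fm)
  out <- apply_standardizer(std, fm)
  expect_equal(out$a, c(-1.224745, 0, 1.224745), tolerance = 1e-6)

  fm2 <- tiny_fm(a = c(2, 4, 6), b = c(5, 5, 5), label = c(1L, 1L, 2L))
  std2 <- fit_standardizer(fm2)
  expect_true(std2$constant[["b"]])
  out2 <- apply_standardizer(std2, fm2)
  expect_equal(out2$b, c(0, 0, 0))
  expect_identical(out2$label, fm2$label)
})

test_that("standardizing the training matrix twice is idempotent", {
  fm <- table3_features(1)[1:500, ]
  class(fm) <- c("feature_matrix", "data.frame")
  once <- apply_standardizer(fit_standardizer(fm), fm)
  expect_true(all(abs(colMeans(as.matrix(once[feature_names()]))) < 1e-9))
  twice <- apply_standardizer(fit_standardizer(once), once)
  expect_equal(as.matrix(twice[feature_names()]),
               as.matrix(once[feature_names()]), tolerance = 1e-9)
})

test_that("correlation screening finds duplicated and avoids independent columns", {
  set.seed(31)
  n <- 1000
  a <- rnorm(n)
  fm <- tiny_fm(a = a, b = a + rnorm(n, sd = 1e-6), c = rnorm(n),
                label = rep(1L, n))
  pairs <- find_correlated(fm, threshold = 0.7)
  expect_equal(nrow(pairs), 1)
  expect_setequal(c(pairs$feature_a, pairs$feature_b), c("a", "b"))
  expect_gt(pairs$r, 0.999)

  indep <- tiny_fm(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                   label = rep(1L, n))
  expect_equal(nrow(find_correlated(indep, 0.7)), 0)

  # constant features are excluded, not NaN-flagged
  withcon <- tiny_fm(a = rnorm(n), k = rep(1, n), label = rep(1L, n))
  expect_equal(nrow(find_correlated(withcon, 0.7)), 0)
})

test_that("redundant same-axis spread features are flagged on synthetic data", {
  fm <- table3_features(1)
  pairs <- find_correlated(fm, threshold = 0.7)
  key <- paste(pairs$feature_a, pairs$feature_b)
  for (ax in c("x", "y")) {
    expect_true(paste0("sd_", ax, " variance_", ax) %in% key ||
                  paste0("variance_", ax, " sd_", ax) %in% key)
    expect_true(any(grepl(paste0("sd_", ax), key) &
                      grepl(paste0("energy_", ax), key)))
  }
})

test_that("greedy removal drops the most-connected feature first", {
  fm <- tiny_fm(a = 1:5, b = 2:6, c = 3:7, label = rep(1L, 5))
  # synthetic flagged chain a~b, b~c: b has degree 2 and must go
  pairs <- data.frame(feature_a = c("a", "b"), feature_b = c("b", "c"),
                      r = c(0.9, 0.9))
  out <- drop_correlated(fm, pairs)
  expect_identical(attr(out, "dropped"), "b")
  expect_setequal(names(out), c("a", "c", "label"))

  # duplicated column: exactly one of the two goes (the later one)
  dup_pairs <- data.frame(feature_a = "a", feature_b = "b", r = 1)
  out2 <- drop_correlated(fm, dup_pairs)
  expect_identical(attr(out2, "dropped"), "b")

  # no pairs: unchanged
  none <- drop_correlated(fm, pairs[0, ])
  expect_setequal(names(none), names(fm))
})

test_that("PCA keeps the smallest component set reaching the variance target", {
  set.seed(32)
  x <- matrix(rnorm(500 * 31), 500, 31)
  fm <- as.data.frame(x)
  names(fm) <- paste0("f", 1:31)
  fm$label <- rep(1L, 500)
  class(fm) <- c("feature_matrix", "data.frame")
  std <- apply_standardizer(fit_standardizer(fm), fm)
  model <- fit_pca(std, var_threshold = 0.95)

  # oracle: full eigendecomposition of the covariance matrix
  ev <- sort(eigen(stats::cov(as.matrix(std[paste0("f", 1:31)])),
                   symmetric = TRUE)$values, decreasing = TRUE)
  cum <- cumsum(ev / sum(ev))
  k_oracle <- which(cum >= 0.95)[1]
  expect_equal(model$k, k_oracle)
  expect_gte(sum(model$explained[seq_len(model$k)]), 0.95)
  expect_lt(sum(model$explained[seq_len(model$k - 1)]), 0.95)
  # sample eigenvalues match prcomp's explained fractions
  expect_equal(model$explained, ev / sum(ev), tolerance = 1e-6)
  # explained fractions are non-increasing and sum to <= 1
  expect_true(all(diff(model$explained) <= 1e-12))
  expect_lte(sum(model$explained), 1 + 1e-9)

  red <- apply_pca(model, std)
  expect_equal(ncol(red), model$k + 1)  # scores + label
  expect_identical(red$label, std$label)
})

test_that("lossless and rank-1 PCA limits behave as expected", {
  set.seed(33)
  x <- matrix(rnorm(100 * 5), 100, 5)
  fm <- as.data.frame(x)
  names(fm) <- paste0("f", 1:5)
  fm$label <- rep(1L, 100)
  class(fm) <- c("feature_matrix", "data.frame")

  full <- fit_pca(fm, var_threshold = 1.0)
  expect_equal(full$k, 5)
  scores <- as.matrix(apply_pca(full, fm)[paste0("PC", 1:5)])
  recon <- sweep(scores %*% t(full$rotation), 2, full$center, "+")
  expect_lt(max(abs(recon - x)), 1e-9)
  # full-rank projection preserves pairwise distances
  d0 <- stats::dist(x)
  d1 <- stats::dist(scores)
  expect_lt(max(abs(d0 - d1)), 1e-6)

  rank1 <- fm
  dir <- rnorm(5)
  base <- rnorm(100)
  rank1[paste0("f", 1:5)] <- outer(base, dir)
  expect_equal(fit_pca(rank1, 0.95)$k, 1)

  expect_error(fit_pca(fm, 0), "var_threshold")
  expect_error(fit_pca(fm, 1.5), "var_threshold")
})

test_that("fold-wise preprocessing differs from the leaky global fit", {
  # trees are invariant to per-feature affine maps, so the leak only
  # becomes visible through PCA, whose rotation mixes features
  fm <- blob_features(sd = 2, seed = 77L)
  safe <- crossval(fm, model_spec("bagged_trees"), k = 4, pca = TRUE,
                   global_prep = FALSE, seed = 9L)
  leaky <- crossval(fm, model_spec("bagged_trees"), k = 4, pca = TRUE,
                    global_prep = TRUE, seed = 9L)
  expect_false(identical(safe$confusion, leaky$confusion))
  expect_true(leaky$config$global_prep)
})
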