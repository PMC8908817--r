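test_that("confusion metrics match hand-computed examples", {
  perfect <- metrics_from_confusion(diag(c(5, 5, 5)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$per_class$f1, rep(1, 3))
  expect_equal(perfect$overall_f1, 1)

  # class 1: TP = 8, FP = 2 -> precision 0.8
  cm2 <- rbind(c(8, 0), c(2, 3))
  expect_equal(metrics_from_confusion(cm2)$per_class$precision[1], 0.8)

  cm3 <- rbind(c(10, 0, 0), c(0, 5, 5), c(0, 0, 10))
  m <- metrics_from_confusion(cm3)
  expect_equal(m$per_class$recall[2], 0.5)
  expect_equal(m$per_class$precision[3], 10 / 15)
  expect_equal(m$per_class$precision, c(1, 1, 2 / 3))
  expect_equal(m$per_class$recall, c(1, 0.5, 1))
  expect_equal(m$per_class$f1, c(1, 2 / 3, 0.8))
  expect_equal(m$accuracy, 25 / 30)
  expect_equal(m$overall_f1, mean(c(1, 2 / 3, 0.8)))

  expect_error(metrics_from_confusion(matrix(0, 3, 3)), "empty")
})

test_that("metric formulas agree with a brute-force tally on random matrices", {
  set.seed(51)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 4), k, k)
    if (sum(cm) == 0) next
    m <- suppressWarnings(metrics_from_confusion(cm))
    o <- oracle_metrics(cm)
    expect_identical(m$accuracy, o$accuracy)
    expect_identical(m$per_class$precision, o$precision)
    expect_identical(m$per_class$recall, o$recall)
    expect_identical(m$per_class$f1, o$f1)
    expect_identical(m$overall_f1, o$overall_f1)
    # accuracy is the recall mean weighted by true-class proportions
    expect_equal(m$accuracy,
                 sum(o$recall * rowSums(cm) / sum(cm)), tolerance = 1e-12)
  }
})

test_that("macro F1 is invariant under class relabelling", {
  set.seed(52)
  cm <- matrix(rpois(9, 10), 3, 3)
  m0 <- suppressWarnings(metrics_from_confusion(cm))
  perm <- c(3, 1, 2)
  m1 <- suppressWarnings(metrics_from_confusion(cm[perm, perm]))
  expect_equal(sort(m0$per_class$f1), sort(m1$per_class$f1))
  expect_equal(m0$overall_f1, m1$overall_f1)
  expect_equal(m0$accuracy, m1$accuracy)
})

test_that("undefined 0/0 metrics warn and report zero", {
  cm <- rbind(c(5, 0, 0), c(5, 0, 0), c(5, 0, 0))
  expect_warning(m <- metrics_from_confusion(cm), "undefined")
  expect_equal(m$per_class$precision[2:3], c(0, 0))
  expect_equal(m$per_class$f1[2:3], c(0, 0))
})

test_that("the paired t-test matches the reference implementation", {
  expect_equal(paired_ttest(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, p = 1, df = 2L))
  expect_error(paired_ttest(1, 1), "insufficient pairs")
  expect_error(paired_ttest(1:3, 1:4), "equal length")

  set.seed(53)
  a <- rnorm(10)
  b <- a + 0.5 + rnorm(10, sd = 0.3)
  got <- paired_ttest(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(got$p, ref$p.value, tolerance = 1e-6)
  expect_equal(got$df, unname(ref$parameter))

  # constant nonzero shift: degenerate, p = 0 by convention
  shifted <- paired_ttest(c(1, 2, 3) + 1, c(1, 2, 3))
  expect_equal(shifted$p, 0)
  expect_true(is.infinite(shifted$t))
})

test_that("perfectly separable classes are classified perfectly", {
  fm <- blob_features(sd = 0.3)
  for (fam in c("bagged_trees", "random_forest")) {
    rep_ <- crossval(fm, model_spec(fam), seed = 2L)
    expect_equal(rep_$accuracy, 1)
    expect_equal(rep_$per_class$f1, rep(1, 3))
    expect_equal(rep_$overall_f1, 1)
  }
})

test_that("permuted labels collapse accuracy to the majority proportion", {
  fm <- blob_features(n_per_class = c(100, 30, 20), sd = 0.3, seed = 88L)
  set.seed(54)
  fm$label <- sample(fm$label)
  rep_ <- crossval(fm, model_spec("bagged_trees"), penalties = FALSE,
                   seed = 4L)
  p0 <- max(table(fm$label)) / nrow(fm)
  se <- sqrt(p0 * (1 - p0) / nrow(fm))
  expect_lt(abs(rep_$accuracy - p0), 3 * se)
})

test_that("cross-validation is reproducible and validates its folds", {
  fm <- blob_features(sd = 2)
  a <- crossval(fm, model_spec("bagged_trees"), seed = 6L)
  b <- crossval(fm, model_spec("bagged_trees"), seed = 6L)
  expect_identical(a$confusion, b$confusion)
  expect_identical(a$fold_accuracies, b$fold_accuracies)
  c2 <- crossval(fm, model_spec("bagged_trees"), seed = 7L)
  expect_false(identical(a$fold_accuracies, c2$fold_accuracies))

  rare <- blob_features(n_per_class = c(50, 50, 3))
  expect_error(crossval(rare, model_spec("bagged_trees"), k = 4),
               "fewer windows")
  # in plain random partitioning a singleton class must miss the training
  # side of the fold that holds it
  singleton <- blob_features(n_per_class = c(50, 50, 1))
  expect_error(
    crossval(singleton, model_spec("bagged_trees"), k = 2,
             stratified = FALSE, seed = 1L),
    "stratified")
})

test_that("holdout validation bounds and degenerate classes behave", {
  fm <- blob_features(sd = 0.8, seed = 101L)
  cv <- crossval(fm, model_spec("bagged_trees"), seed = 8L)
  resub <- holdout_validate(fm, fm, model_spec("bagged_trees"), seed = 8L)
  expect_gte(resub$accuracy, cv$accuracy)

  test_no3 <- fm[fm$label != 3, ]
  class(test_no3) <- c("feature_matrix", "data.frame")
  w <- capture_warnings(
    r <- holdout_validate(fm, test_no3, model_spec("bagged_trees"),
                          seed = 8L))
  expect_true(any(grepl("absent from the test session", w)))
  expect_equal(r$per_class$recall[3], 0)
  expect_true(all(r$confusion[3, ] == 0))

  mism <- fm
  names(mism)[1] <- "other"
  class(mism) <- c("feature_matrix", "data.frame")
  expect_error(holdout_validate(fm, mism, model_spec("bagged_trees")),
               "schemas")
})

test_that("the subspace-KNN extra votes over random feature subspaces", {
  fm <- blob_features(sd = 0.3)
  w <- capture_warnings(
    crossval(fm, model_spec("subspace_knn", n_trees = 15), seed = 3L))
  expect_true(any(grepl("does not support class weights", w)))
  unweighted <- crossval(fm, model_spec("subspace_knn", n_trees = 15),
                         penalties = FALSE, seed = 3L)
  expect_gt(unweighted$accuracy, 0.9)
})

test_that("the experiment grid reports cells, repeats and paired tests", {
  s <- rich_session()
  grid <- run_experiment_grid(s$trace, s$track, window_s = c(1, 4),
                              pca = FALSE, families = "bagged_trees",
                              repeats = 2, seed = 5L)
  expect_equal(nrow(grid$metrics), 4)  # 2 cells x 2 repeats
  expect_true(all(grid$metrics$accuracy >= 0 & grid$metrics$accuracy <= 1))
  expect_equal(nrow(grid$tests), 5)    # long-vs-short on 5 metrics
  expect_true(all(grid$tests$comparison == "long_vs_short"))
  expect_true(all(grid$tests$p >= 0 & grid$tests$p <= 1))

  single <- run_experiment_grid(s$trace, s$track, window_s = 1,
                                pca = FALSE, families = "bagged_trees",
                                repeats = 1, seed = 5L)
  expect_equal(nrow(single$metrics), 1)
  expect_equal(nrow(single$tests), 0)
})
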