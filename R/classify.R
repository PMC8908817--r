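#' Ensemble model specification
#'
#' Both tree ensembles bootstrap-aggregate decision trees and differ in one
#' structural choice: the random forest draws a random subset of
#' `floor(sqrt(p))` features at every split, while bagged trees consider
#' all `p` features. A random-subspace KNN ensemble is provided as an
#' optional extra; it votes over KNN learners each restricted to a random
#' `sqrt(p)`-dimensional feature subspace and does not support class
#' weights.
#'
#' @param family `"bagged_trees"`, `"random_forest"` or `"subspace_knn"`.
#' @param n_trees Number of trees (or subspace learners); default 100.
#' @param knn_k Neighbour count for the subspace-KNN family.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("bagged_trees", "random_forest",
                                  "subspace_knn"),
                       n_trees = 100L, knn_k = 5L) {
  family <- match.arg(family)
  stopifnot(n_trees >= 1L)
  structure(list(family = family, n_trees = as.integer(n_trees),
                 knn_k = as.integer(knn_k)),
            class = "model_spec")
}

# Fit one model on a feature matrix (label column excluded from x).
# weights: named per-class penalty vector or NULL for unweighted training.
# Tree ensembles are grown as probability forests; the penalties enter the
# Bayes decision rule at prediction time: with row-constant
# misclassification costs, minimizing expected cost is equivalent to
# predicting argmax_j penalty_j * P(class j | x).
fit_model <- function(fm, model, weights = NULL, seed = 1L) {
  x <- as.matrix(fm[feature_cols(fm)])
  y <- factor(fm$label)
  if (model$family %in% c("bagged_trees", "random_forest")) {
    p <- ncol(x)
    mtry <- if (model$family == "bagged_trees") p else max(1L, floor(sqrt(p)))
    fit <- ranger::ranger(x = x, y = y,
                          num.trees = model$n_trees, mtry = mtry,
                          probability = TRUE,
                          seed = seed, num.threads = 1L)
    w <- if (is.null(weights)) rep(1, nlevels(y))
         else unname(weights[levels(y)])
    list(kind = "ranger", fit = fit, levels = levels(y), w = w)
  } else {
    if (!requireNamespace("class", quietly = TRUE))
      stop("the 'class' package is required for subspace_knn",
           call. = FALSE)
    if (!is.null(weights))
      warning("subspace_knn does not support class weights; ignoring them",
              call. = FALSE)
    p <- ncol(x)
    d <- max(1L, round(sqrt(p)))
    subspaces <- with_local_seed(seed, replicate(
      model$n_trees, sort(sample.int(p, d)), simplify = FALSE))
    list(kind = "subspace_knn", x = x, y = y, subspaces = subspaces,
         k = model$knn_k, levels = levels(y))
  }
}

predict_model <- function(fit, fm) {
  x <- as.matrix(fm[colnames2(fit)])
  if (fit$kind == "ranger") {
    prob <- stats::predict(fit$fit, data = x,
                           num.threads = 1L)$predictions
    prob <- prob[, fit$levels, drop = FALSE]
    scores <- sweep(prob, 2L, fit$w, "*")
    # ties go to the higher (rarer, more dynamic) class
    fit$levels[max.col(scores, ties.method = "last")]
  } else {
    votes <- matrix(0L, nrow(x), length(fit$levels),
                    dimnames = list(NULL, fit$levels))
    for (s in fit$subspaces) {
      pred <- class::knn(fit$x[, s, drop = FALSE], x[, s, drop = FALSE],
                         fit$y, k = min(fit$k, nrow(fit$x)))
      idx <- cbind(seq_len(nrow(x)), match(as.character(pred), fit$levels))
      votes[idx] <- votes[idx] + 1L
    }
    fit$levels[max.col(votes, ties.method = "last")]
  }
}

colnames2 <- function(fit) {
  if (fit$kind == "ranger") fit$fit$forest$independent.variable.names
  else colnames(fit$x)
}

#' Confusion-matrix metrics
#'
#' For each class `i` in the one-vs-rest reading: `TP = cm[i, i]`,
#' `FP = colsum_i - TP`, `FN = rowsum_i - TP`, `TN = total - TP - FP - FN`;
#' precision = TP / (TP + FP), recall = TP / (TP + FN), per-class F1 is
#' their harmonic mean; 0/0 is defined as 0 (with a warning). Accuracy is
#' the standard multiclass `sum(diag) / total`, and the overall (macro) F1
#' is the arithmetic mean of the per-class F1 scores.
#'
#' @param cm Square matrix of non-negative counts, rows = true classes,
#'   columns = predicted classes.
#' @return List with `confusion`, `accuracy`, `per_class` (data frame with
#'   precision, recall, f1 per class) and `overall_f1`.
#' @examples
#' cm <- rbind(c(10, 0, 0), c(0, 5, 5), c(0, 0, 10))
#' metrics_from_confusion(cm)$per_class
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(cm)
  labels <- rownames(cm)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  ratio0 <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning(sprintf("%s undefined (0/0) for class %s; reported as 0",
                      what, paste(labels[bad], collapse = ", ")),
              call. = FALSE)
    ifelse(den == 0, 0, num / den)
  }
  precision <- ratio0(tp, tp + fp, "precision")
  recall <- ratio0(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  list(confusion = cm,
       accuracy = sum(tp) / total,
       per_class = data.frame(class = labels, precision = precision,
                              recall = recall, f1 = f1,
                              row.names = NULL),
       overall_f1 = mean(f1))
}

new_evaluation_report <- function(cm, fold_accuracies, config) {
  m <- metrics_from_confusion(cm)
  structure(c(m, list(fold_accuracies = fold_accuracies, config = config)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("<evaluation_report>\n")
  print(x$confusion)
  cat(sprintf("accuracy: %.*f   overall (macro) F1: %.*f\n",
              digits, x$accuracy, digits, x$overall_f1))
  pc <- x$per_class
  pc[-1] <- round(pc[-1], digits)
  print(pc)
  if (length(x$fold_accuracies))
    cat("fold accuracies:",
        paste(round(x$fold_accuracies, digits), collapse = " "), "\n")
  invisible(x)
}

# Seeded fold assignment. Stratified assignment shuffles within each class
# so every fold carries every class (required when one class holds only a
# few dozen windows).
make_folds <- function(labels, k, stratified, seed) {
  n <- length(labels)
  with_local_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < k)
          stop(sprintf(
            "class %s has fewer windows (%d) than folds (%d)",
            cl, length(idx), k), call. = FALSE)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    fold
  })
}

# Fit-on-train / apply-to-both preprocessing used by crossval and holdout.
prep_fold <- function(train, test, standardize, pca, pca_var) {
  if (standardize) {
    std <- fit_standardizer(train)
    train <- apply_standardizer(std, train)
    test <- apply_standardizer(std, test)
  }
  if (pca) {
    pm <- fit_pca(train, var_threshold = pca_var)
    train <- apply_pca(pm, train)
    test <- apply_pca(pm, test)
  }
  list(train = train, test = test)
}

resolve_weights <- function(penalties, train_labels) {
  if (inherits(penalties, "penalty_matrix")) return(penalties$weights)
  if (isTRUE(penalties)) return(compute_penalties(table(train_labels))$weights)
  NULL
}

#' Penalty-weighted k-fold cross-validation
#'
#' Splits the windows into `k` seeded folds (stratified by class unless
#' `stratified = FALSE`), and for every fold fits the preprocessing
#' (standardization, optional PCA) and the misclassification penalties on
#' the training part only before training the ensemble and predicting the
#' held-out part. Out-of-fold predictions are pooled into a single
#' confusion matrix. `global_prep = TRUE` instead fits standardizer, PCA
#' and penalties once on the full matrix before splitting — statistically
#' leaky, but it mirrors a common legacy protocol and is exposed so that
#' the difference can be measured.
#'
#' @param features A `feature_matrix`.
#' @param model A `model_spec`.
#' @param k Number of folds (default 4).
#' @param penalties `TRUE` to derive Eq.-style inverse-frequency penalties
#'   from the training data, `FALSE`/`NULL` for unweighted training, or a
#'   `penalty_matrix` to use as-is.
#' @param standardize Standardize features (fitted per training fold)?
#' @param pca Apply PCA (fitted per training fold)?
#' @param pca_var PCA explained-variance target.
#' @param stratified Stratify folds by class?
#' @param global_prep Fit standardizer/PCA/penalties globally before
#'   splitting (leaky legacy protocol)?
#' @param seed Integer seed controlling folds and tree growing; fixed seed
#'   gives bit-identical reports.
#' @return An `evaluation_report`.
#' @export
crossval <- function(features, model, k = 4L, penalties = TRUE,
                     standardize = TRUE, pca = FALSE, pca_var = 0.95,
                     stratified = TRUE, global_prep = FALSE, seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(model, "model_spec"), k >= 2L)
  labels <- features$label
  fold <- make_folds(labels, k, stratified, seed)
  classes <- sort(unique(labels))

  g_std <- g_pca <- g_w <- NULL
  if (global_prep) {
    full <- features
    if (standardize) {
      g_std <- fit_standardizer(full)
      full <- apply_standardizer(g_std, full)
    }
    if (pca) g_pca <- fit_pca(full, var_threshold = pca_var)
    g_w <- resolve_weights(penalties, labels)
  }

  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  fold_acc <- numeric(k)
  for (i in seq_len(k)) {
    tr <- features[fold != i, , drop = FALSE]
    te <- features[fold == i, , drop = FALSE]
    if (!all(classes %in% tr$label))
      stop("a class is absent from a training fold; use stratified = TRUE",
           call. = FALSE)
    if (global_prep) {
      if (standardize) {
        tr <- apply_standardizer(g_std, tr)
        te <- apply_standardizer(g_std, te)
      }
      if (pca) {
        tr <- apply_pca(g_pca, tr)
        te <- apply_pca(g_pca, te)
      }
      w <- g_w
    } else {
      pp <- prep_fold(tr, te, standardize, pca, pca_var)
      tr <- pp$train
      te <- pp$test
      w <- resolve_weights(penalties, tr$label)
    }
    fit <- fit_model(tr, model, weights = w, seed = seed + i)
    pred <- predict_model(fit, te)
    fcm <- table(factor(te$label, levels = classes),
                 factor(pred, levels = classes))
    cm <- cm + as.matrix(fcm)
    fold_acc[i] <- sum(diag(fcm)) / sum(fcm)
  }
  new_evaluation_report(cm, fold_acc,
                        list(model = model, k = k,
                             penalties = !is.null(resolve_weights(
                               penalties, labels)),
                             standardize = standardize, pca = pca,
                             pca_var = pca_var, stratified = stratified,
                             global_prep = global_prep, seed = seed))
}

#' Cross-individual holdout validation
#'
#' Trains once on the full feature matrix of one individual's session and
#' evaluates on another individual's session; nothing from the test session
#' (not even standardization constants) enters the fit. A class missing
#' from the test session yields zero metrics for that class with a
#' warning, not an error.
#'
#' @param train_features,test_features `feature_matrix` objects with
#'   identical feature schemas.
#' @inheritParams crossval
#' @return An `evaluation_report`.
#' @export
holdout_validate <- function(train_features, test_features, model,
                             penalties = TRUE, standardize = TRUE,
                             pca = FALSE, pca_var = 0.95, seed = 1L) {
  stopifnot(inherits(train_features, "feature_matrix"),
            inherits(test_features, "feature_matrix"),
            inherits(model, "model_spec"))
  if (!identical(feature_cols(train_features),
                 feature_cols(test_features)))
    stop("train and test feature matrices have different schemas",
         call. = FALSE)
  classes <- sort(unique(train_features$label))
  missing <- setdiff(classes, unique(test_features$label))
  if (length(missing))
    warning("class ", paste(missing, collapse = ", "),
            " absent from the test session; its metrics are reported as 0",
            call. = FALSE)
  pp <- prep_fold(train_features, test_features, standardize, pca, pca_var)
  w <- resolve_weights(penalties, pp$train$label)
  fit <- fit_model(pp$train, model, weights = w, seed = seed)
  pred <- predict_model(fit, pp$test)
  cm <- as.matrix(table(factor(pp$test$label, levels = classes),
                        factor(pred, levels = classes)))
  dimnames(cm) <- list(true = classes, predicted = classes)
  new_evaluation_report(cm, numeric(0),
                        list(model = model, penalties = !is.null(w),
                             standardize = standardize, pca = pca,
                             pca_var = pca_var, seed = seed))
}

#' Two-tailed paired-samples t-test
#'
#' Paired t statistic on the elementwise differences, with the p-value from
#' the t distribution on `n - 1` degrees of freedom. Identical inputs (zero
#' differences throughout) return `p = 1` by convention; a constant nonzero
#' difference returns `p = 0`.
#'
#' @param a,b Equal-length numeric vectors (length >= 2) of paired metric
#'   values.
#' @return List with `t`, `p` and `df`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("insufficient pairs", call. = FALSE)
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1L))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L))
  }
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1L), df = n - 1L)
}

#' Run the window-length x PCA x model experiment grid
#'
#' Evaluates every combination of window length, PCA on/off and model
#' family by penalty-weighted cross-validation, repeating each cell with a
#' fresh partition seed, and compares matched cells (PCA vs none at the
#' same window length; long vs short window at the same PCA setting) with
#' two-tailed paired t-tests on accuracy and every F1 score.
#'
#' @param trace A `sensor_trace`.
#' @param track The matching `annotation_track`.
#' @param window_s Window lengths in seconds to compare.
#' @param pca Logical vector of PCA settings to compare.
#' @param families Model families (see [model_spec()]).
#' @param repeats Repeats per cell; at least 2 for t-tests.
#' @param shift_s Window shift in seconds.
#' @inheritParams crossval
#' @return An `experiment_grid`: list with `metrics` (one row per cell per
#'   repeat) and `tests` (paired comparisons; empty when `repeats < 2` or
#'   the grid has a single cell).
#' @export
run_experiment_grid <- function(trace, track, window_s = c(1, 4),
                                pca = c(FALSE, TRUE),
                                families = "bagged_trees",
                                repeats = 2L, shift_s = 0.5, k = 4L,
                                penalties = TRUE, pca_var = 0.95,
                                stratified = TRUE, seed = 1L) {
  stopifnot(repeats >= 1L)
  feats <- lapply(window_s, function(ws)
    build_feature_matrix(make_windows(trace, track,
                                      window_spec(ws, shift_s))))
  names(feats) <- as.character(window_s)

  cells <- expand.grid(window_s = window_s, pca = pca, family = families,
                       stringsAsFactors = FALSE)
  rows <- list()
  for (r in seq_len(repeats)) {
    rep_seed <- seed + 101L * r
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      rep_i <- crossval(feats[[as.character(cell$window_s)]],
                        model_spec(cell$family),
                        k = k, penalties = penalties,
                        standardize = TRUE, pca = cell$pca,
                        pca_var = pca_var, stratified = stratified,
                        seed = rep_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        window_s = cell$window_s, pca = cell$pca, family = cell$family,
        rep = r, accuracy = rep_i$accuracy,
        f1_class1 = rep_i$per_class$f1[1],
        f1_class2 = rep_i$per_class$f1[2],
        f1_class3 = rep_i$per_class$f1[3],
        overall_f1 = rep_i$overall_f1)
    }
  }
  metrics <- do.call(rbind, rows)

  tests <- list()
  metric_cols <- c("accuracy", "f1_class1", "f1_class2", "f1_class3",
                   "overall_f1")
  add_tests <- function(sub_a, sub_b, comparison, context) {
    sub_a <- sub_a[order(sub_a$rep), ]
    sub_b <- sub_b[order(sub_b$rep), ]
    for (mc in metric_cols) {
      tt <- paired_ttest(sub_a[[mc]], sub_b[[mc]])
      tests[[length(tests) + 1L]] <<- data.frame(
        comparison = comparison, context = context, metric = mc,
        mean_a = mean(sub_a[[mc]]), mean_b = mean(sub_b[[mc]]),
        t = tt$t, p = tt$p)
    }
  }
  if (repeats >= 2L) {
    for (fam in unique(cells$family)) {
      if (all(c(FALSE, TRUE) %in% pca))
        for (ws in window_s)
          add_tests(
            metrics[metrics$family == fam & metrics$window_s == ws &
                      metrics$pca, ],
            metrics[metrics$family == fam & metrics$window_s == ws &
                      !metrics$pca, ],
            "pca_vs_none", sprintf("%s, %g s window", fam, ws))
      if (length(window_s) == 2L)
        for (pc in pca)
          add_tests(
            metrics[metrics$family == fam & metrics$pca == pc &
                      metrics$window_s == max(window_s), ],
            metrics[metrics$family == fam & metrics$pca == pc &
                      metrics$window_s == min(window_s), ],
            "long_vs_short", sprintf("%s, pca = %s", fam, pc))
    }
  }
  structure(list(metrics = metrics,
                 tests = if (length(tests)) do.call(rbind, tests)
                         else data.frame(),
                 repeats = repeats, seed = seed),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, digits = 3, ...) {
  cat(sprintf("<experiment_grid> %d cells x %d repeats\n",
              nrow(unique(x$metrics[c("window_s", "pca", "family")])),
              x$repeats))
  m <- x$metrics
  m[vapply(m, is.numeric, TRUE)] <- round(m[vapply(m, is.numeric, TRUE)],
                                          digits)
  print(m)
  if (nrow(x$tests)) {
    cat("paired t-tests:\n")
    tt <- x$tests
    tt[c("mean_a", "mean_b", "t")] <- round(tt[c("mean_a", "mean_b", "t")],
                                            digits)
    tt$p <- signif(tt$p, 3)
    print(tt)
  }
  invisible(x)
}
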