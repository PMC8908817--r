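#' Fit and apply feature standardization
#'
#' Learns per-feature centre and scale from a training matrix and maps
#' features to zero mean and unit standard deviation (population
#' normalization, divide by n). Constant features (zero standard deviation)
#' are flagged and mapped to 0 rather than NaN. Fitting on training folds
#' only and applying to held-out folds keeps test information out of the
#' fitted parameters.
#'
#' @param train A `feature_matrix` used to learn the parameters.
#' @return `fit_standardizer()` returns a `standardizer` with fields
#'   `mean`, `sd` and `constant` (logical flags).
#' @export
fit_standardizer <- function(train) {
  stopifnot(is.data.frame(train), nrow(train) > 0L)
  cols <- feature_cols(train)
  x <- as.matrix(train[cols])
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2L, m)^2))
  structure(list(mean = m, sd = s, constant = s == 0),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params A fitted `standardizer`.
#' @param fm Any `feature_matrix` with the same feature columns.
#' @return `apply_standardizer()` returns the transformed
#'   `feature_matrix`.
#' @export
apply_standardizer <- function(params, fm) {
  stopifnot(inherits(params, "standardizer"), is.data.frame(fm))
  cols <- names(params$mean)
  if (!all(cols %in% names(fm)))
    stop("feature matrix lacks columns the standardizer was fitted on",
         call. = FALSE)
  x <- sweep(as.matrix(fm[cols]), 2L, params$mean)
  s <- ifelse(params$constant, 1, params$sd)
  x <- sweep(x, 2L, s, "/")
  x[, params$constant] <- 0
  out <- fm
  out[cols] <- as.data.frame(x)
  as_feature_matrix(out)
}

#' Find highly correlated feature pairs
#'
#' Flags every unordered pair of features whose Pearson correlation exceeds
#' `threshold` in absolute value. Constant features are excluded (their
#' correlation is undefined).
#'
#' @param fm A `feature_matrix` with at least 3 rows.
#' @param threshold Absolute correlation threshold (default 0.7).
#' @return Data frame with columns `feature_a`, `feature_b`, `r`, one row
#'   per flagged pair.
#' @export
find_correlated <- function(fm, threshold = 0.7) {
  stopifnot(is.data.frame(fm), nrow(fm) >= 3L)
  cols <- feature_cols(fm)
  x <- as.matrix(fm[cols])
  keep <- apply(x, 2L, function(v) stats::sd(v) > 0)
  x <- x[, keep, drop = FALSE]
  r <- stats::cor(x)
  hit <- which(abs(r) > threshold & upper.tri(r), arr.ind = TRUE)
  data.frame(feature_a = colnames(r)[hit[, 1]],
             feature_b = colnames(r)[hit[, 2]],
             r = r[hit],
             stringsAsFactors = FALSE)
}

#' Drop features until no flagged correlation pair remains
#'
#' Greedy removal: repeatedly drop the feature participating in the most
#' unresolved flagged pairs, breaking ties toward the later column index,
#' until no pair survives. Deterministic, so repeated runs remove the same
#' features.
#'
#' @param fm A `feature_matrix`.
#' @param pairs Flagged pairs from [find_correlated()].
#' @return The reduced `feature_matrix` with attribute `"dropped"` listing
#'   removed feature names in removal order.
#' @export
drop_correlated <- function(fm, pairs) {
  stopifnot(is.data.frame(fm), is.data.frame(pairs))
  dropped <- character(0)
  a <- pairs$feature_a
  b <- pairs$feature_b
  cols <- feature_cols(fm)
  while (length(a) > 0L) {
    deg <- table(factor(c(a, b), levels = cols))
    worst <- names(deg)[deg == max(deg)]
    victim <- worst[which.max(match(worst, cols))]
    dropped <- c(dropped, victim)
    keep <- a != victim & b != victim
    a <- a[keep]
    b <- b[keep]
  }
  out <- fm[setdiff(names(fm), dropped)]
  out <- as_feature_matrix(out)
  attr(out, "dropped") <- dropped
  out
}

#' Fit and apply PCA at a target explained variance
#'
#' Principal component analysis on (already standardized) features: the
#' retained dimension `k` is the smallest count of leading components whose
#' cumulative explained variance reaches `var_threshold` (default 95%).
#'
#' @param train A standardized `feature_matrix`.
#' @param var_threshold Target cumulative explained-variance fraction in
#'   (0, 1].
#' @return `fit_pca()` returns a `pca_model` with fields `center`,
#'   `rotation` (loadings of the retained components), `explained`
#'   (explained-variance fractions of all components) and `k`.
#' @export
fit_pca <- function(train, var_threshold = 0.95) {
  stopifnot(is.data.frame(train), nrow(train) >= 2L)
  if (!(is.numeric(var_threshold) && length(var_threshold) == 1L &&
        var_threshold > 0 && var_threshold <= 1))
    stop("var_threshold must be in (0, 1]", call. = FALSE)
  cols <- feature_cols(train)
  x <- as.matrix(train[cols])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  explained <- ev / sum(ev)
  k <- which(cumsum(explained) >= var_threshold - 1e-12)[1]
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = explained,
                 k = k),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param model A fitted `pca_model`.
#' @param fm Any `feature_matrix` with the same feature columns.
#' @return `apply_pca()` returns a `feature_matrix` whose feature columns
#'   are the `k` retained component scores (`PC1..PCk`).
#' @export
apply_pca <- function(model, fm) {
  stopifnot(inherits(model, "pca_model"), is.data.frame(fm))
  cols <- rownames(model$rotation)
  if (!all(cols %in% names(fm)))
    stop("feature matrix lacks columns the PCA was fitted on",
         call. = FALSE)
  scores <- sweep(as.matrix(fm[cols]), 2L, model$center) %*% model$rotation
  out <- data.frame(scores, check.names = FALSE)
  if ("label" %in% names(fm)) out$label <- fm$label
  as_feature_matrix(out)
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "<pca_model> %d of %d components retained (%.1f%% variance explained)\n",
    x$k, length(x$explained), 100 * sum(x$explained[seq_len(x$k)])))
  invisible(x)
}
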