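#' Names of the 31 window features
#'
#' For each axis (x, y, z), in order: skewness, kurtosis, mean, standard
#' deviation, variance, minimum, maximum, entropy, energy, covariance —
#' followed by the overall average signal magnitude. The `covariance`
#' feature of an axis is the population covariance of the *other two* axes
#' (so `covariance_x = cov(y, z)`), which is the reading of "covariance per
#' direction" that yields exactly 31 features together with the magnitude
#' term.
#'
#' @return Character vector of length 31; part of the stable public
#'   contract of [build_feature_matrix()].
#' @export
feature_names <- function() {
  base <- c("skewness", "kurtosis", "mean", "sd", "variance",
            "min", "max", "entropy", "energy", "covariance")
  c(paste(rep(base, 3), rep(c("x", "y", "z"), each = 10L), sep = "_"),
    "magnitude")
}

# Shannon entropy (bits) of the 16-bin histogram of v over [min(v), max(v)].
# Degenerate (constant) input has zero entropy by definition.
axis_entropy <- function(v, bins = 16L) {
  mn <- min(v)
  mx <- max(v)
  if (mx <= mn) return(0)
  br <- seq(mn, mx, length.out = bins + 1L)
  idx <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, nbins = bins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Compute the 31-feature vector of one window
#'
#' Per-axis statistics use population normalization (divide by `n`):
#' variance is the population variance, skewness the third and kurtosis the
#' fourth standardized central moment (kurtosis is non-excess, 3 for a
#' normal population; both are defined as 0 for a zero-variance axis).
#' Energy is the mean squared sample value (time domain); entropy is the
#' Shannon entropy (base 2) of the axis's 16-bin amplitude histogram over
#' its own range within the window (0 if the axis is constant). The
#' magnitude feature is the mean over samples of `sqrt(x^2 + y^2 + z^2)`.
#'
#' @param samples An `n x 3` numeric matrix (n >= 2) of accelerations,
#'   columns x, y, z — e.g. from [get_window()].
#' @param entropy_bins Histogram bin count for the entropy features.
#' @return Named numeric vector of length 31, in [feature_names()] order.
#' @examples
#' w <- cbind(x = sin(1:100), y = cos(1:100), z = rnorm(100))
#' extract_features(w)[c("mean_x", "variance_x", "magnitude")]
#' @export
extract_features <- function(samples, entropy_bins = 16L) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 2L) stop("a window needs at least 2 samples", call. = FALSE)
  stopifnot(ncol(samples) == 3L, all(is.finite(samples)))

  out <- numeric(31L)
  centered <- vector("list", 3L)
  for (ax in 1:3) {
    v <- samples[, ax]
    m <- mean(v)
    cv <- v - m
    varp <- mean(cv^2)
    sdp <- sqrt(varp)
    skew <- if (sdp > 0) mean(cv^3) / sdp^3 else 0
    kurt <- if (sdp > 0) mean(cv^4) / varp^2 else 0
    centered[[ax]] <- cv
    out[(ax - 1L) * 10L + 1:9] <-
      c(skew, kurt, m, sdp, varp, min(v), max(v),
        axis_entropy(v, entropy_bins), mean(v^2))
  }
  # covariance_x = cov(y, z), etc.: the population covariance of the two
  # axes orthogonal to the named one
  out[10L] <- mean(centered[[2]] * centered[[3]])
  out[20L] <- mean(centered[[1]] * centered[[3]])
  out[30L] <- mean(centered[[1]] * centered[[2]])
  out[31L] <- mean(sqrt(rowSums(samples^2)))
  names(out) <- feature_names()
  out
}

#' Assemble the feature matrix of a window set
#'
#' Applies [extract_features()] to every window, preserving window order,
#' and attaches each window's class label.
#'
#' @param windows A non-empty `labeled_windows` object from
#'   [make_windows()].
#' @param entropy_bins Histogram bin count for the entropy features.
#' @return A `feature_matrix`: data frame with the 31 feature columns of
#'   [feature_names()] plus an integer `label` column.
#' @export
build_feature_matrix <- function(windows, entropy_bins = 16L) {
  stopifnot(inherits(windows, "labeled_windows"))
  n_win <- length(windows$label)
  if (n_win == 0L) stop("no windows to featurize", call. = FALSE)
  feats <- matrix(NA_real_, n_win, 31L,
                  dimnames = list(NULL, feature_names()))
  for (w in seq_len(n_win))
    feats[w, ] <- extract_features(get_window(windows, w), entropy_bins)
  fm <- data.frame(feats, check.names = FALSE)
  fm$label <- as.integer(windows$label)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

# Feature columns of a feature matrix (everything except the label).
feature_cols <- function(fm) setdiff(names(fm), "label")

as_feature_matrix <- function(d) {
  stopifnot(is.data.frame(d))
  class(d) <- unique(c("feature_matrix", class(d)))
  d
}

#' Write or read a feature matrix as delimited text
#'
#' @param fm A `feature_matrix`.
#' @param path File path; the header carries the feature names plus
#'   `label`.
#' @return `read_feature_matrix()` returns a `feature_matrix`;
#'   `write_feature_matrix()` returns `path` invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  data.table::fwrite(as.data.frame(fm), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  if (!"label" %in% names(d))
    stop("feature file missing 'label' column", call. = FALSE)
  as_feature_matrix(d)
}
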