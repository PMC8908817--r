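#' Inverse-class-frequency misclassification penalties
#'
#' The cost of misclassifying a sample whose true class is `i` is
#' `penalty_i = n_total / n_class_i`: the rarer the class, the larger the
#' penalty, which counteracts severe class imbalance (in the reference
#' recording the highly dynamic class holds 37 of 6666 windows). The
#' penalties are exposed both as a K x K cost matrix — rows are true
#' classes, columns predicted classes, diagonal 0, every off-diagonal entry
#' of row `i` equal to `penalty_i` — and as the per-class weight vector
#' that weight-based trainers accept. For balanced classes the penalty
#' equals the number of classes K.
#'
#' @param class_counts Positive per-class counts, e.g.
#'   `table(fm$label)`. Names (class labels) are preserved.
#' @return A `penalty_matrix` object: list with `cost` (K x K matrix),
#'   `weights` (per-class penalty vector), `class_counts` and `n_total`.
#' @examples
#' compute_penalties(c(`1` = 3023, `2` = 3606, `3` = 37))$weights
#' @export
compute_penalties <- function(class_counts) {
  counts <- as.numeric(class_counts)
  if (length(counts) < 1L || any(!is.finite(counts)))
    stop("class_counts must be finite", call. = FALSE)
  if (any(counts <= 0))
    stop("class absent from training data", call. = FALSE)
  labels <- names(class_counts)
  if (is.null(labels)) labels <- as.character(seq_along(counts))
  n_total <- sum(counts)
  w <- n_total / counts
  k <- length(counts)
  cost <- matrix(rep(w, each = k), k, k, byrow = TRUE,
                 dimnames = list(true = labels, predicted = labels))
  diag(cost) <- 0
  structure(list(cost = cost,
                 weights = stats::setNames(w, labels),
                 class_counts = stats::setNames(counts, labels),
                 n_total = n_total),
            class = "penalty_matrix")
}

#' @export
print.penalty_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<penalty_matrix> %d classes, %g samples\n",
              length(x$weights), x$n_total))
  cat("per-class penalty (n_total / n_class):\n")
  print(round(x$weights, digits))
  cat("cost matrix (rows = true, cols = predicted):\n")
  print(round(x$cost, digits))
  invisible(x)
}
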