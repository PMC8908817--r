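#' Window specification
#'
#' Windows of `window_s` seconds are advanced by `shift_s` seconds, giving an
#' overlap fraction of `1 - shift_s / window_s` between consecutive windows
#' (50% for 1-s and 87.5% for 4-s windows at the default 0.5-s shift).
#' `window_s` must be a positive integer multiple of `shift_s`.
#'
#' @param window_s Window length in seconds (1 or 4 in the reference
#'   protocol).
#' @param shift_s Window shift in seconds (default 0.5, one annotation slot).
#' @return A `window_spec` object.
#' @export
window_spec <- function(window_s, shift_s = 0.5) {
  stopifnot(is.numeric(window_s), length(window_s) == 1L, window_s > 0,
            is.numeric(shift_s), length(shift_s) == 1L, shift_s > 0)
  ratio <- window_s / shift_s
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("window_s must be an integer multiple of shift_s", call. = FALSE)
  structure(list(window_s = window_s, shift_s = shift_s),
            class = "window_spec")
}

#' Majority label of a set of annotation slots
#'
#' Returns the most frequent label; exact ties are broken toward the highest
#' class index among the tied labels. Class 3 (highly dynamic) is both the
#' rarest and the shortest-lived, so breaking ties upward keeps its few
#' windows from being absorbed by the dominant classes.
#'
#' @param slot_labels Non-empty vector of labels in \{1, 2, 3\}.
#' @return A single label.
#' @examples
#' majority_label(c(1, 1, 2, 2))  # tie -> 2
#' @export
majority_label <- function(slot_labels) {
  if (length(slot_labels) == 0L)
    stop("cannot take the majority of zero slots", call. = FALSE)
  stopifnot(all(slot_labels %in% 1:3))
  counts <- tabulate(slot_labels, nbins = 3L)
  max(which(counts == max(counts)))
}

#' Cut a synchronized session into labelled windows
#'
#' Window start times form the grid `t0, t0 + shift_s, ...` anchored at the
#' first instant covered by both the trace and the annotation track. A
#' window is emitted only when it is fully covered by both; its label is the
#' majority label over the 0.5-s slots it spans ([majority_label()]).
#'
#' @param trace A `sensor_trace`.
#' @param track An `annotation_track` on the same clock (see
#'   [apply_sync()]).
#' @param spec A `window_spec`. `window_s * fs` must be a whole number of
#'   samples.
#' @return A `labeled_windows` object: list with `start_s`, `label`
#'   (integer vector), `samples` (array `n_samples x 3 x n_windows`), `fs`
#'   and `spec`. Zero windows (duration shorter than `window_s`) gives
#'   empty vectors, not an error.
#' @export
make_windows <- function(trace, track, spec) {
  stopifnot(inherits(trace, "sensor_trace"),
            inherits(track, "annotation_track"),
            inherits(spec, "window_spec"))
  eps <- 1e-9
  fs <- attr(trace, "fs")
  nspw <- spec$window_s * fs
  if (abs(nspw - round(nspw)) > 1e-9)
    stop("window_s * fs must be an integer sample count", call. = FALSE)
  nspw <- round(nspw)
  if (abs(spec$window_s / 0.5 - round(spec$window_s / 0.5)) > 1e-9)
    stop("window_s must span a whole number of 0.5-s annotation slots",
         call. = FALSE)

  trace_span <- c(trace$t[1], trace$t[nrow(trace)] + 1 / fs)
  track_span <- c(track$slot_start[1],
                  track$slot_start[nrow(track)] + 0.5)
  # anchor the window grid at the first slot boundary covered by the trace,
  # so every window spans whole annotation slots
  first_slot <- which(track$slot_start >= trace_span[1] - eps)[1]
  if (is.na(first_slot)) first_slot <- nrow(track) + 1L
  t0 <- if (first_slot <= nrow(track)) track$slot_start[first_slot] else Inf
  t_end <- min(trace_span[2], track_span[2])

  n_win <- floor((t_end - t0 - spec$window_s) / spec$shift_s + eps) + 1
  if (n_win < 1) {
    return(structure(list(start_s = numeric(0), label = integer(0),
                          samples = array(0, c(nspw, 3L, 0L)),
                          fs = fs, spec = spec),
                     class = "labeled_windows"))
  }
  starts <- t0 + (seq_len(n_win) - 1) * spec$shift_s

  acc <- as.matrix(trace[c("acc_x", "acc_y", "acc_z")])
  samples <- array(NA_real_, c(nspw, 3L, n_win))
  labels <- integer(n_win)
  slots_per_win <- round(spec$window_s / 0.5)
  for (w in seq_len(n_win)) {
    i1 <- round((starts[w] - trace$t[1]) * fs) + 1L
    samples[, , w] <- acc[i1:(i1 + nspw - 1L), ]
    s1 <- round((starts[w] - track$slot_start[1]) / 0.5) + 1L
    labels[w] <- majority_label(track$label[s1:(s1 + slots_per_win - 1L)])
  }
  structure(list(start_s = starts, label = labels, samples = samples,
                 fs = fs, spec = spec),
            class = "labeled_windows")
}

#' Extract one window's samples
#'
#' @param windows A `labeled_windows` object.
#' @param i Window index.
#' @return An `n_samples x 3` matrix of accelerations (columns x, y, z).
#' @export
get_window <- function(windows, i) {
  stopifnot(inherits(windows, "labeled_windows"),
            i >= 1, i <= length(windows$label))
  m <- windows$samples[, , i, drop = TRUE]
  dim(m) <- c(dim(windows$samples)[1], 3L)
  colnames(m) <- c("x", "y", "z")
  m
}

#' @export
print.labeled_windows <- function(x, ...) {
  tab <- table(factor(x$label, levels = 1:3))
  cat(sprintf(
    "<labeled_windows> %d windows of %g s (shift %g s, %d samples each); labels 1/2/3: %s\n",
    length(x$label), x$spec$window_s, x$spec$shift_s,
    dim(x$samples)[1], paste(tab, collapse = "/")))
  invisible(x)
}

#' @export
length.labeled_windows <- function(x) length(x$label)
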