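#' Write and read sensor traces
#'
#' Sensor traces are stored as delimited text with header
#' `t,acc_x,acc_y,acc_z` (seconds, m/s^2). Extra columns (e.g. gyroscope or
#' magnetometer channels) are tolerated on read and ignored by the feature
#' layer. [read_sensor()] infers the sampling frequency from the median
#' sample spacing and validates that the spacing is constant to within 1% of
#' the sampling interval.
#'
#' @param trace A `sensor_trace`.
#' @param path File path.
#' @return `read_sensor()` returns a `sensor_trace`; `write_sensor()`
#'   returns `path` invisibly.
#' @export
write_sensor <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  data.table::fwrite(as.data.frame(trace), path)
  invisible(path)
}

#' @rdname write_sensor
#' @export
read_sensor <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- data.table::fread(path, data.table = FALSE)
  need <- c("t", "acc_x", "acc_y", "acc_z")
  if (!all(need %in% names(d)))
    stop("sensor file missing required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  if (nrow(d) == 0L) stop("empty trace", call. = FALSE)
  d <- d[need]
  if (anyNA(d) || !all(is.finite(as.matrix(d))))
    stop("sensor file contains missing or non-finite samples",
         call. = FALSE)
  if (nrow(d) < 2L) stop("empty trace", call. = FALSE)
  dt <- diff(d$t)
  med <- stats::median(dt)
  if (med <= 0) stop("sample times must be strictly increasing",
                     call. = FALSE)
  fs <- round(1 / med)
  if (any(abs(dt - 1 / fs) > 0.01 / fs))
    stop("irregular sampling: spacing deviates by more than 1% of 1/fs",
         call. = FALSE)
  new_sensor_trace(d$t, as.matrix(d[c("acc_x", "acc_y", "acc_z")]), fs)
}

#' Write and read annotation tracks
#'
#' Annotation tracks are stored as delimited text with header
#' `slot_start,label`: one row per 0.5-s slot, label in \{1, 2, 3\}.
#'
#' @param track An `annotation_track`.
#' @param path File path.
#' @return `read_annotations()` returns an `annotation_track`;
#'   `write_annotations()` returns `path` invisibly.
#' @export
write_annotations <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  data.table::fwrite(as.data.frame(track), path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- data.table::fread(path, data.table = FALSE)
  need <- c("slot_start", "label")
  if (!all(need %in% names(d)))
    stop("annotation file missing required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  if (nrow(d) == 0L) stop("empty annotation track", call. = FALSE)
  if (!all(d$label %in% 1:3))
    stop("annotation labels must be in {1, 2, 3}", call. = FALSE)
  if (nrow(d) > 1L && any(abs(diff(d$slot_start) - 0.5) > 1e-6))
    stop("annotation slots must be contiguous 0.5-s intervals",
         call. = FALSE)
  new_annotation_track(d$slot_start, d$label)
}

#' Align the annotation clock with the sensor clock
#'
#' The behavioural annotations are made against a video clock; `offset_s` is
#' the number of seconds to add to annotation times to land them on the
#' sensor clock (it may be negative). After shifting, the track is clipped to
#' the span of the sensor trace; slots only partially covered by the trace
#' are dropped, since a label must describe a full 0.5 s of signal.
#'
#' @param track An `annotation_track`.
#' @param offset_s Finite clock offset in seconds.
#' @param trace The `sensor_trace` defining the target clock and span.
#' @return The shifted, clipped `annotation_track`.
#' @export
apply_sync <- function(track, offset_s, trace) {
  stopifnot(inherits(track, "annotation_track"),
            inherits(trace, "sensor_trace"),
            is.numeric(offset_s), length(offset_s) == 1L,
            is.finite(offset_s))
  eps <- 1e-9
  fs <- attr(trace, "fs")
  span <- c(trace$t[1], trace$t[nrow(trace)] + 1 / fs)
  start <- track$slot_start + offset_s
  keep <- start >= span[1] - eps & start + 0.5 <= span[2] + eps
  if (!any(keep))
    stop("no overlap between annotation track and sensor trace",
         call. = FALSE)
  new_annotation_track(start[keep], track$label[keep])
}

#' Read a session manifest
#'
#' A manifest is a flat `key = value` text file naming the files of one
#' recording session and its clock offset. Recognised keys: `sensor`,
#' `annotations`, `offset_s`. Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path Manifest file path.
#' @return A list with elements `sensor`, `annotations` and `offset_s`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop("manifest lines must be 'key = value'", call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  m <- as.list(stats::setNames(vals, keys))
  for (k in c("sensor", "annotations"))
    if (!is.null(m[[k]]) && !grepl("^(/|[A-Za-z]:)", m[[k]]))
      m[[k]] <- file.path(dirname(path), m[[k]])
  m$offset_s <- if (is.null(m$offset_s)) 0 else as.numeric(m$offset_s)
  m[c("sensor", "annotations", "offset_s")]
}
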