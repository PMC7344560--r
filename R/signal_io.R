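#' Read a knee accelerometer recording from delimited text
#'
#' Accepts comma- or tab-delimited files (delimiter sniffed from the first
#' data line) with either three numeric columns (ax, ay, az) or four
#' (timestamp, ax, ay, az). A timestamp column, when present, is validated
#' against `fs` (median sampling interval within 1%) and then discarded: the
#' pipeline is index-based. Sample order is preserved exactly; no row is
#' dropped or reordered.
#'
#' @param path path to the file.
#' @param subject_id,knee,state,course_id metadata attached to the recording
#'   (see [gait_recording()]).
#' @param fs sampling frequency in Hz (default 32).
#' @param range_action `"error"` (strict +/- 8 g validation, default) or
#'   `"clip"`.
#' @param header whether the file carries a header row (auto-detected when
#'   `NA`, the default: a first line with any non-numeric field is treated as
#'   a header).
#' @return a [gait_recording()].
#' @export
read_recording <- function(path, subject_id, knee, state = "unknown",
                           fs = 32, course_id = NULL,
                           range_action = c("error", "clip"), header = NA) {
  range_action <- match.arg(range_action)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty recording file: ", path)
  delim <- if (grepl("\t", lines[[1L]])) "\t" else ","
  first <- strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]]
  if (is.na(header))
    header <- anyNA(suppressWarnings(as.numeric(first)))
  start <- if (header) 2L else 1L
  if (start > length(lines)) stop("no data rows in ", path)
  rows <- strsplit(lines[start:length(lines)], delim, fixed = TRUE)
  ncol <- length(rows[[1L]])
  if (!ncol %in% c(3L, 4L))
    stop("expected 3 or 4 columns in ", path, "; got ", ncol)
  mat <- matrix(NA_real_, nrow = length(rows), ncol = ncol)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != ncol)
      stop("malformed row at line ", start + i - 1L, " of ", path,
           ": expected ", ncol, " fields, got ", length(f))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop("malformed row at line ", start + i - 1L, " of ", path,
           ": non-numeric field '", f[which(is.na(v))[1L]], "'")
    mat[i, ] <- v
  }
  if (ncol == 4L) {
    ts <- mat[, 1L]
    if (nrow(mat) > 1L) {
      dt <- stats::median(diff(ts))
      if (!is.finite(dt) || dt <= 0 || abs(dt * fs - 1) > 0.01)
        stop("timestamp column of ", path, " implies a sampling interval of ",
             format(dt), " s, inconsistent with fs = ", fs, " Hz (> 1% off)")
    }
    mat <- mat[, 2:4, drop = FALSE]
  }
  gait_recording(mat, subject_id = subject_id, knee = knee, state = state,
                 fs = fs, course_id = course_id, range_action = range_action)
}

#' Write a recording to delimited text
#'
#' Inverse of [read_recording()]: writes one row per sample with a
#' `ax,ay,az` header, full double precision (round-trips bitwise through
#' [read_recording()]).
#'
#' @param rec a [gait_recording()].
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "gait_recording"))
  utils::write.table(
    format_full_precision(as.data.frame(rec$samples)), path, sep = sep,
    row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

# 17 significant digits: doubles survive the text round trip bitwise
format_full_precision <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Write a feature table to delimited text
#'
#' The on-disk layout is one row per window with the metadata columns
#' (`subject_id`, `course_id`, `window_index`, `label`, per-knee gait quality
#' flags) followed by the 32 named feature columns. Values are written at
#' full double precision so that [read_feature_table()] round-trips
#' losslessly.
#'
#' @param table a feature table as produced by [featurize_cohort()].
#' @param path output path.
#' @param sep field separator (default tab: feature names contain commas-free
#'   spaces and parentheses).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, sep = "\t") {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("feature table is empty; refusing to write an empty file")
  utils::write.table(format_full_precision(table), path, sep = sep,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path path to the file.
#' @param sep field separator (default tab).
#' @return a data.frame with the same columns (feature names preserved
#'   verbatim, including spaces and parentheses).
#' @export
read_feature_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  tab
}

#' Read a cohort layout declared in a YAML config
#'
#' The config maps files to metadata, one entry per recording:
#' ```yaml
#' fs: 32
#' recordings:
#'   - path: subj01_on_left.csv
#'     subject_id: subj01
#'     knee: left
#'     state: on
#' ```
#' Paths are resolved relative to the config file's directory.
#'
#' @param config_path path to the YAML file.
#' @param range_action passed through to [read_recording()].
#' @return a [gait_cohort()].
#' @export
read_cohort_config <- function(config_path, range_action = "error") {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$recordings) || !length(cfg$recordings))
    stop("cohort config lists no recordings")
  fs <- if (is.null(cfg$fs)) 32 else cfg$fs
  base <- dirname(normalizePath(config_path))
  recs <- lapply(cfg$recordings, function(e) {
    p <- e$path
    if (!file.exists(p)) p <- file.path(base, e$path)
    read_recording(p, subject_id = e$subject_id, knee = e$knee,
                   state = e$state, fs = fs, course_id = e$course_id,
                   range_action = range_action)
  })
  gait_cohort(recs)
}
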