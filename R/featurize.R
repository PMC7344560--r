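stat_feature_labels <- c(
  mean = "Mean", std = "Standard Deviation",
  mad = "Median Absolute Deviation", minimum = "Minimum",
  maximum = "Maximum", energy = "Energy Measure",
  iqr = "Inter Quartile Range", sma = "Signal Magnitude Area",
  skewness = "Skewness", kurtosis = "Kurtosis")

gait_feature_labels <- c(
  step_length = "Step Length", stride_length = "Stride Length",
  step_time = "Step Time", stride_time = "Stride Time",
  step_velocity = "Step Velocity", stride_velocity = "Stride Velocity")

#' Canonical names of the 32 window features
#'
#' Sixteen features per knee (ten statistical, six spatiotemporal gait
#' parameters), left knee block first, named exactly as they appear in
#' feature tables and packaged feature-selection masks, e.g.
#' `"Mean (Left Knee)"` ... `"Stride Velocity (Right Knee)"`.
#'
#' @return character vector of length 32.
#' @export
feature_names <- function() {
  per_knee <- c(stat_feature_labels, gait_feature_labels)
  c(paste0(per_knee, " (Left Knee)"), paste0(per_knee, " (Right Knee)"))
}

#' Extract the 32 features of one window
#'
#' For each knee: the ten statistical features on the magnitude series (SMA
#' on the three axes) and the six gait parameters from strike detection on
#' the magnitude plus inverted-pendulum integration of the vertical axis.
#'
#' @param w a `window_segment` from [segment_windows()].
#' @param fs sampling frequency in Hz.
#' @param leg_length pendulum length in metres (default 0.9).
#' @param vertical_axis column index of the vertical axis in the sample
#'   block (default 3; declared per sensor mounting, not estimated).
#' @param gait_control optional list overriding [detect_strikes()] thresholds
#'   (`period_band`, `prominence_sd`, `refractory_frac`, `min_autocorr`).
#' @return named numeric vector of the 32 features, with attributes
#'   `flag_left`/`flag_right` marking event-poor gait windows.
#' @export
window_features <- function(w, fs, leg_length = 0.9, vertical_axis = 3L,
                            gait_control = list()) {
  one_knee <- function(block) {
    st <- stat_features(block)
    mag <- magnitude(block)
    ev <- do.call(detect_strikes, c(list(x = mag, fs = fs), gait_control))
    gf <- gait_features(ev, block[, vertical_axis], fs,
                        leg_length = leg_length)
    list(values = c(st, gf), flagged = isTRUE(attr(gf, "flagged")))
  }
  left <- one_knee(w$left)
  right <- one_knee(w$right)
  out <- c(left$values, right$values)
  names(out) <- feature_names()
  attr(out, "flag_left") <- left$flagged
  attr(out, "flag_right") <- right$flagged
  out
}

#' Filter, window, and featurize a whole cohort
#'
#' The full feature-engineering front end: each course's left/right pair is
#' low-pass filtered, segmented into folds, and reduced to one 32-feature row
#' per window. The row count therefore equals the summed per-course window
#' counts (`round-half-up(N/fold)` each).
#'
#' @param cohort a [gait_cohort()]; each subject must have matched left/right
#'   recordings per course.
#' @param spec a [filter_spec()] (defaults to the 4th-order 15 Hz Butterworth
#'   at the cohort's sampling rate, zero-phase).
#' @param fold fold length in samples (default 320).
#' @param leg_length pendulum length in metres, either a scalar or a named
#'   vector keyed by subject_id (default 0.9).
#' @param vertical_axis vertical axis column index (default 3).
#' @param gait_control optional [detect_strikes()] threshold overrides.
#' @param verbose log per-course window counts (default FALSE).
#' @return a data.frame: columns `subject_id`, `course_id`, `window_index`,
#'   `label`, `flag_left`, `flag_right`, then the 32 features (names as
#'   [feature_names()], preserved verbatim). Zero-row data.frame (with a
#'   warning) for a cohort whose courses are all empty.
#' @export
featurize_cohort <- function(cohort, spec = NULL, fold = 320L,
                             leg_length = 0.9, vertical_axis = 3L,
                             gait_control = list(), verbose = FALSE) {
  stopifnot(inherits(cohort, "gait_cohort"))
  keys <- vapply(cohort$recordings, function(r)
    paste(r$subject_id, r$course_id, sep = "\r"), character(1))
  rows <- list()
  for (key in unique(keys)) {
    recs <- cohort$recordings[keys == key]
    knees <- vapply(recs, `[[`, character(1), "knee")
    if (!setequal(knees, c("left", "right")) || length(recs) != 2L)
      stop("course ", recs[[1L]]$course_id, " of subject ",
           recs[[1L]]$subject_id,
           " does not have exactly one left and one right recording")
    left <- recs[[which(knees == "left")]]
    right <- recs[[which(knees == "right")]]
    sp <- if (is.null(spec)) filter_spec(fs_hz = left$fs) else spec
    wins <- segment_windows(lowpass_filter(left, sp),
                            lowpass_filter(right, sp), fold = fold)
    if (verbose)
      message(left$subject_id, " ", left$course_id, ": ", length(wins),
              " window(s)")
    ll <- if (length(leg_length) > 1L) {
      if (is.null(names(leg_length)) || !left$subject_id %in% names(leg_length))
        stop("per-subject leg_length vector lacks entry for ",
             left$subject_id)
      leg_length[[left$subject_id]]
    } else leg_length
    for (w in wins) {
      fv <- window_features(w, fs = left$fs, leg_length = ll,
                            vertical_axis = vertical_axis,
                            gait_control = gait_control)
      meta <- data.frame(subject_id = w$subject_id, course_id = w$course_id,
                         window_index = w$window_index, label = w$label,
                         flag_left = attr(fv, "flag_left"),
                         flag_right = attr(fv, "flag_right"),
                         stringsAsFactors = FALSE)
      feat <- as.data.frame(as.list(fv), check.names = FALSE)
      rows[[length(rows) + 1L]] <- cbind(meta, feat)
    }
  }
  if (!length(rows)) {
    warning("cohort produced no windows (all courses shorter than fold/2)")
    empty <- data.frame(subject_id = character(0), course_id = character(0),
                        window_index = integer(0), label = character(0),
                        flag_left = logical(0), flag_right = logical(0),
                        stringsAsFactors = FALSE)
    for (nm in feature_names()) empty[[nm]] <- numeric(0)
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
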