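#' Construct a knee accelerometer recording
#'
#' A `gait_recording` holds one knee's tri-axial acceleration trace together
#' with its acquisition metadata. Acceleration is expressed in g; the sensor
#' model assumed throughout the package saturates at +/- 8 g, and values
#' outside that range are either rejected (`range_action = "error"`) or
#' clipped with a warning (`range_action = "clip"`) -- never passed through
#' silently.
#'
#' @param samples numeric matrix with 3 columns (ax, ay, az) in g, one row per
#'   sample, in acquisition order.
#' @param subject_id character scalar identifying the subject.
#' @param knee `"left"` or `"right"`.
#' @param state medication state of the course: `"on"`, `"off"` or
#'   `"unknown"`.
#' @param fs sampling frequency in Hz (default 32).
#' @param course_id character scalar identifying the walking course; defaults
#'   to `"<subject>_<state>"`.
#' @param range_action what to do with samples outside +/- 8 g: `"error"`
#'   (strict, default) or `"clip"`.
#' @return an object of class `gait_recording`: a list with elements
#'   `samples` (n x 3 matrix), `subject_id`, `knee`, `state`, `fs`,
#'   `course_id`.
#' @export
gait_recording <- function(samples, subject_id, knee, state = "unknown",
                           fs = 32, course_id = NULL,
                           range_action = c("error", "clip")) {
  range_action <- match.arg(range_action)
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    stop("samples must have exactly 3 columns (ax, ay, az); got ",
         ncol(samples))
  if (nrow(samples) == 0L)
    stop("recording has no samples")
  if (!is.numeric(samples) || anyNA(samples))
    stop("samples must be numeric and free of missing values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  knee <- match.arg(knee, c("left", "right"))
  state <- match.arg(state, c("on", "off", "unknown"))
  out_of_range <- abs(samples) > 8
  if (any(out_of_range)) {
    if (range_action == "error") {
      bad <- which(rowSums(out_of_range) > 0)[1L]
      stop("acceleration outside the +/- 8 g sensor range at sample ", bad,
           " (", format(samples[bad, ][which(out_of_range[bad, ])[1L]]),
           " g); use range_action = \"clip\" to saturate instead")
    }
    warning(sum(out_of_range), " sample value(s) outside +/- 8 g clipped")
    samples[samples > 8] <- 8
    samples[samples < -8] <- -8
  }
  if (is.null(course_id)) course_id <- paste(subject_id, state, sep = "_")
  colnames(samples) <- c("ax", "ay", "az")
  structure(
    list(samples = samples, subject_id = as.character(subject_id),
         knee = knee, state = state, fs = fs,
         course_id = as.character(course_id)),
    class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf(
    "<gait_recording> subject %s, %s knee, state %s: %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$knee, x$state, nrow(x$samples), x$fs,
    nrow(x$samples) / x$fs))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a `gait_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' Assemble recordings into a cohort
#'
#' A cohort is the unit the modelling functions consume: a list of
#' `gait_recording` objects plus the roster of subject ids they cover. A
#' *complete* study-shaped cohort has four recordings per subject
#' (left/right knee x on/off course); `validate_cohort()` checks this shape.
#'
#' @param recordings list of `gait_recording` objects.
#' @return an object of class `gait_cohort` with elements `recordings` and
#'   `roster` (sorted unique subject ids).
#' @export
gait_cohort <- function(recordings) {
  if (!length(recordings)) stop("cohort needs at least one recording")
  ok <- vapply(recordings, inherits, logical(1), "gait_recording")
  if (!all(ok)) stop("all elements must be gait_recording objects")
  roster <- sort(unique(vapply(recordings, `[[`, character(1), "subject_id")))
  structure(list(recordings = recordings, roster = roster),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d recordings from %d subject(s)\n",
              length(x$recordings), length(x$roster)))
  invisible(x)
}

#' Check that a cohort has the complete study shape
#'
#' @param cohort a `gait_cohort`.
#' @return invisibly `TRUE`; errors describing the first violation otherwise.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "gait_cohort"))
  for (sid in cohort$roster) {
    recs <- Filter(function(r) r$subject_id == sid, cohort$recordings)
    combos <- sort(vapply(recs, function(r) paste(r$knee, r$state),
                          character(1)))
    expected <- sort(c("left on", "left off", "right on", "right off"))
    if (!identical(combos, expected))
      stop("subject ", sid, " does not have the 4 expected recordings ",
           "(left/right x on/off); found: ", paste(combos, collapse = ", "))
  }
  invisible(TRUE)
}
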