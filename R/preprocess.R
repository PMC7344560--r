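#' Butterworth low-pass filter specification
#'
#' Defaults follow the acquisition protocol the package models: a
#' fourth-order low-pass Butterworth at 15 Hz cutoff on 32 Hz data. Note that
#' 15 Hz sits at 0.94 x Nyquist for fs = 32, so the default filter removes
#' only a thin band just below Nyquist; the protocol defaults are kept as is
#' and an advisory message is emitted when cutoff/Nyquist > 0.9.
#'
#' @param order filter order (>= 1), default 4.
#' @param cutoff_hz -3 dB cutoff frequency in Hz, default 15; must lie
#'   strictly below fs/2.
#' @param fs_hz sampling frequency in Hz, default 32.
#' @param mode `"zero_phase"` (forward-backward filtering: no phase lag,
#'   squared magnitude response; the default, appropriate for offline feature
#'   extraction) or `"causal"` (single forward pass).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 15, fs_hz = 32,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (order < 1) stop("filter order must be >= 1")
  if (cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2)
    stop("cutoff_hz must lie in (0, fs/2); got ", cutoff_hz,
         " with Nyquist ", fs_hz / 2)
  if (cutoff_hz > 0.9 * fs_hz / 2)
    message("note: cutoff ", cutoff_hz, " Hz is at ",
            sprintf("%.2f", cutoff_hz / (fs_hz / 2)),
            " x Nyquist; the filter removes only a thin high band")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 fs_hz = fs_hz, mode = mode), class = "filter_spec")
}

butter_coefs <- function(spec) {
  signal::butter(spec$order, spec$cutoff_hz / (spec$fs_hz / 2), type = "low")
}

filter_series <- function(x, spec) {
  ba <- butter_coefs(spec)
  if (spec$mode == "zero_phase") {
    as.numeric(signal::filtfilt(ba, x))
  } else {
    as.numeric(signal::filter(ba, x))
  }
}

#' Low-pass filter a recording
#'
#' Applies the Butterworth filter of `spec` independently to each of the
#' three axes. Output length equals input length. In `zero_phase` mode the
#' filter is run forward and backward, giving zero phase lag and the squared
#' magnitude response -- the right choice when gait-event timing is extracted
#' downstream.
#'
#' @param rec a [gait_recording()].
#' @param spec a [filter_spec()]; its `fs_hz` must match the recording.
#' @return a filtered [gait_recording()] with identical metadata. Filtered
#'   output is not re-validated against the +/- 8 g range (a linear filter
#'   cannot exceed the range of an in-range signal by more than ringing).
#' @export
lowpass_filter <- function(rec, spec = filter_spec(fs_hz = rec$fs)) {
  stopifnot(inherits(rec, "gait_recording"), inherits(spec, "filter_spec"))
  if (!isTRUE(all.equal(spec$fs_hz, rec$fs)))
    stop("filter_spec fs_hz (", spec$fs_hz, ") does not match recording fs (",
         rec$fs, ")")
  n <- nrow(rec$samples)
  if (n <= 3 * spec$order)
    stop("recording too short to filter: ", n, " samples <= 3 x order (",
         3 * spec$order, ")")
  out <- rec
  out$samples <- apply(rec$samples, 2L, filter_series, spec = spec)
  colnames(out$samples) <- c("ax", "ay", "az")
  out
}

#' Window count implied by the fold rule
#'
#' A course of `n` samples yields `floor(n/fold)` full folds plus one final
#' partial fold retained iff its length is at least `fold/2` -- i.e. the
#' count is `n/fold` rounded half up. With the default 320-sample fold this
#' reproduces the per-course window bookkeeping of the study design the
#' package models (e.g. 5370 samples -> 17 windows, 5217 -> 16).
#'
#' @param n total sample count (vectorised).
#' @param fold fold length in samples (default 320 = 10 s at 32 Hz).
#' @return integer window count(s).
#' @export
window_count <- function(n, fold = 320L) {
  as.integer(n %/% fold + ((n %% fold) >= fold / 2))
}

#' Segment a left/right course pair into classification windows
#'
#' Cuts the two knees' recordings of one course into contiguous,
#' non-overlapping folds of `fold` samples in temporal order. A final partial
#' fold is kept iff it has at least `fold/2` samples; shorter remainders are
#' dropped. If the two knees differ in length both are truncated to the
#' shorter stream (with a warning) before segmentation, so every window holds
#' equally long blocks from both knees.
#'
#' @param left,right [gait_recording()]s of the same course, left and right
#'   knee.
#' @param fold fold length in samples (default 320); must be >= 2.
#' @return a list of `window_segment` objects, each a list with
#'   `subject_id`, `course_id`, `label` (the course state), `window_index`
#'   (0-based), `n_samples`, and `left`/`right` n x 3 sample blocks. An empty
#'   list when the course has no samples after truncation.
#' @export
segment_windows <- function(left, right, fold = 320L) {
  stopifnot(inherits(left, "gait_recording"),
            inherits(right, "gait_recording"))
  if (fold < 2) stop("fold must be >= 2")
  if (left$knee != "left" || right$knee != "right")
    stop("segment_windows expects (left, right) knee recordings in order")
  if (left$subject_id != right$subject_id ||
      left$course_id != right$course_id)
    stop("left/right recordings are from different courses")
  nl <- nrow(left$samples); nr <- nrow(right$samples)
  n <- min(nl, nr)
  if (nl != nr)
    warning("knee streams differ in length (", nl, " vs ", nr,
            "); truncating both to ", n, " samples")
  k <- window_count(n, fold)
  if (k == 0L) return(list())
  lapply(seq_len(k) - 1L, function(i) {
    from <- i * fold + 1L
    to <- min((i + 1L) * fold, n)
    structure(list(
      subject_id = left$subject_id,
      course_id = left$course_id,
      label = left$state,
      window_index = i,
      n_samples = to - from + 1L,
      left = left$samples[from:to, , drop = FALSE],
      right = right$samples[from:to, , drop = FALSE]),
      class = "window_segment")
  })
}
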