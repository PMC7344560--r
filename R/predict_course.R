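#' Classify the windows of one recorded course
#'
#' End-to-end inference for a left/right recording pair: filter, segment,
#' featurize, and score every window with a fitted model, then summarise the
#' course by majority vote. A course too short to yield any window (fewer
#' than `fold/2` samples) returns an explicit `"insufficient data"` outcome
#' rather than an error.
#'
#' @param model a `gait_model` from [train_classifier()].
#' @param left,right [gait_recording()]s of the course.
#' @param spec a [filter_spec()] (default: package default at the
#'   recording's fs).
#' @param fold fold length in samples (default 320).
#' @param leg_length,vertical_axis,gait_control see [featurize_cohort()].
#' @return list with `windows` (data.frame: `window_index`, `label`,
#'   `score`), `majority` (`"on"`, `"off"`, or `"insufficient data"`), and
#'   `n_windows`.
#' @export
predict_course <- function(model, left, right, spec = NULL, fold = 320L,
                           leg_length = 0.9, vertical_axis = 3L,
                           gait_control = list()) {
  stopifnot(inherits(model, "gait_model"))
  sp <- if (is.null(spec)) filter_spec(fs_hz = left$fs) else spec
  wins <- segment_windows(lowpass_filter(left, sp),
                          lowpass_filter(right, sp), fold = fold)
  if (!length(wins))
    return(list(windows = data.frame(window_index = integer(0),
                                     label = character(0),
                                     score = numeric(0)),
                majority = "insufficient data", n_windows = 0L))
  feats <- do.call(rbind, lapply(wins, function(w) {
    fv <- window_features(w, fs = left$fs, leg_length = leg_length,
                          vertical_axis = vertical_axis,
                          gait_control = gait_control)
    as.data.frame(as.list(fv), check.names = FALSE)
  }))
  pred <- predict(model, feats)
  majority <- if (mean(pred$label == "on") >= 0.5) "on" else "off"
  list(windows = data.frame(
         window_index = vapply(wins, `[[`, integer(1), "window_index"),
         label = as.character(pred$label), score = pred$score,
         stringsAsFactors = FALSE),
       majority = majority, n_windows = length(wins))
}
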