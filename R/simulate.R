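#' Simulation configuration for one walking course
#'
#' Parameterises the synthetic bilateral knee-accelerometer generator. The
#' signal model per knee: the vertical axis is a 1 g gravity baseline plus a
#' train of smooth biphasic impulse waveforms (a Ricker wavelet of full width
#' about one tenth of the stride period) centred at that leg's heel-strike
#' times -- left and right legs alternate, offset by half a stride -- plus an
#' optional parkinsonian tremor sinusoid and additive white sensor noise. The
#' anterior-posterior and mediolateral axes are scaled, phase-shifted copies
#' of the impulse train with independent noise.
#'
#' @param fs sampling frequency in Hz (default 32).
#' @param duration_s course duration in seconds (default 210, i.e. 3.5 min).
#' @param cadence_spm cadence in steps per minute, in 30..160 (two steps per
#'   stride; default 100).
#' @param step_impulse_g peak amplitude of the step impulse in g (default 1).
#' @param timing_jitter_cv coefficient of variation of stride intervals
#'   (default 0.02).
#' @param tremor_hz frequency of an additive tremor oscillation in Hz
#'   (0 = none, default).
#' @param tremor_g tremor amplitude in g (default 0).
#' @param noise_g white-noise standard deviation in g (default 0.05).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(fs = 32, duration_s = 210, cadence_spm = 100,
                       step_impulse_g = 1.0, timing_jitter_cv = 0.02,
                       tremor_hz = 0, tremor_g = 0, noise_g = 0.05) {
  if (fs <= 0 || duration_s <= 0) stop("fs and duration_s must be positive")
  if (cadence_spm < 30 || cadence_spm > 160)
    stop("cadence_spm must lie in [30, 160]")
  if (any(c(step_impulse_g, timing_jitter_cv, tremor_g, noise_g) < 0))
    stop("amplitudes and jitter must be non-negative")
  # worst-case amplitude sum must stay inside the +/- 8 g sensor range
  if (1 + step_impulse_g + tremor_g + 4 * noise_g > 8)
    stop("configured amplitudes can exceed the 8 g sensor range")
  structure(list(fs = fs, duration_s = duration_s, cadence_spm = cadence_spm,
                 step_impulse_g = step_impulse_g,
                 timing_jitter_cv = timing_jitter_cv, tremor_hz = tremor_hz,
                 tremor_g = tremor_g, noise_g = noise_g),
            class = "sim_config")
}

#' Packaged On / Off course configurations
#'
#' The package's reference contrast between medication states, used by the
#' end-to-end validation runs: relative to the On course, the Off course has
#' 20% lower cadence, 40% weaker step impulses, threefold stride-timing
#' jitter, and an added 5 Hz tremor component -- the qualitative signature
#' of the unmedicated parkinsonian gait (slower, weaker, more variable,
#' tremulous).
#'
#' @return a [sim_config()].
#' @export
on_default_config <- function() sim_config()

#' @rdname on_default_config
#' @export
off_default_config <- function() {
  sim_config(cadence_spm = 80, step_impulse_g = 0.6, timing_jitter_cv = 0.06,
             tremor_hz = 5, tremor_g = 0.25)
}

# Ricker (Mexican-hat) wavelet: smooth, biphasic, band-limited step impulse.
ricker <- function(t, sigma) (1 - (t / sigma)^2) * exp(-t^2 / (2 * sigma^2))

impulse_train <- function(t, strike_times, amp, sigma) {
  y <- numeric(length(t))
  for (st in strike_times) {
    lo <- st - 4 * sigma; hi <- st + 4 * sigma
    sel <- which(t >= lo & t <= hi)
    if (length(sel)) y[sel] <- y[sel] + amp * ricker(t[sel] - st, sigma)
  }
  y
}

#' Simulate one bilateral walking course
#'
#' Generates the left- and right-knee recordings of one course under the
#' configured gait state, together with the ground truth that produced them.
#' Strike times of the two legs alternate (right offset by half a stride);
#' stride intervals are jittered multiplicatively with the configured CV.
#' Fully determined by `seed`.
#'
#' @param cfg a [sim_config()].
#' @param subject_id,state,course_id metadata for the resulting recordings.
#' @param seed integer RNG seed.
#' @return list with `left` and `right` ([gait_recording()]s of
#'   `round(fs * duration_s)` samples each) and `truth` (list:
#'   `strikes_left`/`strikes_right` in seconds, `config`).
#' @export
simulate_course <- function(cfg, subject_id = "sim", state = "unknown",
                            course_id = NULL, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- round(cfg$fs * cfg$duration_s)
  t <- (seq_len(n) - 1L) / cfg$fs
  stride_s <- 2 * 60 / cfg$cadence_spm
  sigma <- 0.1 * stride_s / (2 * sqrt(2 * log(2)))  # FWHM = 0.1 stride
  withr::with_seed(seed, {
    strikes_of <- function(offset) {
      times <- c(); tm <- offset
      while (tm < cfg$duration_s) {
        times <- c(times, tm)
        tm <- tm + stride_s * max(0.2, 1 + cfg$timing_jitter_cv * stats::rnorm(1))
      }
      times
    }
    strikes_left <- strikes_of(0.5 * stride_s * stats::runif(1))
    strikes_right <- strikes_left + stride_s / 2
    strikes_right <- strikes_right[strikes_right < cfg$duration_s]
    knee_signal <- function(strikes) {
      pulse <- impulse_train(t, strikes, cfg$step_impulse_g, sigma)
      tremor <- if (cfg$tremor_hz > 0 && cfg$tremor_g > 0)
        cfg$tremor_g * sin(2 * pi * cfg$tremor_hz * t +
                             2 * pi * stats::runif(1))
      else 0
      shift <- max(1L, round(0.1 * stride_s * cfg$fs))
      lagged <- c(rep(0, shift), pulse[seq_len(n - shift)])
      vertical <- 1 + pulse + tremor + stats::rnorm(n, 0, cfg$noise_g)
      ap <- 0.5 * lagged + 0.4 * tremor + stats::rnorm(n, 0, cfg$noise_g)
      ml <- 0.3 * lagged + 0.2 * tremor + stats::rnorm(n, 0, cfg$noise_g)
      cbind(ax = ap, ay = ml, az = vertical)
    }
    left_block <- knee_signal(strikes_left)
    right_block <- knee_signal(strikes_right)
  })
  list(
    left = gait_recording(left_block, subject_id = subject_id, knee = "left",
                          state = state, fs = cfg$fs, course_id = course_id,
                          range_action = "clip"),
    right = gait_recording(right_block, subject_id = subject_id,
                           knee = "right", state = state, fs = cfg$fs,
                           course_id = course_id, range_action = "clip"),
    truth = list(strikes_left = strikes_left, strikes_right = strikes_right,
                 config = cfg))
}

#' Simulate a study-shaped cohort
#'
#' Two courses (On and Off) times two knees per subject, with subject-level
#' random effects: a cadence offset (SD `cadence_sd_spm` steps/min) and a
#' log-normal impulse-amplitude multiplier (SD `amplitude_sdlog`) drawn once
#' per subject and applied to both course configurations, giving
#' leave-one-subject-out folds genuine between-subject variance. Course
#' durations are drawn uniformly from `duration_range_s` per course so that
#' window counts differ across courses, as in real recordings. Deterministic
#' given `seed`.
#'
#' @param n_subjects number of subjects (>= 2; default 20).
#' @param on_cfg,off_cfg [sim_config()]s of the two courses (defaults:
#'   [on_default_config()] / [off_default_config()]).
#' @param seed integer RNG seed.
#' @param cadence_sd_spm SD of the per-subject cadence offset (default 6).
#' @param amplitude_sdlog SD of the per-subject log amplitude multiplier
#'   (default 0.1).
#' @param duration_range_s per-course duration range in seconds
#'   (default `c(185, 235)`, within the 3-4 min protocol).
#' @return list with `cohort` (a [gait_cohort()] of `4 * n_subjects`
#'   recordings) and `truth` (named per subject: `on`/`off` ground truth of
#'   [simulate_course()]).
#' @export
simulate_cohort <- function(n_subjects = 20L, on_cfg = on_default_config(),
                            off_cfg = off_default_config(), seed = 1L,
                            cadence_sd_spm = 6, amplitude_sdlog = 0.1,
                            duration_range_s = c(185, 235)) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  draws <- withr::with_seed(seed, list(
    cad = stats::rnorm(n_subjects, 0, cadence_sd_spm),
    amp = exp(stats::rnorm(n_subjects, 0, amplitude_sdlog)),
    dur = matrix(stats::runif(2 * n_subjects, duration_range_s[1],
                              duration_range_s[2]), ncol = 2),
    course_seeds = sample.int(.Machine$integer.max - 1L, 2 * n_subjects)))
  recs <- list(); truth <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("subj%02d", i)
    truth[[sid]] <- list()
    for (j in 1:2) {
      state <- c("on", "off")[j]
      base <- if (state == "on") on_cfg else off_cfg
      cfg <- sim_config(
        fs = base$fs, duration_s = draws$dur[i, j],
        cadence_spm = min(160, max(30, base$cadence_spm + draws$cad[i])),
        step_impulse_g = base$step_impulse_g * draws$amp[i],
        timing_jitter_cv = base$timing_jitter_cv,
        tremor_hz = base$tremor_hz, tremor_g = base$tremor_g,
        noise_g = base$noise_g)
      course <- simulate_course(cfg, subject_id = sid, state = state,
                                seed = draws$course_seeds[2 * (i - 1) + j])
      recs <- c(recs, list(course$left, course$right))
      truth[[sid]][[state]] <- course$truth
    }
  }
  list(cohort = gait_cohort(recs), truth = truth)
}
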