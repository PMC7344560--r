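# Independent oracles used across tests; deliberately written from first
# principles, not via the package's own code paths.

# Direct formula evaluation of the ten statistical window features.
oracle_stat_features <- function(block) {
  x <- sqrt(block[, 1]^2 + block[, 2]^2 + block[, 3]^2)
  n <- length(x)
  m <- sum(x) / n
  sigma <- sqrt(sum((x - m)^2) / n)
  med <- median(x)
  mad_ <- median(abs(x - med))
  # Tukey hinges: median of each half, overall median in both halves (odd n)
  xs <- sort(x)
  half <- if (n %% 2 == 0) n / 2 else (n + 1) / 2
  q1 <- median(xs[1:half]); q3 <- median(xs[(n - half + 1):n])
  s <- sqrt(sum((x - m)^2) / (n - 1))
  skew <- if (sigma == 0) 0 else n / ((n - 1) * (n - 2)) * sum(((x - m) / s)^3)
  kurt <- if (sigma == 0) 0 else
    (sum((x - m)^4) / n) / (sum((x - m)^2) / n)^2 - 3
  c(mean = m, std = sigma, mad = mad_, minimum = min(x), maximum = max(x),
    energy = sum(x^2) / n, iqr = q3 - q1,
    sma = sum(abs(block[, 1]) + abs(block[, 2]) + abs(block[, 3])) / n,
    skewness = skew, kurtosis = kurt)
}

# Analytic Butterworth magnitude response |H(f)| for a single causal pass.
butterworth_gain <- function(f, fc, order) (1 + (f / fc)^(2 * order))^(-1 / 2)

# Steady-state amplitude of a (possibly filtered) sinusoid: RMS * sqrt(2)
# over the central portion, transients trimmed.
measured_amplitude <- function(y, fs, trim_s = 2) {
  keep <- y[(trim_s * fs):(length(y) - trim_s * fs)]
  sqrt(2 * mean(keep^2))
}

# A sinusoid recording on all three axes.
sine_recording <- function(f, fs = 32, duration = 60, amp = 1,
                           knee = "left") {
  t <- (seq_len(fs * duration) - 1) / fs
  x <- amp * sin(2 * pi * f * t)
  gait_recording(cbind(x, x, x), subject_id = "sine", knee = knee,
                 state = "unknown", fs = fs)
}

# Small feature-table stand-in with the 32 feature columns filled from a
# given generator, for modelling tests that do not need real signals.
toy_feature_table <- function(n_subjects = 6, windows_per_course = 5,
                              seed = 1, informative = TRUE, shift = 3) {
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_subjects)) {
      sid <- sprintf("s%02d", i)
      for (state in c("on", "off")) {
        for (w in seq_len(windows_per_course) - 1L) {
          feats <- rnorm(32)
          if (informative)
            feats[1] <- feats[1] + ifelse(state == "on", shift, -shift)
          row <- data.frame(subject_id = sid,
                            course_id = paste(sid, state, sep = "_"),
                            window_index = w, label = state,
                            flag_left = FALSE, flag_right = FALSE,
                            stringsAsFactors = FALSE)
          fm <- as.data.frame(as.list(feats))
          names(fm) <- feature_names()
          rows[[length(rows) + 1L]] <- cbind(row, fm)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
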