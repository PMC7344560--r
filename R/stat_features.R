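#' Per-sample Euclidean magnitude of a tri-axial block
#'
#' The scalar basis signal for the windowed statistical features:
#' `sqrt(ax^2 + ay^2 + az^2)` per sample.
#'
#' @param block n x 3 numeric matrix (ax, ay, az).
#' @return numeric vector of length n, non-negative.
#' @export
magnitude <- function(block) {
  block <- as.matrix(block)
  stopifnot(ncol(block) == 3L, nrow(block) >= 1L)
  sqrt(rowSums(block^2))
}

# Tukey-hinge quartiles: median of the lower/upper half, the overall median
# included in both halves for odd n ("median of halves" quartile rule).
tukey_hinges <- function(x) {
  x <- sort(x)
  n <- length(x)
  half <- if (n %% 2L == 0L) n %/% 2L else (n + 1L) %/% 2L
  c(q1 = stats::median(x[1:half]),
    q3 = stats::median(x[(n - half + 1L):n]))
}

#' Windowed statistical features of one knee
#'
#' Computes the ten statistical descriptors of a classification window. All
#' are evaluated on the magnitude series except the signal magnitude area
#' (SMA), which by its formula uses the three axes: `mean(|ax|+|ay|+|az|)`.
#'
#' Conventions (deliberate, and load-bearing for reproducibility):
#' * standard deviation is the *population* form (divisor n);
#' * MAD is the raw median absolute deviation from the median (no 1.4826
#'   normal-consistency factor);
#' * energy is the mean squared magnitude;
#' * IQR uses Tukey-hinge quartiles (median of each half, overall median
#'   included in both halves for odd n);
#' * skewness is the Fisher-Pearson adjusted coefficient
#'   `n/((n-1)(n-2)) * sum(((x - mean)/s)^3)` with the *sample* s (divisor
#'   n-1);
#' * kurtosis is population excess kurtosis `m4/m2^2 - 3`;
#' * on a zero-variance window skewness and kurtosis are defined as 0 (not
#'   NaN) so the feature matrix stays dense; for n of 2 or 3 the two moment
#'   ratios are likewise emitted as 0 (their denominators are undefined or
#'   unstable) with a message.
#'
#' @param block n x 3 numeric matrix of one knee's window (filtered
#'   acceleration in g), n >= 2.
#' @return named numeric vector with elements `mean`, `std`, `mad`,
#'   `minimum`, `maximum`, `energy`, `iqr`, `sma`, `skewness`, `kurtosis`.
#' @export
stat_features <- function(block) {
  block <- as.matrix(block)
  n <- nrow(block)
  if (n < 2L) stop("degenerate window: need at least 2 samples, got ", n)
  x <- magnitude(block)
  m <- mean(x)
  dev <- x - m
  sigma <- sqrt(mean(dev^2))           # population sd
  md <- stats::median(abs(x - stats::median(x)))
  q <- tukey_hinges(x)
  sma <- mean(abs(block[, 1L]) + abs(block[, 2L]) + abs(block[, 3L]))
  if (n < 4L) {
    message("window of ", n, " samples: skewness/kurtosis emitted as 0")
    skew <- 0; kurt <- 0
  } else if (sigma == 0) {
    skew <- 0; kurt <- 0
  } else {
    s <- stats::sd(x)                  # sample sd for the skewness normaliser
    skew <- n / ((n - 1) * (n - 2)) * sum((dev / s)^3)
    kurt <- mean(dev^4) / mean(dev^2)^2 - 3
  }
  c(mean = m, std = sigma, mad = md, minimum = min(x), maximum = max(x),
    energy = mean(x^2), iqr = unname(q["q3"] - q["q1"]), sma = sma,
    skewness = skew, kurtosis = kurt)
}
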