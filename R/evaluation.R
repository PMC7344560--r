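#' Confusion matrix under the On-positive bookkeeping convention
#'
#' Counts follow the per-subject report convention used throughout the
#' package: the two cells of the true-"On" row are `tp` (On called On) and
#' `fp` (On called Off), and the two cells of the true-"Off" row are `fn`
#' (Off called On) and `tn` (Off called Off). Hence `tp + fp` equals the
#' number of true-On windows and `fn + tn` the number of true-Off windows.
#'
#' @param truth,predicted equal-length label vectors with values `on`/`off`
#'   (character or factor).
#' @return object of class `confusion_matrix`: list with integer `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(truth, predicted) {
  truth <- label_factor(truth)
  predicted <- label_factor(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length")
  structure(list(
    tp = sum(truth == "on" & predicted == "on"),
    fp = sum(truth == "on" & predicted == "off"),
    fn = sum(truth == "off" & predicted == "on"),
    tn = sum(truth == "off" & predicted == "off")),
    class = "confusion_matrix")
}

#' Build a confusion matrix from its four cells
#' @param tp,fp,fn,tn non-negative integer cell counts (see [confusion()]
#'   for the cell convention).
#' @return a `confusion_matrix`.
#' @export
confusion_cells <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0))
    stop("confusion cells must be non-negative")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp %d fp %d | fn %d tn %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

safe_rate <- function(num, den) if (den == 0) 0 else num / den

#' Evaluation metrics from a confusion matrix
#'
#' Standard binary metrics with "On" as the positive class:
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#' `ppv = tp/(tp+fp)`, `accuracy = (tp+tn)/total`; macro (unweighted
#' two-class) averages of recall, precision and F1; and the diagnostic odds
#' ratio `DOR = (tp*tn)/(fp*fn)`, computed with the Haldane-Anscombe
#' correction (+0.5 on all four cells) whenever any cell is zero. Degenerate
#' denominators yield a defined 0 and set `degenerate = TRUE`.
#'
#' @param cm a `confusion_matrix`.
#' @return list of metrics: `accuracy`, `avg_recall`, `avg_precision`,
#'   `avg_f1`, `sensitivity`, `specificity`, `ppv`, `dor`,
#'   `dor_corrected` (was the +0.5 correction applied), `degenerate`.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix")
  degenerate <- (tp + fn) == 0 || (tn + fp) == 0 || (tp + fp) == 0 ||
    (tn + fn) == 0
  recall_on <- safe_rate(tp, tp + fp)     # share of true-On called On
  recall_off <- safe_rate(tn, tn + fn)    # share of true-Off called Off
  prec_on <- safe_rate(tp, tp + fn)       # share of On calls that are On
  prec_off <- safe_rate(tn, tn + fp)      # share of Off calls that are Off
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  corrected <- any(c(tp, fp, fn, tn) == 0)
  dor <- if (corrected)
    ((tp + 0.5) * (tn + 0.5)) / ((fp + 0.5) * (fn + 0.5))
  else (tp * tn) / (fp * fn)
  list(accuracy = (tp + tn) / total,
       avg_recall = (recall_on + recall_off) / 2,
       avg_precision = (prec_on + prec_off) / 2,
       avg_f1 = (f1(prec_on, recall_on) + f1(prec_off, recall_off)) / 2,
       sensitivity = safe_rate(tp, tp + fn),
       specificity = safe_rate(tn, tn + fp),
       ppv = safe_rate(tp, tp + fp),
       dor = dor, dor_corrected = corrected, degenerate = degenerate)
}

#' Rank-based ROC-AUC with a bootstrap confidence interval
#'
#' The AUC is the probability that a uniformly chosen On window outscores a
#' uniformly chosen Off window, ties counting one half (Wilcoxon rank-sum
#' form). The 95% CI comes from a nonparametric bootstrap over windows
#' (resampling scores and labels jointly).
#'
#' @param scores numeric scores (higher = more "On").
#' @param truth labels `on`/`off`; both classes must be present.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return list `auc`, `ci_low`, `ci_high`.
#' @export
roc_auc <- function(scores, truth, n_boot = 1000L, seed = 1L, conf = 0.95) {
  truth <- label_factor(truth)
  if (length(scores) != length(truth))
    stop("scores and truth differ in length")
  if (length(unique(truth)) < 2L)
    stop("AUC undefined: only one class present")
  auc_of <- function(s, y) {
    n_on <- sum(y == "on"); n_off <- sum(y == "off")
    r <- rank(s, ties.method = "average")
    (sum(r[y == "on"]) - n_on * (n_on + 1) / 2) / (n_on * n_off)
  }
  est <- auc_of(scores, truth)
  boots <- withr::with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(length(scores), replace = TRUE)
    y <- truth[idx]
    if (length(unique(y)) < 2L) return(NA_real_)
    auc_of(scores[idx], y)
  }, numeric(1)))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(auc = est, ci_low = qs[1], ci_high = qs[2])
}

#' Per-subject evaluation report
#'
#' Assembles leave-one-subject-out results into the per-subject bookkeeping
#' layout: one row per subject with the four confusion cells, the raw On/Off
#' sample counts, the aggregated (10 s fold) window counts, plus a `Total`
#' row holding the column-wise sums. The window-count columns are recomputed
#' from the sample counts with [window_count()], so the report is internally
#' consistent by construction.
#'
#' @param results named list, one entry per subject: list with `confusion`
#'   (a `confusion_matrix`) and `samples_on`/`samples_off` (raw per-course
#'   sample counts).
#' @param fold fold length (default 320).
#' @return data.frame with columns `subject`, `tp`, `fp`, `fn`, `tn`,
#'   `samples_on`, `samples_off`, `windows_on`, `windows_off`; last row
#'   `Total`.
#' @export
per_subject_report <- function(results, fold = 320L) {
  subjects <- names(results)
  if (is.null(subjects) || any(duplicated(subjects)))
    stop("results must be a named list with unique subject names")
  rows <- lapply(subjects, function(sid) {
    r <- results[[sid]]
    cm <- r$confusion
    stopifnot(inherits(cm, "confusion_matrix"))
    data.frame(subject = sid, tp = cm$tp, fp = cm$fp, fn = cm$fn,
               tn = cm$tn, samples_on = r$samples_on,
               samples_off = r$samples_off,
               windows_on = window_count(r$samples_on, fold),
               windows_off = window_count(r$samples_off, fold),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  total <- data.frame(subject = "Total", tp = sum(tab$tp), fp = sum(tab$fp),
                      fn = sum(tab$fn), tn = sum(tab$tn),
                      samples_on = sum(tab$samples_on),
                      samples_off = sum(tab$samples_off),
                      windows_on = sum(tab$windows_on),
                      windows_off = sum(tab$windows_off),
                      stringsAsFactors = FALSE)
  rbind(tab, total)
}

#' Reference per-subject confusion bookkeeping table
#'
#' The packaged reference table of the clinical study design this pipeline
#' models: 20 subjects, per-subject confusion cells of the best-performing
#' classifier under leave-one-subject-out validation, raw per-course sample
#' counts and aggregated 10 s window counts. Shipped as plain text in
#' `inst/extdata/reference_subject_confusion.tsv` and used by the regression
#' tests for the windowing and bookkeeping rules. Only the 20 per-subject
#' rows are stored; totals are always recomputed as column sums.
#'
#' @return data.frame with columns `subject`, `tp`, `fp`, `fn`, `tn`,
#'   `samples_on`, `samples_off`, `windows_on`, `windows_off`.
#' @export
reference_confusion_table <- function() {
  path <- system.file("extdata", "reference_subject_confusion.tsv",
                      package = "gaitstate", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
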