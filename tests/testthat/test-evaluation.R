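test_that("confusion counting follows the On-positive row convention", {
  truth <- c(rep("on", 17), rep("off", 16))
  perfect <- confusion(truth, truth)
  expect_equal(unlist(perfect[c("tp", "fp", "fn", "tn")]),
               c(tp = 17L, fp = 0L, fn = 0L, tn = 16L))
  all_on <- confusion(truth, rep("on", 33))
  expect_equal(unlist(all_on[c("tp", "fp", "fn", "tn")]),
               c(tp = 17L, fp = 0L, fn = 16L, tn = 0L))
  expect_error(confusion(truth, rep("maybe", 33)), "label")
  expect_error(confusion(truth, truth[-1]), "length")
})

test_that("row identities hold for every reference subject and sums verify", {
  ref <- reference_confusion_table()
  expect_equal(nrow(ref), 20L)
  expect_equal(ref$tp + ref$fp, ref$windows_on)   # true-On windows
  expect_equal(ref$fn + ref$tn, ref$windows_off)  # true-Off windows
  expect_equal(sum(ref$samples_on), 119252)
  expect_equal(sum(ref$samples_off), 118508)
  expect_equal(sum(ref$samples_on) + sum(ref$samples_off), 237760)
  expect_equal(c(sum(ref$tp), sum(ref$fp), sum(ref$fn), sum(ref$tn)),
               c(343, 31, 27, 343))
  # window-count columns are exactly what the fold rule implies
  expect_equal(window_count(ref$samples_on), ref$windows_on)
  expect_equal(window_count(ref$samples_off), ref$windows_off)
})

# first-principles recomputation of every rate, independent of the package
oracle_metrics <- function(tp, fp, fn, tn) {
  tot <- tp + fp + fn + tn
  r_on <- if (tp + fp > 0) tp / (tp + fp) else 0
  r_off <- if (tn + fn > 0) tn / (tn + fn) else 0
  p_on <- if (tp + fn > 0) tp / (tp + fn) else 0
  p_off <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0
  corr <- any(c(tp, fp, fn, tn) == 0)
  cells <- c(tp, fp, fn, tn) + if (corr) 0.5 else 0
  list(accuracy = (tp + tn) / tot, avg_recall = (r_on + r_off) / 2,
       avg_precision = (p_on + p_off) / 2,
       avg_f1 = (f1(p_on, r_on) + f1(p_off, r_off)) / 2,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0,
       specificity = if (tn + fp > 0) tn / (tn + fp) else 0,
       ppv = if (tp + fp > 0) tp / (tp + fp) else 0,
       dor = (cells[1] * cells[4]) / (cells[2] * cells[3]))
}

test_that("metrics agree with a brute-force oracle on random matrices", {
  withr::with_seed(13, {
    for (i in 1:50) {
      cells <- rpois(4, lambda = sample(c(0.5, 3, 20), 1))
      if (sum(cells) == 0) cells <- c(1, 0, 0, 1)
      cm <- confusion_cells(cells[1], cells[2], cells[3], cells[4])
      got <- confusion_metrics(cm)
      want <- oracle_metrics(cells[1], cells[2], cells[3], cells[4])
      for (nm in names(want)) expect_equal(got[[nm]], want[[nm]])
    }
  })
})

test_that("aggregate rates on the reference totals match direct arithmetic", {
  ref <- reference_confusion_table()
  cm <- confusion_cells(sum(ref$tp), sum(ref$fp), sum(ref$fn), sum(ref$tn))
  m <- confusion_metrics(cm)
  expect_equal(m$accuracy, (343 + 343) / 744)
  expect_equal(m$sensitivity, 343 / (343 + 27))
  expect_equal(m$specificity, 343 / (343 + 31))
  expect_false(m$dor_corrected)
})

test_that("the diagnostic odds ratio applies the half-count correction on zeros", {
  m <- confusion_metrics(confusion_cells(50, 0, 0, 50))
  expect_equal(m$accuracy, 1)
  expect_true(m$dor_corrected)
  expect_equal(m$dor, (50.5 * 50.5) / (0.5 * 0.5))
  deg <- confusion_metrics(confusion_cells(0, 0, 0, 10))
  expect_equal(deg$sensitivity, 0)
  expect_equal(deg$specificity, 1)
  expect_true(deg$degenerate)
})

test_that("rank-based AUC matches exhaustive pair enumeration and pROC", {
  scores <- c(0.9, 0.8, 0.7, 0.85)
  labels <- c("on", "on", "off", "off")
  # brute force: all on/off pairs, ties half
  pairs <- expand.grid(i = 1:2, j = 3:4)
  conc <- mean(ifelse(scores[pairs$i] > scores[pairs$j], 1,
                      ifelse(scores[pairs$i] == scores[pairs$j], 0.5, 0)))
  expect_equal(conc, 0.75)
  got <- roc_auc(scores, labels, n_boot = 50, seed = 1)
  expect_equal(got$auc, 0.75)
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    s <- runif(200)
    y <- ifelse(runif(200) < plogis(4 * (s - 0.5)), "on", "off")
  })
  ours <- roc_auc(s, y, n_boot = 50, seed = 1)
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = factor(y, levels = c("off", "on")), predictor = s,
    quiet = TRUE, direction = "<")))
  expect_equal(ours$auc, theirs, tolerance = 1e-12)
})

test_that("AUC is 1 for separated scores, near half for independent ones", {
  sep <- roc_auc(c(rep(0.9, 10), rep(0.1, 10)),
                 c(rep("on", 10), rep("off", 10)), n_boot = 50, seed = 2)
  expect_equal(sep$auc, 1)
  expect_lte(sep$ci_high, 1)
  withr::with_seed(5, {
    s <- runif(2000)
    y <- sample(c("on", "off"), 2000, replace = TRUE)
  })
  null <- roc_auc(s, y, n_boot = 100, seed = 3)
  expect_equal(null$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(1:5, rep("on", 5)), "one class")
})

test_that("the per-subject report reproduces the reference layout and totals", {
  ref <- reference_confusion_table()
  results <- lapply(seq_len(nrow(ref)), function(i) {
    list(confusion = confusion_cells(ref$tp[i], ref$fp[i], ref$fn[i],
                                     ref$tn[i]),
         samples_on = ref$samples_on[i], samples_off = ref$samples_off[i])
  })
  names(results) <- ref$subject
  rep <- per_subject_report(results)
  expect_equal(nrow(rep), 21L)
  tot <- rep[21, ]
  expect_equal(tot$subject, "Total")
  expect_equal(c(tot$tp, tot$fp, tot$fn, tot$tn), c(343, 31, 27, 343))
  expect_equal(c(tot$windows_on, tot$windows_off), c(374, 370))
  expect_equal(rep$windows_on[1:20], ref$windows_on)
  expect_equal(rep$windows_off[1:20], ref$windows_off)
  # single subject: report equals that row plus its total
  one <- per_subject_report(results[1])
  expect_equal(one$tp, c(15, 15))
  expect_error(per_subject_report(stats::setNames(results[c(1, 1)],
                                                  c("a", "a"))), "unique")
})
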