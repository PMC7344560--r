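test_that("hyperparameter defaults match the shipped reference specification", {
  rf <- classifier_spec("random_forest")
  expect_equal(rf$hyperparameters$n_estimators, 500L)
  expect_equal(rf$hyperparameters$criterion, "gini")
  expect_equal(rf$hyperparameters$max_depth, 8L)
  expect_equal(rf$hyperparameters$min_samples_split, 8L)
  expect_equal(rf$hyperparameters$min_samples_leaf, 10L)
  sv <- classifier_spec("svm")
  expect_equal(sv$hyperparameters$kernel, "rbf")
  expect_equal(sv$hyperparameters$C, 1.0)
  expect_equal(sv$hyperparameters$tol, 0.001)
  kn <- classifier_spec("knn")
  expect_equal(kn$hyperparameters$n_neighbors, 50L)
  expect_equal(kn$hyperparameters$p, 2L)
  expect_equal(classifier_spec("naive_bayes")$hyperparameters$distribution,
               "gaussian")
  expect_error(classifier_spec("random_forest", bogus = 1), "unknown")
})

test_that("packaged feature masks have the documented shape", {
  tab <- default_feature_mask()
  expect_equal(tab$Feature, feature_names())
  expect_equal(sum(default_feature_mask("random_forest")), 22L)
  for (fam in c("svm", "knn", "naive_bayes")) {
    m <- default_feature_mask(fam)
    expect_length(m, 32L)
    expect_type(m, "logical")
  }
})

test_that("the 70:30 split is subject-level, sized, and deterministic", {
  tab <- toy_feature_table(n_subjects = 20, windows_per_course = 2)
  sp <- split_70_30(tab, seed = 4)
  expect_length(sp$train_roster, 14L)
  expect_length(sp$test_roster, 6L)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0L)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(tab))
  sp2 <- split_70_30(tab, seed = 4)
  expect_identical(sp$train_roster, sp2$train_roster)
  # boundary: two subjects split 1/1
  tab2 <- toy_feature_table(n_subjects = 2)
  sp3 <- split_70_30(tab2, seed = 1)
  expect_length(sp3$train_roster, 1L)
  expect_length(sp3$test_roster, 1L)
  expect_error(split_70_30(toy_feature_table(n_subjects = 2)[1:10, ]),
               "2 subjects")
})

test_that("LOSO folds partition the table with disjoint test sets", {
  tab <- toy_feature_table(n_subjects = 5, windows_per_course = 3)
  folds <- loso_folds(tab)
  expect_length(folds, 5L)
  test_rows <- lapply(folds, function(f) rownames(f$test))
  expect_length(unlist(test_rows), nrow(tab))
  expect_false(any(duplicated(unlist(test_rows))))
  for (f in folds) {
    expect_false(f$subject_id %in% f$train$subject_id)
    expect_true(all(f$test$subject_id == f$subject_id))
  }
  folds2 <- loso_folds(toy_feature_table(n_subjects = 2))
  expect_length(folds2, 2L)
})

test_that("RFE keeps the single informative feature and honours n_keep", {
  tab <- toy_feature_table(n_subjects = 6, windows_per_course = 6,
                           informative = TRUE)
  mask <- rfe(classifier_spec("random_forest"), tab, n_keep = 1, seed = 2)
  expect_equal(names(which(mask)), feature_names()[1])
  # exhaustive single-feature oracle: feature 1 is the unique best separator
  accs <- vapply(feature_names(), function(f) {
    thr <- mean(tab[[f]])
    max(mean((tab[[f]] > thr) == (tab$label == "on")),
        mean((tab[[f]] <= thr) == (tab$label == "on")))
  }, numeric(1))
  expect_equal(names(which.max(accs)), feature_names()[1])
  full <- suppressMessages(rfe(classifier_spec("svm"), tab, n_keep = 32))
  expect_true(all(full))
  expect_message(rfe(classifier_spec("knn"), tab, n_keep = 31),
                 "univariate")
})

test_that("all four families train and predict on separable data", {
  tab <- toy_feature_table(n_subjects = 6, windows_per_course = 10,
                           informative = TRUE, shift = 6)
  narrow <- stats::setNames(seq_len(32) <= 8, feature_names())
  for (fam in c("random_forest", "svm", "knn", "naive_bayes")) {
    spec <- classifier_spec(fam)
    # knn: neighbourhood sized to the toy table; masked to a feature subset
    # (Euclidean distance over 31 standardised noise axes drowns one
    # informative axis -- the expected lazy-learner behaviour)
    mask <- NULL
    if (fam == "knn") {
      spec <- classifier_spec("knn", n_neighbors = 5L)
      mask <- narrow
    }
    model <- train_classifier(spec, tab, mask = mask, seed = 3)
    pred <- predict(model, tab)
    if (fam == "random_forest")
      expect_equal(mean(pred$label == tab$label), 1)  # separable case
    else
      expect_gte(mean(pred$label == tab$label), 0.95)
    expect_true(all(pred$score >= 0 & pred$score <= 1))
    pred2 <- predict(model, tab)
    expect_identical(pred$label, pred2$label)   # deterministic scoring
  }
})

test_that("training rejects degenerate inputs and tolerates collinearity", {
  tab <- toy_feature_table(n_subjects = 4, windows_per_course = 5)
  single <- tab[tab$label == "on", ]
  expect_error(train_classifier(classifier_spec("random_forest"), single),
               "one class")
  # duplicated feature columns must not break training
  dup <- tab
  dup[[feature_names()[2]]] <- dup[[feature_names()[1]]]
  model <- train_classifier(classifier_spec("random_forest"), dup,
                            mask = NULL, seed = 1)
  expect_s3_class(model, "gait_model")
  expect_error(train_classifier(classifier_spec("knn"), tab, mask = NULL),
               "n_neighbors")
})

test_that("expected improvement matches its closed form and properties", {
  expect_equal(expected_improvement(0, 0, 0.5), 0)
  expect_equal(expected_improvement(0.5, 0, 0.5), 0)
  expect_equal(expected_improvement(1, 0, 0.5), 0.5)  # deterministic gain
  expect_equal(expected_improvement(0.3, 1, 0.3), dnorm(0),
               tolerance = 1e-12)
  # strictly increasing in sigma at fixed mu, f*
  sig <- seq(0.1, 2, by = 0.1)
  ei <- expected_improvement(rep(0.2, length(sig)), sig, 0.5)
  expect_true(all(diff(ei) > 0))
  expect_error(expected_improvement(0, -1, 0), "non-negative")
})

test_that("SMBO recovers a 1-D quadratic argmax and keeps honest bookkeeping", {
  space <- search_space(x = c(0, 10))
  res <- smbo_optimize(space, function(p) -(p$x - 7.3)^2, n_init = 6,
                       n_iter = 24, seed = 9)
  expect_equal(nrow(res$trace), 30L)
  expect_true(all(diff(res$trace$best_so_far) >= 0))
  expect_equal(res$best_score, max(res$trace$score))
  expect_equal(res$best$x, 7.3, tolerance = 0.05 * 7.3)
  res2 <- smbo_optimize(space, function(p) -(p$x - 7.3)^2, n_init = 6,
                        n_iter = 24, seed = 9)
  expect_identical(res$trace$score, res2$trace$score)  # seed-deterministic
})

test_that("SMBO records failing objective points and continues", {
  space <- search_space(x = c(0, 1))
  calls <- 0
  obj <- function(p) {
    calls <<- calls + 1
    if (calls == 7) stop("boom")
    p$x
  }
  expect_message(
    res <- smbo_optimize(space, obj, n_init = 4, n_iter = 6, seed = 2),
    "objective failed")
  expect_equal(nrow(res$trace), 10L)
  expect_true(is.finite(res$best_score))
})
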