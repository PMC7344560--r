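#' Classifier specification with published hyperparameter defaults
#'
#' The four classifier families and the hyperparameter defaults the package
#' ships with:
#' * `random_forest`: `n_estimators = 500`, `criterion = "gini"`,
#'   `max_depth = 8`, `min_samples_split = 8`, `min_samples_leaf = 10`
#'   (fitted with \pkg{ranger}; `min_samples_split` is recorded but
#'   non-binding, since `min_samples_leaf = 10` already forbids splitting
#'   nodes below 20 samples);
#' * `svm`: RBF kernel, `degree = 3`, `gamma = "auto"` (1/n_features),
#'   `C = 1`, `tol = 0.001` (fitted with \pkg{e1071}, internally
#'   cross-validated Platt scaling for probability scores);
#' * `knn`: `n_neighbors = 50`, uniform weights, Minkowski `p = 2`
#'   (exact Euclidean search via \pkg{class}; `leaf_size` is recorded for
#'   completeness but is a search-tree implementation detail with no effect
#'   on predictions);
#' * `naive_bayes`: Gaussian.
#'
#' @param family one of `"random_forest"`, `"svm"`, `"knn"`,
#'   `"naive_bayes"`.
#' @param ... named hyperparameter overrides of the defaults above.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("random_forest", "svm", "knn",
                                       "naive_bayes"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    random_forest = list(n_estimators = 500L, criterion = "gini",
                         max_depth = 8L, min_samples_split = 8L,
                         min_samples_leaf = 10L),
    svm = list(kernel = "rbf", degree = 3L, gamma = "auto", C = 1.0,
               tol = 0.001, cache_size = 200),
    knn = list(n_neighbors = 50L, weights = "uniform", leaf_size = 40L,
               p = 2L, metric = "minkowski"),
    naive_bayes = list(distribution = "gaussian"))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  structure(list(family = family, hyperparameters = defaults),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, format, character(1)),
              sep = "=", collapse = ", ")
  cat("<classifier_spec>", x$family, "|", hp, "\n")
  invisible(x)
}

#' Packaged per-family feature-selection masks
#'
#' The used/removed flag of each of the 32 features for each classifier
#' family, as shipped in `inst/extdata/feature_masks.tsv` (the package's
#' reference selection; see [rfe()] to recompute a mask from data).
#'
#' @param family optionally one of the four family names; when given,
#'   returns a named logical vector (TRUE = used) over [feature_names()],
#'   otherwise the full data.frame of flags.
#' @return logical vector or data.frame.
#' @export
default_feature_mask <- function(family = NULL) {
  path <- system.file("extdata", "feature_masks.tsv", package = "gaitstate",
                      mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(identical(tab$Feature, feature_names()))
  if (is.null(family)) return(tab)
  col <- switch(match.arg(family, c("random_forest", "svm", "knn",
                                    "naive_bayes")),
                random_forest = "RFC", svm = "SVM", knn = "KNN",
                naive_bayes = "NB")
  mask <- tab[[col]] == "Used"
  names(mask) <- tab$Feature
  mask
}

feature_matrix <- function(table, mask = NULL) {
  feats <- feature_names()
  missing <- setdiff(feats, names(table))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  if (!is.null(mask)) {
    if (is.logical(mask)) feats <- feats[mask[feats]]
    else feats <- intersect(feats, mask)
  }
  m <- as.matrix(table[, feats, drop = FALSE])
  if (anyNA(m)) stop("feature matrix contains missing values")
  m
}

label_factor <- function(labels) {
  bad <- setdiff(unique(as.character(labels)), c("on", "off"))
  if (length(bad))
    stop("unexpected label value(s): ", paste(bad, collapse = ", "))
  factor(as.character(labels), levels = c("off", "on"))
}

#' Subject-level 70:30 split
#'
#' Splits at the subject level, so no subject's windows straddle the
#' train/test boundary: `floor(0.7 * n_subjects)` subjects (at least 1, at
#' most n-1) are drawn into the training roster with the remainder held out.
#' With 20 subjects this is the 14/6 design split. Deterministic given
#' `seed`.
#'
#' @param table a feature table ([featurize_cohort()]).
#' @param seed integer RNG seed.
#' @return list with `train`/`test` (row subsets of `table`) and
#'   `train_roster`/`test_roster`.
#' @export
split_70_30 <- function(table, seed = 1L) {
  subjects <- sort(unique(table$subject_id))
  n <- length(subjects)
  if (n < 2L) stop("need at least 2 subjects to split; got ", n)
  n_train <- max(1L, min(n - 1L, floor(0.7 * n)))
  train_roster <- sort(withr::with_seed(seed, sample(subjects, n_train)))
  test_roster <- setdiff(subjects, train_roster)
  in_train <- table$subject_id %in% train_roster
  list(train = table[in_train, , drop = FALSE],
       test = table[!in_train, , drop = FALSE],
       train_roster = train_roster, test_roster = test_roster)
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: that subject's windows form the test set, all other
#' subjects' windows the training set. Test sets are pairwise disjoint and
#' jointly cover the table.
#'
#' @param table a feature table.
#' @return named list (by subject) of lists with `train`, `test`,
#'   `subject_id`.
#' @export
loso_folds <- function(table) {
  subjects <- sort(unique(table$subject_id))
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects")
  folds <- lapply(subjects, function(sid) {
    held <- table$subject_id == sid
    list(subject_id = sid,
         train = table[!held, , drop = FALSE],
         test = table[held, , drop = FALSE])
  })
  names(folds) <- subjects
  folds
}

# Per-feature ranking score for one RFE round. Random forest uses impurity
# importance; the other families have no native coefficient/importance
# notion, so they fall back to a univariate |Welch t| ranking (logged once).
rfe_scores <- function(spec, x, y, seed) {
  if (spec$family == "random_forest") {
    fit <- fit_family(spec, x, y, seed = seed, importance = TRUE)
    imp <- ranger::importance(fit$model)
    imp[colnames(x)]
  } else {
    on_rows <- y == "on"
    vapply(colnames(x), function(f) {
      t <- tryCatch(stats::t.test(x[on_rows, f], x[!on_rows, f])$statistic,
                    error = function(e) 0)
      abs(as.numeric(t))
    }, numeric(1))
  }
}

#' Recursive feature elimination
#'
#' Iteratively fits the estimator on the surviving features and removes the
#' lowest-ranked one (step size 1) until `n_keep` remain. The random forest
#' family ranks by impurity importance; svm (RBF), knn and naive Bayes have
#' no importance/coefficient notion, so a univariate score ranking (absolute
#' Welch t statistic between classes) is used for them, with a message.
#'
#' @param spec a [classifier_spec()].
#' @param train training feature table.
#' @param n_keep number of features to retain, in 1..32; defaults to the
#'   "Used" count of the packaged mask for the family.
#' @param seed integer seed (forest refits are randomised).
#' @return named logical vector over [feature_names()] (TRUE = kept).
#' @export
rfe <- function(spec, train, n_keep = NULL, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (is.null(n_keep)) n_keep <- sum(default_feature_mask(spec$family))
  if (n_keep < 1L || n_keep > length(feature_names()))
    stop("n_keep must be in 1..", length(feature_names()))
  if (spec$family != "random_forest")
    message("rfe: ", spec$family,
            " exposes no importance; using univariate |t| ranking")
  y <- label_factor(train$label)
  keep <- feature_names()
  while (length(keep) > n_keep) {
    x <- feature_matrix(train, keep)
    sc <- rfe_scores(spec, x, y, seed = seed)
    keep <- setdiff(keep, names(which.min(sc)))
  }
  mask <- feature_names() %in% keep
  names(mask) <- feature_names()
  mask
}

fit_family <- function(spec, x, y, seed, importance = FALSE) {
  hp <- spec$hyperparameters
  model <- switch(spec$family,
    random_forest = {
      ranger::ranger(
        x = x, y = y,
        num.trees = hp$n_estimators,
        max.depth = hp$max_depth,
        min.node.size = hp$min_samples_leaf,
        splitrule = hp$criterion,
        probability = TRUE,
        importance = if (importance) "impurity" else "none",
        num.threads = 1L, seed = seed)
    },
    svm = {
      gamma <- if (identical(hp$gamma, "auto")) 1 / ncol(x) else hp$gamma
      withr::with_seed(seed, e1071::svm(
        x = x, y = y, kernel = "radial", degree = hp$degree,
        gamma = gamma, cost = hp$C, tolerance = hp$tol,
        cachesize = hp$cache_size, probability = TRUE, scale = TRUE))
    },
    knn = {
      if (hp$p != 2L || hp$metric != "minkowski")
        stop("knn supports only the Minkowski p=2 (Euclidean) metric")
      # lazy learner: standardise and store the training set
      mu <- colMeans(x); sd <- apply(x, 2L, stats::sd)
      sd[sd == 0] <- 1
      list(x = scale(x, mu, sd), y = y, mu = mu, sd = sd,
           k = hp$n_neighbors)
    },
    naive_bayes = e1071::naiveBayes(x = x, y = y))
  structure(list(family = spec$family, spec = spec, model = model,
                 feature_names = colnames(x), seed = seed),
            class = "gait_model")
}

#' Train a medication-state classifier
#'
#' Fits the given family (with its hyperparameters) on the masked training
#' features. The fitted model predicts a hard `on`/`off` label plus a score
#' interpreted as the probability of the `on` state ("On" is the positive
#' class throughout the package).
#'
#' @param spec a [classifier_spec()].
#' @param train training feature table (rows of [featurize_cohort()]).
#' @param mask logical feature mask over [feature_names()] (default: the
#'   packaged mask for the family); `NULL` uses all 32 features.
#' @param seed integer seed for the stochastic learners.
#' @return a `gait_model`; see [predict.gait_model()].
#' @export
train_classifier <- function(spec, train, mask = default_feature_mask(spec$family),
                             seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  x <- feature_matrix(train, mask)
  if (nrow(x) == 0L) stop("empty training set")
  y <- label_factor(train$label)
  if (length(unique(y)) < 2L)
    stop("degenerate training set: only one class present")
  k <- spec$hyperparameters$n_neighbors
  if (spec$family == "knn" && !is.null(k) && k > nrow(x))
    stop("knn needs at least n_neighbors = ", k, " training rows; got ",
         nrow(x))
  fit_family(spec, x, y, seed = seed)
}

#' Predict window states with a fitted classifier
#'
#' @param object a `gait_model` from [train_classifier()].
#' @param newdata feature table (or matrix) holding at least the model's
#'   feature columns.
#' @param ... unused.
#' @return data.frame with `label` (factor off/on) and `score`
#'   (probability of "on").
#' @export
predict.gait_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) {
    missing <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing))
      stop("prediction input lacks feature(s): ",
           paste(missing, collapse = ", "))
    newdata[, object$feature_names, drop = FALSE]
  } else feature_matrix(newdata, object$feature_names)
  score <- switch(object$family,
    random_forest = stats::predict(object$model, data = x,
                                   num.threads = 1L)$predictions[, "on"],
    svm = {
      pr <- stats::predict(object$model, newdata = x, probability = TRUE)
      attr(pr, "probabilities")[, "on"]
    },
    knn = {
      m <- object$model
      xs <- scale(x, m$mu, m$sd)
      pred <- class::knn(m$x, xs, m$y, k = m$k, prob = TRUE)
      p <- attr(pred, "prob")            # share of winning class
      ifelse(pred == "on", p, 1 - p)
    },
    naive_bayes = stats::predict(object$model, newdata = x,
                                 type = "raw")[, "on"])
  data.frame(label = factor(ifelse(score >= 0.5, "on", "off"),
                            levels = c("off", "on")),
             score = as.numeric(score))
}

#' Run leave-one-subject-out cross-validation for one classifier family
#'
#' Trains on all-but-one subject and tests on the held-out subject, for every
#' subject, asserting on every fold that the held-out subject is absent from
#' the training roster (structural leakage guard).
#'
#' @param spec a [classifier_spec()].
#' @param table feature table.
#' @param mask feature mask (default: packaged mask for the family).
#' @param seed integer seed.
#' @return list with `per_subject` (named list: `confusion`, `accuracy`,
#'   `predictions`, `n_on`, `n_off`) and `mean_accuracy` (unweighted mean of
#'   per-fold accuracies).
#' @export
run_loso <- function(spec, table, mask = default_feature_mask(spec$family),
                     seed = 1L) {
  folds <- loso_folds(table)
  per <- lapply(folds, function(fold) {
    stopifnot(!fold$subject_id %in% fold$train$subject_id)
    model <- train_classifier(spec, fold$train, mask = mask, seed = seed)
    pred <- predict(model, fold$test)
    truth <- label_factor(fold$test$label)
    cm <- confusion(truth, pred$label)
    list(confusion = cm,
         accuracy = (cm$tp + cm$tn) / sum(unlist(cm[c("tp","fp","fn","tn")])),
         predictions = pred,
         n_on = sum(truth == "on"), n_off = sum(truth == "off"))
  })
  list(per_subject = per,
       mean_accuracy = mean(vapply(per, `[[`, numeric(1), "accuracy")))
}
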