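#' Random-forest configuration
#'
#' The hyperparameters of the case/control classifier: 101 trees, maximum
#' depth 4, at least 19 samples in a node to attempt a split, at least 1
#' sample per leaf, balanced class weights. Forests are grown with
#' \pkg{ranger}; see the methods vignette for the split-criterion note
#' (Gini impurity is used in place of information gain, which ranger does
#' not offer).
#'
#' @param n_trees Number of trees (default 101).
#' @param max_depth Maximum tree depth (default 4).
#' @param min_split Minimum node size to attempt a split (default 19).
#' @param min_leaf Minimum terminal node size (default 1).
#' @param class_weight `"balanced"` (inverse class frequencies) or
#'   `"none"`.
#' @param seed Integer seed for tree growing.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 101, max_depth = 4, min_split = 19,
                      min_leaf = 1, class_weight = "balanced", seed = 1L) {
  stopifnot(n_trees >= 1, max_depth >= 1, min_split >= 1, min_leaf >= 1)
  class_weight <- match.arg(class_weight, c("balanced", "none"))
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 min_split = as.integer(min_split),
                 min_leaf = as.integer(min_leaf),
                 class_weight = class_weight,
                 seed = as.integer(seed)),
            class = "rf_config")
}

as_feature_matrix <- function(X) {
  if (inherits(X, "cohort_matrix")) X$X else as.matrix(X)
}

rf_fit <- function(X, y, cfg) {
  yf <- factor(y)
  cw <- if (cfg$class_weight == "balanced") {
    tab <- table(yf)
    as.numeric(length(yf) / (length(tab) * tab))
  } else NULL
  colnames(X) <- paste0("p", seq_len(ncol(X)))
  ranger::ranger(x = X, y = yf,
                 num.trees = cfg$n_trees, max.depth = cfg$max_depth,
                 min.node.size = cfg$min_split, min.bucket = cfg$min_leaf,
                 class.weights = cw, seed = cfg$seed, num.threads = 1,
                 verbose = FALSE)
}

rf_predict <- function(fit, X) {
  colnames(X) <- paste0("p", seq_len(ncol(X)))
  as.character(stats::predict(fit, data = X, num.threads = 1)$predictions)
}

## Stratified fold assignment, deterministic given the seed.
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validated classification
#'
#' Per-fold accuracy of a random forest trained on the remaining folds.
#' If a `selector` function is supplied, feature selection is refit
#' inside every training fold (selection never sees the test fold); when
#' it is omitted, the matrix is used as given — the protocol in which
#' sites are selected once on the full optimization set corresponds to
#' selecting beforehand and passing the restricted matrix.
#'
#' @param X Feature matrix (samples x sites) or `cohort_matrix`.
#' @param y Class labels (from the cohort matrix when omitted).
#' @param cfg An [rf_config()].
#' @param n_folds Number of folds (default 10); every class must have at
#'   least `n_folds` members.
#' @param seed Seed for the fold shuffle (default `cfg$seed`).
#' @param selector Optional `function(X_train, y_train) -> column indices`
#'   refit inside each fold.
#' @return An object of class `cv_report`: list with `fold_accuracy`
#'   (length `n_folds`), `mean_accuracy`, `max_accuracy`, and `confusion`
#'   (summed over folds).
#' @export
crossval_classify <- function(X, y = NULL, cfg = rf_config(), n_folds = 10,
                              seed = cfg$seed, selector = NULL) {
  if (inherits(X, "cohort_matrix")) { y <- y %||% X$group; X <- X$X }
  X <- as.matrix(X)
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) != 2) stop("classification requires exactly 2 classes")
  if (min(tab) < n_folds)
    stop(sprintf("class '%s' has %d samples; use at most %d folds",
                 names(tab)[which.min(tab)], min(tab), min(tab)))
  fold <- stratified_folds(y, n_folds, seed)
  lv <- sort(unique(y))
  confusion <- matrix(0L, 2, 2, dimnames = list(truth = lv, predicted = lv))
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (!is.null(selector)) {
      keep <- selector(Xtr, y[tr])
      Xtr <- Xtr[, keep, drop = FALSE]
      Xte <- Xte[, keep, drop = FALSE]
    }
    pred <- rf_predict(rf_fit(Xtr, y[tr], cfg), Xte)
    acc[f] <- mean(pred == y[te])
    for (i in seq_along(pred))
      confusion[y[te][i], pred[i]] <- confusion[y[te][i], pred[i]] + 1L
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 max_accuracy = max(acc), confusion = confusion,
                 n_folds = n_folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV: mean accuracy %.2f%%, max %.2f%%\n",
              x$n_folds, 100 * x$mean_accuracy, 100 * x$max_accuracy))
  invisible(x)
}

#' Train on one cohort, test on a disjoint one
#'
#' @param X_train,y_train Training matrix and labels.
#' @param X_test,y_test Held-out matrix and labels; must have the same
#'   feature columns as the training matrix.
#' @param cfg An [rf_config()].
#' @return List with `accuracy`, `per_class_recall`, and `confusion`.
#' @export
train_and_test <- function(X_train, y_train, X_test, y_test,
                           cfg = rf_config()) {
  X_train <- as_feature_matrix(X_train); X_test <- as_feature_matrix(X_test)
  if (ncol(X_train) != ncol(X_test))
    stop("train and test matrices have different feature columns")
  y_train <- as.character(y_train); y_test <- as.character(y_test)
  pred <- rf_predict(rf_fit(X_train, y_train, cfg), X_test)
  lv <- sort(unique(c(y_train, y_test)))
  confusion <- table(factor(y_test, lv), factor(pred, lv),
                     dnn = c("truth", "predicted"))
  recall <- vapply(lv, function(cl) {
    n <- sum(y_test == cl)
    if (n == 0) NA_real_ else mean(pred[y_test == cl] == cl)
  }, numeric(1))
  list(accuracy = mean(pred == y_test),
       per_class_recall = recall,
       confusion = confusion)
}

#' The HVS1 hypervariable region
#'
#' Positions 15,977-16,391 (1-based, inclusive) of the rCRS axis: the
#' 415 bp hypervariable segment 1 of the mtDNA control region.
#'
#' @return List with `start` and `end`.
#' @export
hvs1_region <- function() list(start = 15977L, end = 16391L)

#' Restrict a cohort matrix to a genomic region
#'
#' @param X A `cohort_matrix` (or plain matrix whose columns are
#'   positions 1..L).
#' @param region List with 1-based inclusive `start` and `end`
#'   (default [hvs1_region()]).
#' @return Object of the same kind with columns limited to the region.
#' @export
restrict_to_region <- function(X, region = hvs1_region()) {
  if (region$start < 1 || region$end < region$start)
    stop("empty or invalid region")
  if (inherits(X, "cohort_matrix")) {
    keep <- X$positions >= region$start & X$positions <= region$end
    if (!any(keep)) stop("region contains no columns")
    X$X <- X$X[, keep, drop = FALSE]
    X$positions <- X$positions[keep]
    return(X)
  }
  if (region$end > ncol(X)) stop("region extends past the matrix")
  as.matrix(X)[, region$start:region$end, drop = FALSE]
}

#' Cross-validated random-forest grade regression
#'
#' Predicts the neoplasm histologic grade (integer 1..4) from SMEP
#' features with a random-forest regressor sharing the classifier's
#' structural hyperparameters, and reports the k-fold mean absolute
#' error together with a label-permutation baseline (the MAE of
#' predicting a random permutation of the observed grades, averaged over
#' `n_permutations` permutations).
#'
#' @param X Feature matrix or `cohort_matrix`.
#' @param grades Integer grades, at least two distinct values.
#' @param cfg An [rf_config()].
#' @param n_folds Folds (default 10).
#' @param seed Seed (default `cfg$seed`).
#' @param n_permutations Permutations for the baseline (default 100).
#' @return List with `mae`, `fold_mae`, and `baseline_mae`.
#' @export
grade_regression <- function(X, grades, cfg = rf_config(), n_folds = 10,
                             seed = cfg$seed, n_permutations = 100) {
  X <- as_feature_matrix(X)
  grades <- as.numeric(grades)
  if (length(unique(grades)) < 2) stop("grades are constant")
  fold <- stratified_folds(as.character(grades), n_folds, seed)
  ## Small grade classes may not fill every fold; fall back to plain
  ## shuffled folds if any fold came out empty.
  if (any(tabulate(fold, n_folds) == 0))
    fold <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), length(grades))))
  fold_mae <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
    colnames(Xtr) <- colnames(Xte) <- paste0("p", seq_len(ncol(Xtr)))
    fit <- ranger::ranger(x = Xtr, y = grades[tr],
                          num.trees = cfg$n_trees, max.depth = cfg$max_depth,
                          min.node.size = cfg$min_split,
                          min.bucket = cfg$min_leaf,
                          seed = cfg$seed, num.threads = 1, verbose = FALSE)
    pred <- stats::predict(fit, data = Xte, num.threads = 1)$predictions
    fold_mae[f] <- mean(abs(pred - grades[!tr]))
  }
  baseline <- withr::with_seed(seed, {
    mean(vapply(seq_len(n_permutations),
                function(i) mean(abs(sample(grades) - grades)),
                numeric(1)))
  })
  list(mae = mean(fold_mae), fold_mae = fold_mae, baseline_mae = baseline)
}
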