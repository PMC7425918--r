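#' Stratified fold plan for k-fold cross-validation
#'
#' Partitions `n` records into `k` disjoint, exhaustive folds, stratified
#' by class: within every class, members are shuffled (seeded) and dealt
#' out so that per-fold class counts differ by at most one; per-class
#' remainders go to the currently smallest folds, so total fold sizes also
#' differ by at most one. With 7500 balanced records and k = 10 every fold
#' has exactly 750.
#'
#' @param n number of records.
#' @param k number of folds (`k <= n`).
#' @param labels class factor per record (`NULL` for unstratified).
#' @param seed RNG seed for the shuffles.
#' @return A `fold_plan`: list with `k`, `assignments` (fold index per
#'   record), `seed`.
#' @export
make_folds <- function(n, k, labels = NULL, seed = 1L) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (k < 2L || k > n) stopf("need 2 <= k <= n")
  if (is.null(labels)) labels <- factor(rep("all", n))
  labels <- droplevels(as.factor(labels))
  if (length(labels) != n) stopf("labels length must equal n")
  assignments <- integer(n)
  with_seed(seed, {
    sizes <- integer(k)
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      n_c <- length(idx)
      base <- n_c %/% k
      rem <- n_c %% k
      # remainders go to the currently smallest folds
      extra <- order(sizes, sample(k))[seq_len(rem)]
      per_fold <- rep(base, k)
      per_fold[extra] <- per_fold[extra] + 1L
      assignments[idx] <- rep(seq_len(k), per_fold)
      sizes <- sizes + per_fold
    }
  })
  structure(list(k = k, assignments = assignments, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Probabilistic neural network prediction
#'
#' PNN from its definition (input, pattern, summation, output layers):
#' for every test point, the class score is the mean over that class's
#' training points of `exp(-||x - x_i||^2 / (2 spread^2))` (mean, not
#' sum, so class imbalance does not bias the summation layer); the
#' predicted class is the argmax, ties broken toward the lower (earlier)
#' class level.
#'
#' @param train_X,train_y training matrix and class factor.
#' @param test_X test matrix (same columns).
#' @param spread Gaussian kernel spread (sigma), > 0.
#' @return factor of predicted labels with the training levels.
#' @export
pnn_predict <- function(train_X, train_y, test_X, spread = 0.1) {
  if (!(spread > 0)) stopf("spread must be > 0")
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X, ncol = ncol(train_X))
  train_y <- as.factor(train_y)
  d2 <- outer(rowSums(test_X^2), rep(1, nrow(train_X))) +
    outer(rep(1, nrow(test_X)), rowSums(train_X^2)) -
    2 * tcrossprod(test_X, train_X)
  d2 <- pmax(d2, 0)
  k <- exp(-d2 / (2 * spread^2))
  lev <- levels(train_y)
  counts <- table(train_y)
  if (any(counts == 0L)) {
    warning(sprintf("class(es) %s empty in training; never predicted",
                    paste(lev[counts == 0L], collapse = ", ")), call. = FALSE)
  }
  scores <- vapply(lev, function(cl) {
    idx <- which(train_y == cl)
    if (length(idx) == 0L) return(rep(-Inf, nrow(test_X)))
    rowSums(k[, idx, drop = FALSE]) / length(idx)
  }, numeric(nrow(test_X)))
  scores <- matrix(scores, nrow = nrow(test_X))
  factor(lev[apply(scores, 1L, which.max)], levels = lev)
}

#' Train one classifier and predict test labels
#'
#' The three classifiers used for size classification, all deterministic
#' given the data: a linear support vector machine (libsvm via
#' [e1071::svm()], cost 1, libsvm's native one-vs-one multi-class
#' voting), the probabilistic neural network ([pnn_predict()]) and
#' Gaussian naive Bayes ([e1071::naiveBayes()], per-class feature
#' means/variances).
#'
#' @param train_X,train_y training matrix and class factor.
#' @param test_X test matrix.
#' @param model_spec `"svm_linear"`, `"gaussian_nb"`, `"pnn"` or
#'   `list(name = "pnn", spread = <sigma>)`.
#' @return factor of predicted labels.
#' @export
train_predict <- function(train_X, train_y, test_X, model_spec) {
  spec <- as_model_spec(model_spec)
  train_y <- droplevels(as.factor(train_y))
  if (nlevels(train_y) < 2L) stopf("training set has a single class")
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X)
  colnames(train_X) <- colnames(test_X) <- paste0("f", seq_len(ncol(train_X)))
  switch(spec$name,
    svm_linear = {
      fit <- e1071::svm(train_X, train_y, kernel = "linear", cost = 1,
                        scale = apply(train_X, 2L, function(c) sd(c) > 0))
      unname(stats::predict(fit, test_X))
    },
    gaussian_nb = {
      fit <- e1071::naiveBayes(as.data.frame(train_X), train_y)
      stats::predict(fit, as.data.frame(test_X))
    },
    pnn = pnn_predict(train_X, train_y, test_X, spread = spec$spread)
  )
}

as_model_spec <- function(model_spec) {
  if (is.character(model_spec)) model_spec <- list(name = model_spec)
  model_spec$name <- match.arg(model_spec$name,
                               c("svm_linear", "gaussian_nb", "pnn"))
  if (model_spec$name == "pnn" && is.null(model_spec$spread)) {
    model_spec$spread <- 0.1
  }
  model_spec
}

#' Confusion matrix of predicted vs true labels
#'
#' @param truth,predicted factors over the same class levels.
#' @return square integer table, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  table(truth = truth, predicted = predicted)
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' Per class (one-vs-rest): `TP` is the diagonal entry, `FN` the rest of
#' the row, `FP` the rest of the column, `TN` the remainder; then
#' `accuracy = (TN + TP) / (TN + TP + FN + FP)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`, all in
#' percent. The reported scalar `accuracy` is the overall correct-
#' classification rate (the pooled `(TP + TN) / total`, which for the
#' multi-class table is `sum(diag) / total`, so a chance classifier on
#' six balanced classes scores near 16.7%); `macro_accuracy` is the
#' macro-average of the per-class one-vs-rest accuracies (the multi-class
#' averaging convention, which sits near 72% for the same chance
#' classifier because true negatives dominate each one-vs-rest table);
#' `sensitivity` and `specificity` are macro-averages of the per-class
#' one-vs-rest values. Classes absent from the test set (empty row) are
#' excluded from the macro-averages.
#'
#' @param confusion square counts table (rows = truth).
#' @return list with `accuracy` (percent, overall), `macro_accuracy`,
#'   `sensitivity`, `specificity` (percent, macro-averaged), `per_class`
#'   (data.frame with the per-class one-vs-rest values and TP/FP/TN/FN
#'   counts), `excluded` (classes absent from the test set).
#' @export
score_confusion <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm) || sum(cm) == 0) stopf("invalid confusion matrix")
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  per_class <- data.frame(
    class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
    TP = as.integer(tp), FN = as.integer(fn), FP = as.integer(fp),
    TN = as.integer(tn),
    accuracy = 100 * (tp + tn) / total,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp))
  present <- rowSums(cm) > 0
  list(accuracy = 100 * sum(tp) / total,
       macro_accuracy = mean(per_class$accuracy[present]),
       sensitivity = mean(per_class$sensitivity[present]),
       specificity = mean(per_class$specificity[present]),
       per_class = per_class,
       excluded = per_class$class[!present])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified k-fold cross-validation of one classifier
#'
#' Runs [train_predict()] over a seeded stratified fold plan: each fold in
#' turn is the test set, the remaining k-1 folds train the model. Emits
#' one confusion matrix and one metric triple per fold; the averaged
#' metrics are the plain mean over folds.
#'
#' @param x records x features matrix.
#' @param y class factor per record.
#' @param model_spec see [train_predict()].
#' @param k number of folds.
#' @param seed seed for the fold plan.
#' @param folds optional explicit [make_folds()] plan (overrides
#'   `k`/`seed`).
#' @return An `eval_report`: list with `folds` (per fold: `confusion`,
#'   `metrics`), `average` (accuracy/sensitivity/specificity percent),
#'   `per_fold` (data.frame), `model`, `k`, `seed`.
#' @export
cross_validate <- function(x, y, model_spec, k = 10L, seed = 1L,
                           folds = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (is.null(folds)) folds <- make_folds(nrow(x), k, labels = y, seed = seed)
  stopifnot(inherits(folds, "fold_plan"), length(folds$assignments) == nrow(x))
  spec <- as_model_spec(model_spec)
  fold_out <- lapply(seq_len(folds$k), function(f) {
    test <- folds$assignments == f
    pred <- train_predict(x[!test, , drop = FALSE], y[!test],
                          x[test, , drop = FALSE], spec)
    cm <- confusion_matrix(y[test], pred)
    list(confusion = cm, metrics = score_confusion(cm))
  })
  per_fold <- data.frame(
    fold = seq_len(folds$k),
    accuracy = vapply(fold_out, function(f) f$metrics$accuracy, numeric(1)),
    macro_accuracy = vapply(fold_out, function(f) f$metrics$macro_accuracy,
                            numeric(1)),
    sensitivity = vapply(fold_out, function(f) f$metrics$sensitivity, numeric(1)),
    specificity = vapply(fold_out, function(f) f$metrics$specificity, numeric(1)))
  structure(list(folds = fold_out,
                 per_fold = per_fold,
                 average = c(accuracy = mean(per_fold$accuracy),
                             macro_accuracy = mean(per_fold$macro_accuracy),
                             sensitivity = mean(per_fold$sensitivity),
                             specificity = mean(per_fold$specificity)),
                 model = spec$name, k = folds$k, seed = folds$seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d-fold: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              x$model, x$k, x$average["accuracy"], x$average["sensitivity"],
              x$average["specificity"]))
  invisible(x)
}
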