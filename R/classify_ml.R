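## Trait-table classification baseline --------------------------------------
##
## Six classical models on the 11-trait table with stratified 5-fold
## cross-validation and per-fold grid search, plus the shared confusion-count
## metrics used by both the baseline and the point-set classifier.

#' Accuracy and F1 from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)` and
#' `F1 = 2 TP / (2 TP + FP + FN)`, evaluated exactly on the integer counts.
#'
#' @param TP,FP,TN,FN non-negative counts.
#' @return list with `accuracy` and `F1`.
#' @export
compute_metrics <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("all confusion counts are zero")
  f1_den <- 2 * TP + FP + FN
  f1 <- if (f1_den == 0) {
    warning("F1 undefined (no positive predictions or truths); reported as 0")
    0
  } else 2 * TP / f1_den
  list(accuracy = (TP + TN) / sum(counts), F1 = f1)
}

#' Build a classification report from predictions
#'
#' Positive class is the first factor level of `truth`.
#'
#' @param truth factor of true labels.
#' @param predicted factor of predictions (same levels).
#' @param times optional per-sample inference times (seconds).
#' @return object of class `classification_report`: confusion counts,
#'   `accuracy`, `F1`, `times` and `efficiency` (total inference time).
#' @export
classification_report <- function(truth, predicted, times = NULL) {
  truth <- factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  pos <- levels(truth)[1]
  tp <- sum(truth == pos & predicted == pos)
  fp <- sum(truth != pos & predicted == pos)
  tn <- sum(truth != pos & predicted != pos)
  fn <- sum(truth == pos & predicted != pos)
  m <- compute_metrics(tp, fp, tn, fn)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 accuracy = m$accuracy, F1 = m$F1,
                 positive_class = pos, times = times,
                 efficiency = if (!is.null(times)) sum(times) else NA_real_),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> positive = '%s'\n", x$positive_class))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  accuracy %.4f  F1 %.4f", x$accuracy, x$F1))
  if (!is.na(x$efficiency)) cat(sprintf("  efficiency %.3f s", x$efficiency))
  cat("\n")
  invisible(x)
}

# Stratified fold assignment: each class is spread evenly over k folds.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

default_grids <- function() {
  list(
    dt = expand.grid(cp = c(0.001, 0.01, 0.05), maxdepth = c(4, 8)),
    rf = expand.grid(ntree = c(100, 300), mtry = c(2, 3)),
    svm = expand.grid(cost = c(0.1, 1, 10), gamma = c(0.05, 0.2)),
    nb = expand.grid(laplace = 0),
    bpnn = expand.grid(size = c(4, 8), decay = c(1e-4, 1e-2)),
    xgb = expand.grid(max_depth = c(2, 4), nrounds = c(50, 150), eta = 0.1)
  )
}

# Fit one model on (X, y) with one grid row; returns a predict closure.
fit_one <- function(model, X, y, par) {
  df <- data.frame(X, .y = y)
  switch(model,
    dt = {
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            cp = par$cp, maxdepth = par$maxdepth))
      function(Xn) predict(fit, data.frame(Xn), type = "class")
    },
    rf = {
      fit <- randomForest::randomForest(x = X, y = y, ntree = par$ntree,
                                        mtry = min(par$mtry, ncol(X)))
      function(Xn) predict(fit, Xn)
    },
    svm = {
      fit <- e1071::svm(x = X, y = y, kernel = "radial",
                        cost = par$cost, gamma = par$gamma)
      function(Xn) predict(fit, Xn)
    },
    nb = {
      fit <- e1071::naiveBayes(x = X, y = y, laplace = par$laplace)
      function(Xn) predict(fit, Xn)
    },
    bpnn = {
      fit <- nnet::nnet(X, nnet::class.ind(y), size = par$size,
                        decay = par$decay, maxit = 300, trace = FALSE,
                        softmax = TRUE)
      function(Xn) factor(levels(y)[max.col(predict(fit, Xn),
                                            ties.method = "first")],
                          levels = levels(y))
    },
    xgb = {
      fit <- xgboost::xgboost(as.matrix(X), y, nrounds = par$nrounds,
                              max_depth = par$max_depth,
                              learning_rate = par$eta,
                              nthreads = 1, verbosity = 0)
      # predictions are probabilities of the second factor level
      function(Xn) factor(levels(y)[(predict(fit, as.matrix(Xn)) > 0.5) + 1L],
                          levels = levels(y))
    },
    stop("unknown model '", model, "'"))
}

# Models whose features are standardized within each training fold.
scaled_models <- c("svm", "nb", "bpnn")

#' Cross-validated trait-table classification
#'
#' Runs the six-model baseline (decision tree, random forest, SVM, naive
#' Bayes, back-propagation neural network, gradient boosting) under
#' stratified k-fold cross-validation. Inside each training fold the
#' hyperparameters are chosen by grid search with an inner 3-fold split;
#' the winning setting is refit on the full training fold and evaluated on
#' the held-out fold, so every sample is tested exactly once. Features are
#' z-scored (training-fold statistics) for SVM, naive Bayes and the neural
#' network; tree models see raw traits.
#'
#' @param traits data.frame or matrix of numeric features (e.g. the 11-trait
#'   table from [extract_trait_table()], trait columns only).
#' @param labels factor (or coercible) of class labels.
#' @param models subset of `c("dt","rf","svm","nb","bpnn","xgb")`.
#' @param k number of outer folds.
#' @param grids named list of hyperparameter grids (data.frames), defaults
#'   from `default_grids()`.
#' @param seed integer seed controlling folds and model fits.
#' @return list per model: `report` (pooled [classification_report()]),
#'   `fold_accuracy`, `fold_F1`, `mean_accuracy`, `mean_F1`, `chosen`
#'   (per-fold grid rows).
#' @export
crossval_classifiers <- function(traits, labels,
                                 models = c("dt", "rf", "svm", "nb",
                                            "bpnn", "xgb"),
                                 k = 5, grids = default_grids(), seed = 1L) {
  X <- as.matrix(traits)
  if (!is.numeric(X)) stop("traits must be numeric")
  bad <- colnames(X)[!apply(X, 2, function(v) all(is.finite(v)))]
  if (length(bad) > 0)
    stop("non-finite feature values in columns: ", paste(bad, collapse = ", "))
  labels <- factor(labels)
  if (k < 2) stop("k must be at least 2")
  unknown <- setdiff(models, names(default_grids()))
  if (length(unknown) > 0)
    stop("unknown model name(s): ", paste(unknown, collapse = ", "))

  with_seed(seed, {
    folds <- stratified_folds(labels, k)
    out <- list()
    for (model in models) {
      grid <- grids[[model]]
      preds <- factor(rep(NA, length(labels)), levels = levels(labels))
      fold_acc <- numeric(k)
      fold_f1 <- numeric(k)
      chosen <- vector("list", k)
      for (f in seq_len(k)) {
        tr <- which(folds != f)
        te <- which(folds == f)
        Xtr <- X[tr, , drop = FALSE]
        ytr <- labels[tr]
        if (model %in% scaled_models) {
          mu <- colMeans(Xtr)
          sg <- pmax(apply(Xtr, 2, sd), 1e-12)
          Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
          Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sg, "/")
        } else {
          Xte <- X[te, , drop = FALSE]
        }
        best_row <- 1L
        if (nrow(grid) > 1) {
          inner <- stratified_folds(ytr, 3)
          score <- numeric(nrow(grid))
          for (g in seq_len(nrow(grid))) {
            acc <- numeric(3)
            for (i in 1:3) {
              itr <- inner != i
              pred_fun <- fit_one(model, Xtr[itr, , drop = FALSE], ytr[itr],
                                  grid[g, , drop = FALSE])
              acc[i] <- mean(pred_fun(Xtr[!itr, , drop = FALSE]) == ytr[!itr])
            }
            score[g] <- mean(acc)
          }
          best_row <- which.max(score)
        }
        chosen[[f]] <- grid[best_row, , drop = FALSE]
        pred_fun <- fit_one(model, Xtr, ytr, grid[best_row, , drop = FALSE])
        pf <- pred_fun(Xte)
        preds[te] <- pf
        rep_f <- classification_report(labels[te], pf)
        fold_acc[f] <- rep_f$accuracy
        fold_f1[f] <- rep_f$F1
      }
      out[[model]] <- list(report = classification_report(labels, preds),
                           fold_accuracy = fold_acc, fold_F1 = fold_f1,
                           mean_accuracy = mean(fold_acc),
                           mean_F1 = mean(fold_f1), chosen = chosen)
    }
    out
  })
}

#' Summarise a cross-validation run as a table
#'
#' @param cv result of [crossval_classifiers()].
#' @return data.frame with one row per model.
#' @export
cv_summary <- function(cv) {
  data.frame(model = names(cv),
             mean_accuracy = vapply(cv, function(m) m$mean_accuracy, 0),
             mean_F1 = vapply(cv, function(m) m$mean_F1, 0),
             pooled_accuracy = vapply(cv, function(m) m$report$accuracy, 0),
             pooled_F1 = vapply(cv, function(m) m$report$F1, 0),
             row.names = NULL)
}
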