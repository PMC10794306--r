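#' Leave-one-subject-out folds
#'
#' One fold per subject: the test set is all of that subject's epochs, the
#' training set everyone else's, so no subject ever contributes to both
#' sides of a fold.
#'
#' @param features Feature table with a `subject_id` column.
#' @return List of folds, each a list with `subject`, `train` and `test`
#'   row indices.
#' @export
loso_folds <- function(features) {
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects for LOSO folds")
  lapply(subjects, function(s) {
    test <- which(features$subject_id == s)
    list(subject = s, train = setdiff(seq_len(nrow(features)), test),
         test = test)
  })
}

#' Majority-class chance level
#'
#' The accuracy of always predicting the larger class, as an integer
#' percentage: `round(100 * max(class proportion))`. With 16 MCI and 7
#' healthy participants this is 70%.
#'
#' @param labels Nonempty vector of class labels (one per subject).
#' @return Integer percent.
#' @examples
#' chance_level(rep(c("mci", "healthy"), c(16, 7))) # 70
#' @export
chance_level <- function(labels) {
  if (length(labels) == 0) stop("labels must be nonempty")
  as.integer(round(100 * max(table(labels)) / length(labels)))
}

# per-class precision/recall/f1 with the 0/0 -> 0 convention
class_prf <- function(truth, pred, cls) {
  tp <- sum(truth == cls & pred == cls)
  fp <- sum(truth != cls & pred == cls)
  fn <- sum(truth == cls & pred != cls)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Classification / regression metric panel for aligned predictions
#'
#' For class-valued inputs: accuracy, and precision/recall/f1 either
#' averaged over classes weighted by true-class support (default), macro
#' averaged, or for the positive class only; AUC from `scores` when both
#' classes occur in the truth (otherwise `NA` with a warning). For numeric
#' inputs: pooled r2, MSE, MAE, median absolute error and MAPE (%).
#'
#' @param y_true,y_pred Aligned truth/prediction vectors.
#' @param scores Optional positive-class scores for AUC.
#' @param positive Positive class label (default `"mci"`).
#' @param average `"weighted"`, `"macro"` or `"positive"`.
#' @return Named list of metrics.
#' @export
metric_suite <- function(y_true, y_pred, scores = NULL, positive = "mci",
                         average = c("weighted", "macro", "positive")) {
  average <- match.arg(average)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (is.numeric(y_true) && is.numeric(y_pred) && !is.factor(y_true)) {
    err <- y_true - y_pred
    sst <- sum((y_true - mean(y_true))^2)
    return(list(
      r2 = if (sst == 0) NA_real_ else 1 - sum(err^2) / sst,
      mse = mean(err^2),
      mae = mean(abs(err)),
      median_error = median(abs(err)),
      mape = mean(abs(err) / abs(y_true)) * 100))
  }
  truth <- as.character(y_true); pred <- as.character(y_pred)
  classes <- sort(unique(truth))
  per <- vapply(classes, function(cl) class_prf(truth, pred, cl), numeric(3))
  w <- vapply(classes, function(cl) mean(truth == cl), numeric(1))
  pick <- function(row) switch(average,
    weighted = sum(per[row, ] * w),
    macro = mean(per[row, ]),
    positive = if (positive %in% classes) per[row, positive] else 0)
  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(unique(truth)) < 2) {
      warning("AUC undefined: only one class present in the truth")
    } else {
      r <- pROC::roc(response = factor(truth == positive, c(FALSE, TRUE)),
                     predictor = as.numeric(scores), direction = "<",
                     quiet = TRUE)
      auc <- as.numeric(pROC::auc(r))
    }
  }
  list(accuracy = mean(truth == pred), auc = auc,
       f1 = pick("f1"), recall = pick("recall"),
       precision = pick("precision"))
}

# median + 95-percentile interval across folds
fold_summary <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) return(c(median = NA_real_, lo = NA_real_, hi = NA_real_))
  c(median = median(v), lo = unname(quantile(v, 0.025)),
    hi = unname(quantile(v, 0.975)))
}

prepare_condition <- function(features, condition) {
  stopifnot(condition %in% c("TGT", "IGN", "ALL"))
  sub <- if (condition == "ALL") features else
    features[features$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0) stop("no epochs in condition ", condition)
  sub
}

#' Leave-one-subject-out random-forest MCI classification
#'
#' Trains a random forest (`n_trees` trees) on the six topological features
#' of all training subjects' epochs and predicts each epoch of the held-out
#' subject, for every fold. Scoring is at epoch level; per-fold accuracy,
#' f1, recall and precision are aggregated as median with a 95-percentile
#' interval across folds, and pooled metrics (including AUC from the pooled
#' class probabilities) are computed over all held-out epochs.
#'
#' @param features Feature table with both groups.
#' @param condition `"TGT"`, `"IGN"` or `"ALL"`.
#' @param n_trees Trees in the forest.
#' @param seed Integer seed (per-fold seeds are derived from it).
#' @param average Averaging mode for f1/recall/precision, see
#'   [metric_suite()].
#' @return A `metric_panel`: list with `task`, `condition`, `per_fold`
#'   (data frame of per-fold metrics), `fold_predictions` (per-epoch),
#'   `summary` (median + interval per metric) and `pooled`.
#' @export
classify_loso <- function(features, condition = "ALL", n_trees = 200,
                          seed = 1L, average = "weighted") {
  sub <- prepare_condition(features, condition)
  folds <- loso_folds(sub)
  x <- as.matrix(sub[, tda_feature_names()])
  y <- factor(sub$group, levels = c("healthy", "mci"))
  if (any(is.na(y))) stop("feature table has missing group labels")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  per_fold <- list(); preds <- list()
  for (k in seq_along(folds)) {
    fold <- folds[[k]]
    stopifnot(!fold$subject %in% sub$subject_id[fold$train])  # leakage audit
    ytr <- droplevels(y[fold$train])
    if (nlevels(ytr) < 2)
      stop("training fold for held-out subject ", fold$subject,
           " contains a single class; cannot fit a classifier")
    set.seed(derive_seed(seed, k, stream = 11L))
    rf <- randomForest::randomForest(x[fold$train, , drop = FALSE],
                                     y[fold$train], ntree = n_trees)
    cls <- predict(rf, x[fold$test, , drop = FALSE])
    prob <- predict(rf, x[fold$test, , drop = FALSE], type = "prob")[, "mci"]
    m <- metric_suite(y[fold$test], cls, average = average)
    per_fold[[k]] <- data.frame(subject = fold$subject,
                                n_epochs = length(fold$test),
                                accuracy = m$accuracy, f1 = m$f1,
                                recall = m$recall, precision = m$precision)
    preds[[k]] <- data.frame(subject = fold$subject,
                             truth = as.character(y[fold$test]),
                             pred = as.character(cls),
                             score_mci = as.numeric(prob),
                             stringsAsFactors = FALSE)
  }
  per_fold <- do.call(rbind, per_fold)
  preds <- do.call(rbind, preds)
  pooled <- metric_suite(preds$truth, preds$pred, scores = preds$score_mci,
                         average = average)
  structure(list(task = "classification", condition = condition,
                 per_fold = per_fold, fold_predictions = preds,
                 summary = sapply(c("accuracy", "f1", "recall", "precision"),
                                  function(mm) fold_summary(per_fold[[mm]])),
                 pooled = pooled),
            class = "metric_panel")
}

#' Leave-one-subject-out random-forest MoCA regression
#'
#' Same folding and forests as [classify_loso()], but predicting the
#' held-out subject's MoCA score from each epoch. Pooled r2, MSE, MAE and
#' MAPE are computed over all held-out epochs; the per-fold `median_error`
#' is the absolute difference between the median predicted score and the
#' subject's true score.
#'
#' @inheritParams classify_loso
#' @return A `metric_panel` with regression metrics.
#' @export
regress_loso <- function(features, condition = "ALL", n_trees = 200,
                         seed = 1L) {
  sub <- prepare_condition(features, condition)
  folds <- loso_folds(sub)
  x <- as.matrix(sub[, tda_feature_names()])
  y <- as.numeric(sub$moca)
  if (any(is.na(y))) stop("feature table has missing MoCA scores")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  per_fold <- list(); preds <- list()
  for (k in seq_along(folds)) {
    fold <- folds[[k]]
    stopifnot(!fold$subject %in% sub$subject_id[fold$train])
    set.seed(derive_seed(seed, k, stream = 12L))
    # small cohorts legitimately have few distinct MoCA values; silence the
    # forest's regression-vs-classification heuristic for that case only
    rf <- withCallingHandlers(
      randomForest::randomForest(x[fold$train, , drop = FALSE],
                                 y[fold$train], ntree = n_trees),
      warning = function(w) {
        if (grepl("five or fewer unique values", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    yhat <- predict(rf, x[fold$test, , drop = FALSE])
    truth <- y[fold$test][1]
    per_fold[[k]] <- data.frame(subject = fold$subject,
                                n_epochs = length(fold$test),
                                true_moca = truth,
                                median_pred = median(yhat),
                                median_error = abs(median(yhat) - truth),
                                mae = mean(abs(yhat - y[fold$test])),
                                mse = mean((yhat - y[fold$test])^2))
    preds[[k]] <- data.frame(subject = fold$subject, truth = y[fold$test],
                             pred = as.numeric(yhat),
                             stringsAsFactors = FALSE)
  }
  per_fold <- do.call(rbind, per_fold)
  preds <- do.call(rbind, preds)
  pooled <- metric_suite(preds$truth, preds$pred)
  structure(list(task = "regression", condition = condition,
                 per_fold = per_fold, fold_predictions = preds,
                 summary = sapply(c("median_error", "mae", "mse"),
                                  function(mm) fold_summary(per_fold[[mm]])),
                 pooled = pooled),
            class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, ...) {
  cat(sprintf("LOSO %s panel (%s), %d folds\n", x$task, x$condition,
              nrow(x$per_fold)))
  cat("pooled:", paste(sprintf("%s=%.4g", names(x$pooled),
                               unlist(x$pooled)), collapse = "  "), "\n")
  invisible(x)
}
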