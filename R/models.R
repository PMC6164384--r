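# Model harness: random forest, k-nearest neighbours and SVM learners
# behind one spec/fit/predict interface, with 10-fold cross-validation,
# OOB evaluation, 50:50 class rebalancing and SVM C tuning.

#' Specify a model
#'
#' Hyperparameter defaults follow the reference workflow: RF with 500
#' trees and `mtry = floor(sqrt(p))` (classification) or `floor(p/3)`
#' (regression); k-NN with `k = 10`, Euclidean distances and
#' inverse-distance neighbour weighting; SVM with RBF kernel,
#' `gamma = 1/p` and `C` to be tuned over 10--1000 (default grid
#' `c(10, 50, 100, 250, 500, 1000)`; `epsilon = 0.1` for regression).
#'
#' @param algorithm `"rf"`, `"knn"` or `"svm"`.
#' @param task `"classification"` or `"regression"`.
#' @param seed Integer seed (mandatory for rf; recorded for all).
#' @param n_trees,mtry RF forest size and per-split feature count
#'   (`mtry = NULL` means the task default, resolved at fit time).
#' @param k,knn_weight k-NN neighbour count and weighting
#'   (`"inverse_distance"` or `"uniform"`).
#' @param C,gamma,epsilon SVM cost, RBF width (`NULL` = `1/p`),
#'   regression tube half-width.
#' @param class_weights Optional named per-class weights (see
#'   [rebalance_weights()]); classification only.
#' @return A `model_spec`.
#' @export
model_spec <- function(algorithm = c("rf", "knn", "svm"),
                       task = c("classification", "regression"),
                       seed = 1L,
                       n_trees = 500L, mtry = NULL,
                       k = 10L, knn_weight = c("inverse_distance", "uniform"),
                       C = 10, gamma = NULL, epsilon = 0.1,
                       class_weights = NULL) {
  algorithm <- match.arg(algorithm)
  task <- match.arg(task)
  knn_weight <- match.arg(knn_weight)
  if (!is.null(class_weights) && task != "classification") {
    stop("class weights apply to classification only", call. = FALSE)
  }
  structure(list(algorithm = algorithm, task = task, seed = as.integer(seed),
                 n_trees = as.integer(n_trees), mtry = mtry,
                 k = as.integer(k), knn_weight = knn_weight,
                 C = C, gamma = gamma, epsilon = epsilon,
                 class_weights = class_weights),
            class = "model_spec")
}

#' 50:50 class rebalancing weights
#'
#' Per-class weights inversely proportional to class counts, normalized
#' so each class contributes the same total weight (and the mean sample
#' weight is 1).  Used to counter class imbalance: with counts (25, 49)
#' the active:inactive weight ratio is 49:25.
#'
#' @param class_counts Named vector of per-class counts (two classes,
#'   both non-empty).
#' @return Named numeric weights.
#' @examples
#' rebalance_weights(c(active = 25, inactive = 49))
#' @export
rebalance_weights <- function(class_counts) {
  stopifnot(length(class_counts) == 2)
  if (any(class_counts <= 0)) stop("empty class", call. = FALSE)
  w <- sum(class_counts) / (length(class_counts) * class_counts)
  stats::setNames(as.numeric(w), names(class_counts))
}

.as_class_factor <- function(y) {
  y <- as.factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("classification needs at least two classes",
                           call. = FALSE)
  y
}

.sample_weights <- function(y, class_weights) {
  if (is.null(class_weights)) return(rep(1, length(y)))
  missing_cls <- setdiff(levels(y), names(class_weights))
  if (length(missing_cls)) {
    stop("class_weights lacks: ", paste(missing_cls, collapse = ", "),
         call. = FALSE)
  }
  as.numeric(class_weights[as.character(y)])
}

#' Fit a model
#'
#' @param spec A [model_spec()].
#' @param X Numeric feature matrix (finite values).
#' @param y Target: factor (classification) or numeric (regression).
#' @return A `qsar_model` carrying the fitted state; RF models also hold
#'   `oob` (per-sample out-of-bag predictions/votes) and `importance`
#'   (permutation = mean decrease in accuracy / increase in MSE, plus
#'   impurity-based as secondary output).
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite", call. = FALSE)
  if (nrow(X) < 2) stop("need at least two samples", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)", call. = FALSE)
  classification <- spec$task == "classification"
  if (classification) y <- .as_class_factor(y)

  fitted <- switch(spec$algorithm,
    rf = .fit_rf(spec, X, y, classification),
    knn = list(X = X, y = y),
    svm = .fit_svm(spec, X, y, classification))
  structure(list(spec = spec, fitted = fitted,
                 levels = if (classification) levels(y) else NULL,
                 p = ncol(X), feature_names = colnames(X),
                 oob = fitted$oob, importance = fitted$importance),
            class = "qsar_model")
}

.fit_rf <- function(spec, X, y, classification) {
  mtry <- spec$mtry
  if (is.null(mtry)) {
    mtry <- if (classification) floor(sqrt(ncol(X))) else
      max(1, floor(ncol(X) / 3))
  }
  mtry <- max(1L, min(as.integer(mtry), ncol(X)))
  yv <- if (classification) as.numeric(y) - 1 else as.numeric(y)
  n_classes <- if (classification) nlevels(y) else 0L
  w <- if (classification) .sample_weights(y, spec$class_weights) else
    rep(1, nrow(X))
  set.seed(spec$seed)
  res <- .rf_fit_cpp(X, yv, n_classes, spec$n_trees, mtry,
                     if (classification) 1L else 5L, w, TRUE)
  oob <- if (classification) {
    votes <- res$oob_votes
    colnames(votes) <- levels(y)
    total <- rowSums(votes)
    pred <- factor(levels(y)[max.col(votes, ties.method = "first")],
                   levels = levels(y))
    pred[total == 0] <- NA
    list(votes = votes, prob = votes / pmax(total, 1), pred = pred)
  } else {
    pred <- ifelse(res$oob_cnt > 0, res$oob_sum / pmax(res$oob_cnt, 1),
                   NA_real_)
    list(pred = pred)
  }
  imp <- data.frame(
    feature = if (is.null(colnames(X))) sprintf("V%d", seq_len(ncol(X)))
              else colnames(X),
    permutation = res$importance_permutation,
    impurity = res$importance_impurity)
  list(trees = res$trees, mtry = mtry, oob = oob, importance = imp)
}

.fit_svm <- function(spec, X, y, classification) {
  gamma <- if (is.null(spec$gamma)) 1 / ncol(X) else spec$gamma
  if (classification) {
    if (nlevels(y) != 2) stop("svm supports two classes", call. = FALSE)
    # positive class = first level
    y_sign <- ifelse(y == levels(y)[1], 1, -1)
    class_C <- if (is.null(spec$class_weights)) NULL else
      spec$C * .sample_weights(y, spec$class_weights)
    fit <- .svc_fit(X, y_sign, spec$C, gamma, class_C)
  } else {
    fit <- .svr_fit(X, as.numeric(y), spec$C, gamma, spec$epsilon)
  }
  list(svm = fit)
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model> %s %s (p = %d)\n", x$spec$algorithm,
              x$spec$task, x$p))
  invisible(x)
}

.knn_predict <- function(model, X) {
  tr <- model$fitted$X
  y <- model$fitted$y
  k <- min(model$spec$k, nrow(tr))
  classification <- model$spec$task == "classification"
  lev <- model$levels
  n <- nrow(X)
  pred <- if (classification) character(n) else numeric(n)
  prob <- if (classification) matrix(0, n, length(lev),
                                     dimnames = list(NULL, lev))
  d2 <- outer(rowSums(X^2), rep(1, nrow(tr))) - 2 * X %*% t(tr) +
    outer(rep(1, n), rowSums(tr^2))
  d <- sqrt(pmax(d2, 0))
  for (i in seq_len(n)) {
    di <- d[i, ]
    exact <- which(di < 1e-12)
    if (length(exact)) {
      # zero-distance rule: exact matches short-circuit
      if (classification) {
        votes <- table(factor(y[exact], levels = lev)) / length(exact)
        prob[i, ] <- as.numeric(votes)
        pred[i] <- lev[which.max(votes)]
      } else {
        pred[i] <- mean(as.numeric(y[exact]))
      }
      next
    }
    nb <- order(di, seq_along(di))[seq_len(k)]
    w <- if (model$spec$knn_weight == "inverse_distance") 1 / di[nb] else
      rep(1, k)
    w <- w / sum(w)
    if (classification) {
      votes <- tapply(w, factor(y[nb], levels = lev), sum, default = 0)
      prob[i, ] <- as.numeric(votes)
      pred[i] <- lev[which.max(votes)]
    } else {
      pred[i] <- sum(w * as.numeric(y[nb]))
    }
  }
  if (classification) {
    list(prediction = factor(pred, levels = lev), probability = prob)
  } else {
    list(prediction = pred)
  }
}

#' Predict from a fitted model
#'
#' Classification returns the predicted factor plus a class-probability
#' matrix: the (weighted) vote fraction for each class (RF: fraction of
#' tree votes; k-NN: inverse-distance-weighted neighbour vote share;
#' SVM: a logistic squash `1/(1+exp(-f))` of the decision value, a
#' convention, not a calibrated probability).  Regression returns the
#' tree mean / weighted neighbour mean / SVR function value.
#'
#' @param object A `qsar_model`.
#' @param X Feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return List with `prediction` and (classification) `probability`.
#' @export
predict.qsar_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$p) {
    stop("dimension mismatch: model expects ", object$p, " features",
         call. = FALSE)
  }
  classification <- object$spec$task == "classification"
  lev <- object$levels
  if (object$spec$algorithm == "rf") {
    res <- .rf_predict_cpp(object$fitted$trees, X,
                           if (classification) length(lev) else 0L)
    if (classification) {
      votes <- res$votes
      colnames(votes) <- lev
      prob <- votes / rowSums(votes)
      pred <- factor(lev[max.col(votes, ties.method = "first")],
                     levels = lev)
      list(prediction = pred, probability = prob)
    } else {
      list(prediction = as.numeric(res$mean))
    }
  } else if (object$spec$algorithm == "knn") {
    .knn_predict(object, X)
  } else {
    f <- .svm_decision(object$fitted$svm, X)
    if (classification) {
      p_pos <- 1 / (1 + exp(-f))
      prob <- cbind(p_pos, 1 - p_pos)
      colnames(prob) <- lev
      pred <- factor(ifelse(f >= 0, lev[1], lev[2]), levels = lev)
      list(prediction = pred, probability = prob)
    } else {
      list(prediction = f)
    }
  }
}

# stratified (classification) or plain (regression) fold assignment
.make_folds <- function(y, folds, classification) {
  n <- length(y)
  assign_fold <- integer(n)
  if (classification) {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      idx <- idx[sample.int(length(idx))]
      assign_fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    assign_fold <- rep_len(seq_len(folds), n)[sample.int(n)]
  }
  assign_fold
}

#' k-fold cross-validation
#'
#' Stratified folds for classification (fold sizes differ by at most
#' one per class); deterministic under `seed`.  Metrics are pooled over
#' the held-out predictions of all folds.
#'
#' @param spec A [model_spec()].
#' @param X,y Data as for [fit_model()].
#' @param folds Number of folds (default 10, `2 <= folds <= n`).
#' @param seed Integer seed for fold assignment (and fold-model fits).
#' @param positive Positive class for the confusion matrix; default the
#'   first factor level.
#' @return List with `predictions` (per-sample held-out prediction),
#'   `fold` assignment, and `metrics` ([classification_report()] or
#'   [regression_report()]).
#' @export
cross_validate <- function(spec, X, y, folds = 10, seed = 1L,
                           positive = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- as.integer(folds)
  if (folds < 2) stop("need at least two folds", call. = FALSE)
  if (folds > n) stop("more folds than samples", call. = FALSE)
  classification <- spec$task == "classification"
  if (classification) y <- .as_class_factor(y)

  set.seed(seed)
  fold_id <- .make_folds(y, folds, classification)
  pred <- if (classification) {
    factor(rep(NA_character_, n), levels = levels(y))
  } else {
    numeric(n)
  }
  prob <- if (classification) matrix(NA_real_, n, nlevels(y),
                                     dimnames = list(NULL, levels(y)))
  for (f in seq_len(folds)) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    fold_spec <- spec
    fold_spec$seed <- spec$seed + f
    m <- fit_model(fold_spec, X[tr, , drop = FALSE], y[tr])
    out <- predict(m, X[te, , drop = FALSE])
    pred[te] <- out$prediction
    if (classification) prob[te, ] <- out$probability
  }
  metrics <- if (classification) {
    classification_report(confusion_counts(observed = y, predicted = pred,
                                           positive = positive))
  } else {
    regression_report(y, pred)
  }
  list(predictions = pred, probability = prob, fold = fold_id,
       metrics = metrics)
}

#' Evaluate a random forest out-of-bag
#'
#' @param model An RF `qsar_model`.
#' @param y The training target the model was fitted on.
#' @param positive Positive class; default first level.
#' @return [classification_report()] or [regression_report()] over the
#'   OOB predictions.
#' @export
oob_report <- function(model, y, positive = NULL) {
  stopifnot(inherits(model, "qsar_model"), model$spec$algorithm == "rf")
  if (model$spec$task == "classification") {
    y <- factor(y, levels = model$levels)
    ok <- !is.na(model$oob$pred)
    classification_report(confusion_counts(
      observed = y[ok], predicted = model$oob$pred[ok], positive = positive))
  } else {
    ok <- !is.na(model$oob$pred)
    regression_report(as.numeric(y)[ok], model$oob$pred[ok])
  }
}

#' Tune the SVM cost parameter by cross-validation
#'
#' Evaluates each grid value with [cross_validate()] (accuracy Q for
#' classification, RMSE for regression) and returns the best; ties go to
#' the smallest C.
#'
#' @param spec An SVM [model_spec()].
#' @param X,y Data.
#' @param grid Candidate C values; default `c(10, 50, 100, 250, 500,
#'   1000)` spanning the conventional 10--1000 range.
#' @param folds,seed Cross-validation controls.
#' @return List with `best_C`, `results` (per-C data.frame) and the
#'   winning `spec`.
#' @export
tune_c <- function(spec, X, y, grid = c(10, 50, 100, 250, 500, 1000),
                   folds = 10, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), spec$algorithm == "svm")
  if (!length(grid)) stop("empty C grid", call. = FALSE)
  grid <- sort(grid)
  classification <- spec$task == "classification"
  score <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- spec
    s$C <- grid[i]
    cv <- cross_validate(s, X, y, folds = folds, seed = seed)
    score[i] <- if (classification) cv$metrics$raw["q"] else
      -cv$metrics$rmse
  }
  best <- which.max(score)  # first max -> smallest C on ties
  best_spec <- spec
  best_spec$C <- grid[best]
  list(best_C = grid[best],
       results = data.frame(C = grid, score = score),
       spec = best_spec)
}

#' Save / load a fitted model bundle
#'
#' Versioned single-file bundle (RDS).
#'
#' @param model A `qsar_model`.
#' @param path Bundle path.
#' @return `path` invisibly / the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "qsar_model"))
  saveRDS(list(format = "nmrqsar-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "nmrqsar-model")) {
    stop("not a model bundle", call. = FALSE)
  }
  obj$model
}

#' Write predictions to CSV
#'
#' Columns: `sample_id`, `prediction` and, for classification, the
#' probability of the positive (first-level) class.
#'
#' @param predictions Result of [predict.qsar_model()].
#' @param sample_ids Sample identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(predictions, sample_ids, path) {
  df <- data.frame(sample_id = sample_ids,
                   prediction = as.character(predictions$prediction))
  if (!is.null(predictions$probability)) {
    df$probability <- predictions$probability[, 1]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
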