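## Classification layer: SVM (LIBSVM via e1071) and a one-dimensional
## threshold classifier, evaluated under repeated stratified k-fold
## cross-validation with nested (inner-CV) hyperparameter selection and
## leakage-free per-fold standardization.

#' Default SVM hyperparameter grid
#'
#' Kernel type (radial basis or polynomial) with three penalty and three
#' kernel-coefficient values each, optionally crossed with the window length
#' \code{n_sub}.
#'
#' @param kernels,cost,gamma candidate values.
#' @param n_sub optional candidate window lengths.
#' @return data frame with one row per configuration.
#' @export
svm_grid <- function(kernels = c("radial", "polynomial"),
                     cost = c(0.1, 1, 10), gamma = c(0.01, 0.1, 1),
                     n_sub = NULL) {
  g <- expand.grid(kernel = kernels, cost = cost, gamma = gamma,
                   stringsAsFactors = FALSE)
  if (!is.null(n_sub))
    g <- merge(g, data.frame(n_sub = n_sub), by = NULL)
  g
}

#' Train a binary SVM with a continuous decision score
#'
#' @param x standardized feature matrix.
#' @param y factor with two levels.
#' @param kernel \code{"radial"} or \code{"polynomial"}.
#' @param cost penalty parameter C.
#' @param gamma kernel coefficient.
#' @param positive the positive class (decision scores are oriented so that
#'   larger means more likely positive).
#' @return an object of class \code{heat_svm}.
#' @export
train_svm <- function(x, y, kernel = "radial", cost = 1, gamma = 0.1,
                      positive = "AFib") {
  y <- factor(y)
  if (nlevels(y) != 2L) stop_invalid("SVM training needs exactly two classes")
  m <- e1071::svm(x, y, kernel = kernel, cost = cost, gamma = gamma,
                  scale = FALSE)
  structure(list(model = m, positive = positive, levels = levels(y)),
            class = "heat_svm")
}

#' @export
predict.heat_svm <- function(object, newdata, ...) {
  p <- stats::predict(object$model, newdata, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  ## e1071 orients the decision value toward the first class in its colname
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  s <- as.numeric(dv[, 1])
  if (first != object$positive) s <- -s
  list(class = p, score = s)
}

#' Rank-based area under the ROC curve
#'
#' Equivalent to the trapezoidal ROC area (Wilcoxon statistic); ties in the
#' scores are handled by midranks.
#'
#' @param scores continuous decision scores (larger = more positive).
#' @param labels class labels.
#' @param positive positive class.
#' @return ROC area in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive = "AFib") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop_invalid("ROC area undefined with a single class")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from decision scores
#'
#' @param scores continuous decision scores.
#' @param labels class labels.
#' @param positive positive class (AFib by convention: sensitivity is AFib
#'   recall, specificity is AFlu recall).
#' @param threshold decision threshold on the scores.
#' @return list with \code{accuracy}, \code{roc_auc}, \code{sensitivity},
#'   \code{specificity}.
#' @export
evaluate_classifier <- function(scores, labels, positive = "AFib",
                                threshold = 0) {
  pos <- labels == positive
  pred <- scores > threshold
  list(accuracy = mean(pred == pos),
       roc_auc = roc_auc(scores, labels, positive),
       sensitivity = mean(pred[pos]),
       specificity = mean(!pred[!pos]))
}

## stratified fold assignment; errors when a class cannot reach every fold
stratified_folds <- function(y, k) {
  ids <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop_invalid(sprintf("class %s has fewer samples than folds", cl))
    ids[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  ids
}

## train + score one model spec on given train/test split (standardizes
## inside, so nothing leaks from the test rows)
fit_and_score <- function(x_tr, y_tr, x_te, model, cfg, positive) {
  sp <- suppressWarnings(fit_standardizer(x_tr))
  x_tr <- apply_standardizer(sp, x_tr)
  x_te <- apply_standardizer(sp, x_te)
  if (model == "svm") {
    m <- train_svm(x_tr, y_tr, kernel = cfg$kernel, cost = cfg$cost,
                   gamma = cfg$gamma, positive = positive)
    list(score = predict(m, x_te)$score, threshold = 0)
  } else if (model == "threshold") {
    ## one-dimensional threshold classifier on the first feature
    v_tr <- x_tr[, 1]
    mu_pos <- mean(v_tr[y_tr == positive]); mu_neg <- mean(v_tr[y_tr != positive])
    sgn <- if (mu_pos >= mu_neg) 1 else -1
    list(score = sgn * x_te[, 1], threshold = sgn * (mu_pos + mu_neg) / 2)
  } else if (model == "cnn") {
    m <- train_cnn(x_tr, y_tr == positive, dropout = cfg$dropout,
                   epochs = cfg$epochs %||% 100L)
    list(score = predict_cnn(m, x_te) - 0.5, threshold = 0)
  } else stop_invalid("unknown model")
}

#' Repeated stratified k-fold cross-validation
#'
#' Outer repeated stratified k-fold; when the hyperparameter grid has more
#' than one row, the configuration is chosen per outer fold by an inner
#' stratified cross-validation on the training folds only (grid-search CV).
#' Standardization parameters are always fitted on the respective training
#' rows.
#'
#' @param x feature matrix, or (when the grid carries an \code{n_sub}
#'   column) a named list of matrices keyed by \code{n_sub}.
#' @param y class labels (character or factor, two classes).
#' @param model \code{"svm"}, \code{"threshold"} (one-dimensional, first
#'   feature) or \code{"cnn"}.
#' @param grid hyperparameter data frame (see \code{\link{svm_grid}});
#'   ignored for the threshold model.
#' @param folds,repeats outer CV layout.
#' @param seed RNG seed for the fold assignments.
#' @param inner_folds folds of the inner selection CV.
#' @param positive positive class.
#' @return an object of class \code{heat_cv}: \code{per_fold} data frame and
#'   aggregate \code{mean_accuracy}, \code{sd_accuracy}, \code{mean_roc},
#'   \code{sd_roc}, \code{sensitivity}, \code{specificity}, plus the chosen
#'   configurations.
#' @export
cross_validate <- function(x, y, model = c("svm", "threshold", "cnn"),
                           grid = NULL, folds = 10, repeats = 10, seed = 1,
                           inner_folds = 3, positive = "AFib") {
  model <- match.arg(model)
  y <- as.character(y)
  if (length(unique(y)) != 2L) stop_invalid("need exactly two classes")
  by_nsub <- is.list(x) && !is.data.frame(x) && !is.matrix(x)
  if (is.null(grid)) {
    grid <- switch(model,
      svm = svm_grid(),
      threshold = data.frame(dummy = 0),
      cnn = data.frame(dropout = c(0.1, 0.2, 0.3)))
  }
  if (by_nsub && !("n_sub" %in% names(grid)))
    stop_invalid("list-valued x needs an n_sub column in the grid")
  get_x <- function(cfg) if (by_nsub) x[[as.character(cfg$n_sub)]] else x
  set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    fold_id <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      te <- which(fold_id == f); tr <- which(fold_id != f)
      ## inner grid-search CV on the training folds only
      best_cfg <- grid[1, , drop = FALSE]
      if (nrow(grid) > 1L) {
        inner_id <- stratified_folds(y[tr], inner_folds)
        acc <- vapply(seq_len(nrow(grid)), function(g) {
          cfg <- grid[g, , drop = FALSE]
          xg <- get_x(cfg)
          mean(vapply(seq_len(inner_folds), function(fi) {
            iv <- tr[inner_id == fi]; it <- tr[inner_id != fi]
            fs <- fit_and_score(xg[it, , drop = FALSE], y[it],
                                xg[iv, , drop = FALSE], model, cfg, positive)
            mean((fs$score > fs$threshold) == (y[iv] == positive))
          }, numeric(1)))
        }, numeric(1))
        best_cfg <- grid[which.max(acc), , drop = FALSE]
      }
      xg <- get_x(best_cfg)
      fs <- fit_and_score(xg[tr, , drop = FALSE], y[tr],
                          xg[te, , drop = FALSE], model, best_cfg, positive)
      met <- evaluate_classifier(fs$score, y[te], positive, fs$threshold)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(repeat_i = rep_i, fold = f, accuracy = met$accuracy,
                   roc_auc = met$roc_auc, sensitivity = met$sensitivity,
                   specificity = met$specificity), best_cfg)
    }
  }
  per_fold <- do.call(rbind, rows)
  structure(list(
    per_fold = per_fold, model = model, folds = folds, repeats = repeats,
    mean_accuracy = mean(per_fold$accuracy),
    sd_accuracy = stats::sd(per_fold$accuracy),
    mean_roc = mean(per_fold$roc_auc),
    sd_roc = stats::sd(per_fold$roc_auc),
    sensitivity = mean(per_fold$sensitivity),
    specificity = mean(per_fold$specificity)), class = "heat_cv")
}

#' @export
print.heat_cv <- function(x, ...) {
  cat(sprintf("%s, %d x stratified %d-fold CV\n", toupper(x$model),
              x$repeats, x$folds))
  cat(sprintf("  accuracy %.2f%% +/- %.2f%%, ROC area %.3f +/- %.3f\n",
              100 * x$mean_accuracy, 100 * x$sd_accuracy,
              x$mean_roc, x$sd_roc))
  cat(sprintf("  sensitivity %.2f%%, specificity %.2f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
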