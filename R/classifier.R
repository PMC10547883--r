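#' Fit a cross-validated ridge classifier on pooled kernel features
#'
#' One-vs-all ridge regression on +/-1 indicator targets, the linear
#' classifier recommended for random-kernel features at this data scale.
#' Features are standardized with training statistics (mean/sd per column;
#' constant columns get scale 1), the regularization strength is selected
#' from 10 log-spaced values on `[1e-3, 1e3]` by stratified 5-fold
#' cross-validation of the squared target error, and the final model is
#' refit on all training data at the chosen strength. When any class has
#' fewer members than the fold count the selection falls back to the
#' closed-form generalized leave-one-out error. All linear algebra runs
#' through a single SVD so the full alpha grid costs one decomposition.
#'
#' @param features numeric trials x features matrix (e.g. from
#'   [rocket_transform()] or [minirocket_features()]).
#' @param labels subject id per trial.
#' @param seed integer seed for the fold assignment.
#' @param alphas regularization grid; default `10^seq(-3, 3, length.out = 10)`.
#' @param n_folds folds for cross-validation (default 5).
#' @return an object of class `fp_classifier`.
#' @export
fit_classifier <- function(features, labels, seed,
                           alphas = 10^seq(-3, 3, length.out = 10),
                           n_folds = 5L) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) invalid_input("`labels` must match feature rows.")
  class_list <- sort(unique(labels))
  if (length(class_list) < 2L) invalid_input("need at least 2 classes.")
  counts <- table(labels)

  center <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl <= 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")

  y <- matrix(-1, nrow(x), length(class_list))
  y[cbind(seq_len(nrow(x)), match(labels, class_list))] <- 1

  use_loocv <- min(counts) < n_folds
  if (use_loocv) {
    cv_err <- ridge_gcv_errors(xs, y, alphas)
  } else {
    folds <- with_seed(seed, stratified_folds(labels, n_folds))
    cv_err <- numeric(length(alphas))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- ridge_path(xs[tr, , drop = FALSE], y[tr, , drop = FALSE], alphas)
      for (a in seq_along(alphas)) {
        pred <- xs[!tr, , drop = FALSE] %*% fit$coef[[a]] +
          matrix(fit$intercept, sum(!tr), ncol(y), byrow = TRUE)
        cv_err[a] <- cv_err[a] + sum((y[!tr, , drop = FALSE] - pred)^2)
      }
    }
  }
  alpha <- alphas[which.min(cv_err)]

  final <- ridge_path(xs, y, alpha)
  structure(
    list(class_list = class_list, coef = final$coef[[1L]],
         intercept = final$intercept, alpha = alpha,
         center = center, scale = scl,
         alphas = alphas, cv_errors = cv_err,
         cv_method = if (use_loocv) "gloo" else "kfold",
         n_train = nrow(x)),
    class = "fp_classifier"
  )
}

stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# Ridge with unpenalized intercept on column-centred x: one SVD serves every
# alpha. Returns per-alpha coefficient matrices plus the shared intercept.
ridge_path <- function(xs, y, alphas) {
  b0 <- colMeans(y)
  yc <- sweep(y, 2L, b0)
  sv <- svd(xs)
  uty <- crossprod(sv$u, yc)
  coef <- lapply(alphas, function(a) {
    sv$v %*% (uty * (sv$d / (sv$d^2 + a)))
  })
  list(coef = coef, intercept = b0)
}

# Closed-form leave-one-out squared error of ridge, per alpha.
ridge_gcv_errors <- function(xs, y, alphas) {
  n <- nrow(xs)
  b0 <- colMeans(y)
  yc <- sweep(y, 2L, b0)
  sv <- svd(xs)
  uty <- crossprod(sv$u, yc)
  vapply(alphas, function(a) {
    shrink <- sv$d^2 / (sv$d^2 + a)
    fitted <- sv$u %*% (uty * shrink)
    h <- rowSums(sweep(sv$u^2, 2L, shrink, "*")) + 1 / n
    h <- pmin(h, 1 - 1e-10)
    sum(((yc - fitted) / (1 - h))^2)
  }, numeric(1))
}

#' @export
print.fp_classifier <- function(x, ...) {
  cat(sprintf("<fp_classifier> %d classes, %d features, alpha = %g (%s CV)\n",
              length(x$class_list), length(x$center), x$alpha, x$cv_method))
  invisible(x)
}

#' Predict subject labels (or scores) for new trials
#'
#' @param object an [fit_classifier()] model.
#' @param features feature matrix with the training feature dimension.
#' @param type `"class"` for labels, `"score"` for the per-class score matrix.
#' @param ... unused.
#' @return character vector of predicted subject ids, or a score matrix.
#'   Score ties are broken toward the earlier class in sorted id order.
#' @export
predict.fp_classifier <- function(object, features, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- as.matrix(features)
  if (nrow(x) == 0L) {
    return(if (type == "class") character(0) else
      matrix(0, 0L, length(object$class_list),
             dimnames = list(NULL, object$class_list)))
  }
  if (ncol(x) != length(object$center)) {
    invalid_input(sprintf("feature dimension %d does not match model (%d).",
                          ncol(x), length(object$center)))
  }
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  scores <- xs %*% object$coef +
    matrix(object$intercept, nrow(x), length(object$intercept), byrow = TRUE)
  colnames(scores) <- object$class_list
  if (type == "score") return(scores)
  object$class_list[max.col(scores, ties.method = "first")]
}

#' Classification metrics with macro averaging
#'
#' Computes accuracy plus per-class true positives, false positives and
#' false negatives, and from them precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and `F1 = 2 PR/(P+R)`. Macro values are unweighted means
#' over classes, so every subject counts equally. A class that is never
#' predicted and has no true positives gets precision (and hence F1) 0,
#' penalizing never-predicted classes in the macro average; the same 0
#' convention applies to recall of a class absent from the truth.
#'
#' @param y_true true subject ids.
#' @param y_pred predicted subject ids.
#' @param class_list classes to evaluate over; defaults to the sorted union.
#' @return an object of class `fp_metrics`.
#' @export
compute_metrics <- function(y_true, y_pred, class_list = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    invalid_input("`y_true` and `y_pred` must have equal length.")
  }
  if (is.null(class_list)) class_list <- sort(unique(c(y_true, y_pred)))
  if (!all(y_pred %in% class_list) || !all(y_true %in% class_list)) {
    invalid_input("labels outside `class_list`.")
  }
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  per_class <- tibble::tibble(
    class = class_list,
    tp = vapply(class_list, function(cl) sum(y_true == cl & y_pred == cl),
                numeric(1), USE.NAMES = FALSE),
    fp = vapply(class_list, function(cl) sum(y_true != cl & y_pred == cl),
                numeric(1), USE.NAMES = FALSE),
    fn = vapply(class_list, function(cl) sum(y_true == cl & y_pred != cl),
                numeric(1), USE.NAMES = FALSE)
  )
  per_class$precision <- safe_div(per_class$tp, per_class$tp + per_class$fp)
  per_class$recall <- safe_div(per_class$tp, per_class$tp + per_class$fn)
  per_class$f1 <- safe_div(2 * per_class$precision * per_class$recall,
                           per_class$precision + per_class$recall)
  structure(
    list(accuracy = if (length(y_true)) mean(y_true == y_pred) else NA_real_,
         macro_precision = mean(per_class$precision),
         macro_recall = mean(per_class$recall),
         macro_f1 = mean(per_class$f1),
         per_class = per_class,
         n_test = length(y_true)),
    class = "fp_metrics"
  )
}

#' @export
print.fp_metrics <- function(x, ...) {
  cat(sprintf(
    "<fp_metrics> n = %d: accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
    x$n_test, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  invisible(x)
}
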