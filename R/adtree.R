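#' Fit an alternating decision tree
#'
#' An alternating decision tree (ADTree) is a boosted classifier whose
#' model alternates decision nodes (a threshold test on one attribute)
#' and real-valued prediction nodes; an instance's classification score
#' is the sum of the prediction values on all paths it satisfies, and its
#' class is the sign of that score.  Each boosting round adds the
#' (precondition, test) pair minimizing the Z-criterion
#' \deqn{Z = 2\left(\sqrt{W_+(c_1 \wedge c_2) W_-(c_1 \wedge c_2)} +
#'   \sqrt{W_+(c_1 \wedge \neg c_2) W_-(c_1 \wedge \neg c_2)}\right) +
#'   W(\neg c_1)}
#' with prediction values \eqn{a = \tfrac12 \ln((W_+ + 1)/(W_- + 1))}
#' (+1 smoothing) and multiplicative weight updates \eqn{e^{-y a}}.
#' Candidate thresholds are the midpoints between consecutive distinct
#' attribute values in the training data; ties in Z are broken
#' deterministically (earlier path, then earlier attribute, then smaller
#' threshold).
#'
#' @param x numeric matrix or data.frame of attributes (instances in
#'   rows); column names are retained in the model.
#' @param y class labels: a two-level factor (or character) or a vector
#'   in \{-1, +1\}.  Both classes must be present.
#' @param rounds number of boosting rounds, i.e. splitter rules
#'   (default 10).
#' @param positive the label mapped to score `> 0`; default
#'   `"inclusion"` when present among the levels, otherwise the first
#'   level.
#' @return object of class `adtree`: the root prediction value, the rule
#'   list (precondition path, attribute, threshold, left/right prediction
#'   values), the attribute names and the class labels.
#' @seealso [predict.adtree()], [adtree_cv()]
#' @examples
#' set.seed(7)
#' x <- matrix(rnorm(200), ncol = 2)
#' y <- ifelse(x[, 1] + rnorm(100, sd = 0.3) > 0, "inclusion", "skipping")
#' fit <- adtree(x, y, rounds = 5)
#' table(predict(fit, x)$class, y)
#' @export
adtree <- function(x, y, rounds = 10, positive = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  if (is.numeric(y) && all(y %in% c(-1, 1))) {
    classes <- c("-1", "1")
    yi <- as.integer(y)
    pos_label <- "1"; neg_label <- "-1"
  } else {
    y <- factor(y)
    if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
    lv <- levels(y)
    if (is.null(positive)) {
      positive <- if ("inclusion" %in% lv) "inclusion" else lv[1]
    }
    if (!positive %in% lv) stop("positive label not among levels")
    pos_label <- positive
    neg_label <- setdiff(lv, positive)[1]
    yi <- ifelse(y == positive, 1L, -1L)
    classes <- lv
  }
  if (length(unique(yi)) < 2) stop("both classes must be present")
  if (nrow(x) != length(yi)) stop("x and y sizes differ")
  fit <- adtree_train_cpp(x, yi, as.integer(rounds))
  structure(
    list(root = fit$root,
         rules = data.frame(path = fit$rule_path,
                            attribute = colnames(x)[fit$rule_attr],
                            attr_index = fit$rule_attr,
                            threshold = fit$rule_threshold,
                            left = fit$rule_left,
                            right = fit$rule_right),
         attributes = colnames(x),
         classes = classes,
         positive = pos_label, negative = neg_label,
         rounds = rounds),
    class = "adtree")
}

#' Predict with an alternating decision tree
#'
#' @param object fitted [adtree()] model.
#' @param newdata matrix or data.frame with (at least) the model's
#'   attribute columns; matched by name when available.
#' @param ... unused.
#' @return list with `score` (real-valued margins) and `class` (the
#'   positive label when `score > 0`, the negative label otherwise, ties
#'   going to the negative class).
#' @export
predict.adtree <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (!is.null(colnames(x)) && !is.null(object$attributes) &&
      all(object$attributes %in% colnames(x))) {
    x <- x[, object$attributes, drop = FALSE]
  }
  score <- adtree_score_cpp(x, object$root,
                            object$rules$path,
                            object$rules$attr_index,
                            object$rules$threshold,
                            object$rules$left,
                            object$rules$right)
  cls <- ifelse(score > 0, object$positive, object$negative)
  list(score = score, class = cls)
}

#' @export
print.adtree <- function(x, ...) {
  cat(sprintf("alternating decision tree: %d rules, root = %+.4f\n",
              nrow(x$rules), x$root))
  cat(sprintf("positive class (score > 0): %s\n", x$positive))
  if (nrow(x$rules) > 0) {
    r <- x$rules
    for (i in seq_len(nrow(r))) {
      cat(sprintf("  [%2d] (path %d) %s < %.4g ? %+.3f : %+.3f\n",
                  i, r$path[i], r$attribute[i], r$threshold[i],
                  r$left[i], r$right[i]))
    }
  }
  invisible(x)
}

#' @export
summary.adtree <- function(object, ...) {
  cat(sprintf("ADTree with %d boosting rounds over %d attributes\n",
              nrow(object$rules), length(object$attributes)))
  used <- unique(object$rules$attribute)
  cat("attributes used:", paste(used, collapse = ", "), "\n")
  invisible(object)
}

#' Serialize / restore an ADTree model as JSON
#'
#' @param model fitted [adtree()] model.
#' @param path output path.
#' @return `path` invisibly (`write_adtree`); an `adtree`
#'   (`read_adtree`).
#' @export
write_adtree <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_adtree
#' @export
read_adtree <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$rules <- as.data.frame(m$rules)
  class(m) <- "adtree"
  m
}

#' Stratified cross-validation of the ADTree classifier
#'
#' Splits the events into `k` stratified folds so that every event is
#' predicted exactly once, trains an [adtree()] on each training portion,
#' and pools the held-out predictions.  The ROC area is the rank
#' (Mann-Whitney) statistic of the pooled scores, averaged over the two
#' class-wise curves weighted by class support (for two classes the two
#' curves have the same area); precision and recall are class-weighted
#' averages at the score-zero decision threshold.
#'
#' @param x numeric matrix (instances by attributes).
#' @param labels two-class labels.
#' @param k folds (default 10).
#' @param rounds boosting rounds per fold model (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param positive see [adtree()].
#' @return object of class `adtree_cv`: per-event `score`, `predicted`
#'   and `label`, the confusion matrix, `roc_area`, `precision`,
#'   `recall`, `accuracy` and `n_correct`.
#' @export
adtree_cv <- function(x, labels, k = 10, rounds = 10, seed = 1L,
                      positive = NULL) {
  labels <- factor(labels)
  x <- as.matrix(x)
  fold_id <- stratified_folds(labels, k, seed)
  score <- numeric(nrow(x))
  predicted <- character(nrow(x))
  for (f in seq_len(k)) {
    tr <- fold_id != f
    fit <- adtree(x[tr, , drop = FALSE], labels[tr], rounds = rounds,
                  positive = positive)
    pr <- predict(fit, x[!tr, , drop = FALSE])
    score[!tr] <- pr$score
    predicted[!tr] <- pr$class
  }
  pos <- if (!is.null(positive)) positive else
    if ("inclusion" %in% levels(labels)) "inclusion" else levels(labels)[1]
  res <- cv_metrics(score, predicted, labels, pos)
  res$fold <- fold_id
  class(res) <- "adtree_cv"
  res
}

# Pooled-prediction metrics shared by adtree_cv and the pipeline.
cv_metrics <- function(score, predicted, labels, positive) {
  labels <- factor(labels)
  neg <- setdiff(levels(labels), positive)[1]
  confusion <- table(predicted = factor(predicted, levels(labels)),
                     truth = labels)
  n_correct <- sum(diag(confusion))
  # Mann-Whitney AUC with tie correction
  is_pos <- labels == positive
  r <- rank(score)
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # class-weighted precision / recall at the zero-score threshold
  prec_rec <- vapply(levels(labels), function(cl) {
    tp <- sum(predicted == cl & labels == cl)
    prec <- if (sum(predicted == cl) == 0) 0 else tp / sum(predicted == cl)
    rec <- tp / sum(labels == cl)
    c(prec, rec)
  }, numeric(2))
  wts <- as.numeric(table(labels)[levels(labels)]) / length(labels)
  list(score = score, predicted = predicted, label = labels,
       confusion = confusion,
       roc_area = auc,
       precision = sum(prec_rec[1, ] * wts),
       recall = sum(prec_rec[2, ] * wts),
       accuracy = n_correct / length(labels),
       n_correct = n_correct,
       positive = positive, negative = neg)
}

#' @export
print.adtree_cv <- function(x, ...) {
  cat("stratified cross-validation of the ADTree classifier\n")
  cat(sprintf("  events: %d   correctly labeled: %d (%.2f%%)\n",
              length(x$label), x$n_correct, 100 * x$accuracy))
  cat(sprintf("  ROC area %.3f   precision %.3f   recall %.3f\n",
              x$roc_area, x$precision, x$recall))
  print(x$confusion)
  invisible(x)
}
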