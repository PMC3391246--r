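# Deterministic k-nearest-neighbor classifier: Euclidean distance, majority
# vote, distance ties by ascending training index, vote ties by smallest
# class label.
knn_predict <- function(train, train_labels, test, k = 5L) {
  k <- min(as.integer(k), nrow(train))
  pred <- integer(nrow(test))
  for (i in seq_len(nrow(test))) {
    d <- sqrt(colSums((t(train) - test[i, ])^2))
    nb <- order(d, method = "radix")[seq_len(k)]
    votes <- table(train_labels[nb])
    top <- names(votes)[votes == max(votes)]
    pred[i] <- min(as.integer(top))
  }
  pred
}

# Stratified fold assignment: within each class, indices are shuffled under
# the seed and dealt round-robin, so fold class proportions match the data.
make_folds <- function(labels, folds, seed = NULL, stratified = TRUE) {
  n <- length(labels)
  if (!is.null(seed)) set.seed(seed)
  assign <- integer(n)
  if (stratified) {
    for (t in unique(labels)) {
      idx <- which(labels == t)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    assign[sample.int(n)] <- rep_len(seq_len(folds), n)
  }
  assign
}

#' Cross-validated classification accuracy on selected features
#'
#' Restricts the dataset to the given feature columns, splits samples into
#' stratified k folds under the seed, trains the chosen classifier on each
#' training portion and reports per-fold and mean accuracy on the held-out
#' fold. Classifiers: \code{"knn"} (Euclidean, majority vote, deterministic
#' smallest-label tie-break) and \code{"svm_linear"}
#' (\code{\link[e1071]{svm}} with a linear kernel and library defaults).
#'
#' Feature selection is performed by the caller, outside this function. When
#' the features were selected on the full dataset the resulting accuracy is
#' optimistically biased (selection sees the test folds); use
#' \code{\link{cv_accuracy_nested}} for a leakage-free protocol.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @param selected integer vector of feature column indices to use.
#' @param folds number of folds (default 5); with stratification it must not
#'   exceed the smallest class size.
#' @param classifier \code{"knn"} or \code{"svm_linear"}.
#' @param knn_k neighbor count for KNN (default 5).
#' @param seed RNG seed controlling fold assignment.
#' @param stratified stratify folds by class (default \code{TRUE}).
#' @return List of class \code{eval_report}: \code{mean_accuracy},
#'   \code{per_fold}, \code{selected}, \code{classifier}, \code{folds}.
#' @export
cv_accuracy <- function(ds, selected, folds = 5L,
                        classifier = c("knn", "svm_linear"),
                        knn_k = 5L, seed = NULL, stratified = TRUE) {
  stopifnot(inherits(ds, "labeled_dataset"))
  classifier <- match.arg(classifier)
  selected <- as.integer(selected)
  if (!length(selected)) stop("empty feature selection")
  if (any(selected < 1L | selected > ds$m)) stop("feature index out of range")
  folds <- as.integer(folds)
  if (folds < 2L) stop("'folds' must be >= 2")
  if (stratified && folds > min(table(ds$labels)))
    stop("'folds' exceeds the smallest class size")

  x <- ds$values[, selected, drop = FALSE]
  y <- ds$labels
  assign <- make_folds(y, folds, seed, stratified)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- assign == f
    pred <- fit_predict(x[!te, , drop = FALSE], y[!te],
                        x[te, , drop = FALSE], classifier, knn_k)
    acc[f] <- mean(pred == y[te])
  }
  structure(list(mean_accuracy = mean(acc), per_fold = acc,
                 selected = selected, classifier = classifier, folds = folds),
            class = "eval_report")
}

fit_predict <- function(xtr, ytr, xte, classifier, knn_k) {
  if (classifier == "knn") {
    knn_predict(xtr, ytr, xte, knn_k)
  } else {
    fit <- e1071::svm(xtr, factor(ytr), kernel = "linear", scale = FALSE)
    as.integer(as.character(stats::predict(fit, xte)))
  }
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%d-fold CV accuracy (%s, %d features): %.4f\n",
              x$folds, x$classifier, length(x$selected), x$mean_accuracy))
  cat("per fold:", paste(sprintf("%.4f", x$per_fold), collapse = " "), "\n")
  invisible(x)
}

#' Leakage-free cross-validation with selection inside each fold
#'
#' Re-runs the feature selector on every training portion, so the held-out
#' fold never influences which features are evaluated. This is the
#' recommended protocol when the accuracy estimate itself is the object of
#' interest.
#'
#' @inheritParams cv_accuracy
#' @param selector function taking a \code{\link{labeled_dataset}} and
#'   returning feature indices, e.g.
#'   \code{function(d) rank_features(cscore(d))[1:10]}.
#' @return An \code{eval_report} (see \code{\link{cv_accuracy}});
#'   \code{selected} holds the per-fold selections as a list.
#' @export
cv_accuracy_nested <- function(ds, selector, folds = 5L,
                               classifier = c("knn", "svm_linear"),
                               knn_k = 5L, seed = NULL, stratified = TRUE) {
  stopifnot(inherits(ds, "labeled_dataset"), is.function(selector))
  classifier <- match.arg(classifier)
  folds <- as.integer(folds)
  if (stratified && folds > min(table(ds$labels)))
    stop("'folds' exceeds the smallest class size")
  assign <- make_folds(ds$labels, folds, seed, stratified)
  acc <- numeric(folds)
  sel_list <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- assign == f
    dtr <- labeled_dataset(ds$values[!te, , drop = FALSE],
                           ds$labels[!te], feature_ids = ds$feature_ids,
                           sample_ids = ds$sample_ids[!te])
    sel <- as.integer(selector(dtr))
    sel_list[[f]] <- sel
    pred <- fit_predict(ds$values[!te, sel, drop = FALSE], ds$labels[!te],
                        ds$values[te, sel, drop = FALSE], classifier, knn_k)
    acc[f] <- mean(pred == ds$labels[te])
  }
  structure(list(mean_accuracy = mean(acc), per_fold = acc,
                 selected = sel_list, classifier = classifier, folds = folds),
            class = "eval_report")
}

#' Single-feature discrimination AUC
#'
#' Area under the ROC curve when a feature's raw values rank one class
#' against the rest, computed by the tie-corrected Mann-Whitney statistic and
#' folded to \code{max(AUC, 1 - AUC)}: a feature whose low values mark the
#' positive class discriminates just as well as one whose high values do, so
#' direction is ignored. Invariant under any strictly monotone transform of
#' the feature.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @param feature feature column index.
#' @param positive_class encoded class label (0-based) treated as positive;
#'   default 1 (the natural choice for two classes).
#' @return AUC in [0.5, 1].
#' @export
feature_auc <- function(ds, feature, positive_class = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  feature <- as.integer(feature)
  if (feature < 1L || feature > ds$m) stop("feature index out of range")
  pos <- ds$labels == positive_class
  n1 <- sum(pos)
  n0 <- ds$n - n1
  if (n1 == 0L || n0 == 0L)
    stop("positive class absent or covers all samples")
  r <- rank(ds$values[, feature])  # midranks: tie-corrected U
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(auc, 1 - auc)
}
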