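test_that("CV accuracy is 1 on a trivially separable feature", {
  synth <- make_dataset(n_samples = 60, n_informative = 1, n_noise = 4,
                        delta = 8, seed = 310)
  rep5 <- cv_accuracy(synth$dataset, selected = 1L, seed = 1)
  expect_equal(rep5$mean_accuracy, 1)
  expect_equal(rep5$per_fold, rep(1, 5))
  expect_equal(rep5$mean_accuracy, mean(rep5$per_fold))

  repsvm <- cv_accuracy(synth$dataset, selected = 1L, seed = 1,
                        classifier = "svm_linear")
  expect_equal(repsvm$mean_accuracy, 1)
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(320)
  accs <- replicate(15, {
    x <- matrix(rnorm(40 * 5), 40, 5)
    ds <- labeled_dataset(x, sample(rep(0:1, 20)))
    cv_accuracy(ds, 1:5, seed = sample.int(1e6, 1))$mean_accuracy
  })
  # mean over seeds near 1/p = 0.5
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("fold loop reproduces an independent re-implementation", {
  set.seed(330)
  ds <- random_dataset(30, 3, 2)
  got <- cv_accuracy(ds, 1:3, folds = 3, knn_k = 3, seed = 99)
  # identical across runs
  again <- cv_accuracy(ds, 1:3, folds = 3, knn_k = 3, seed = 99)
  expect_identical(got$per_fold, again$per_fold)

  # independent fold loop: same stratified assignment rule, scanning KNN
  set.seed(99)
  assign <- integer(ds$n)
  for (t in unique(ds$labels)) {
    idx <- which(ds$labels == t)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(1:3, length(idx))
  }
  acc <- numeric(3)
  for (f in 1:3) {
    te <- which(assign == f)
    tr <- which(assign != f)
    correct <- 0L
    for (i in te) {
      d <- sqrt(rowSums((ds$values[tr, , drop = FALSE] -
                           matrix(ds$values[i, ], length(tr), 3,
                                  byrow = TRUE))^2))
      nb <- tr[order(d, tr)[1:3]]
      votes <- table(ds$labels[nb])
      pred <- min(as.integer(names(votes)[votes == max(votes)]))
      if (pred == ds$labels[i]) correct <- correct + 1L
    }
    acc[f] <- correct / length(te)
  }
  expect_equal(got$per_fold, acc)
})

test_that("CV guards fold counts and empty selections", {
  ds <- labeled_dataset(matrix(rnorm(12), 6, 2), c(0, 0, 0, 0, 1, 1))
  expect_error(cv_accuracy(ds, 1L, folds = 3), "smallest class")
  expect_error(cv_accuracy(ds, integer(0)), "empty")
  expect_error(cv_accuracy(ds, 5L, folds = 2), "out of range")
})

test_that("nested CV re-selects per fold and stays honest on pure noise", {
  set.seed(340)
  x <- matrix(rnorm(60 * 30), 60, 30)
  ds <- labeled_dataset(x, rep(0:1, 30))
  sel10 <- function(d) rank_features(cscore(d))[1:5]
  nested <- cv_accuracy_nested(ds, sel10, folds = 5, seed = 3)
  expect_length(nested$selected, 5)
  expect_true(all(vapply(nested$selected, length, 1L) == 5))
  # pure noise: leakage-free estimate must hover near chance
  expect_lt(nested$mean_accuracy, 0.75)
})

test_that("feature AUC matches hand cases and the pair-count oracle", {
  # all positives above all negatives
  ds <- labeled_dataset(cbind(f = c(1, 2, 3, 7, 8, 9)),
                        c(0, 0, 0, 1, 1, 1))
  expect_equal(feature_auc(ds, 1), 1)

  # identical class distributions: exchangeable, AUC = 0.5
  ds2 <- labeled_dataset(cbind(f = c(1, 2, 3, 1, 2, 3)),
                         c(0, 0, 0, 1, 1, 1))
  expect_equal(feature_auc(ds2, 1), 0.5)

  # hand case with one tie, against the exhaustive pair-count rule:
  # AUC = (#(pos > neg) + 0.5 #(pos == neg)) / (n1 * n0)
  v <- c(1, 4, 2, 4, 5, 7)
  y <- c(0, 0, 0, 1, 1, 1)
  ds3 <- labeled_dataset(cbind(f = v), y)
  pairs <- expand.grid(pos = v[y == 1], neg = v[y == 0])
  auc_oracle <- (sum(pairs$pos > pairs$neg) +
                   0.5 * sum(pairs$pos == pairs$neg)) / (3 * 3)
  expect_equal(feature_auc(ds3, 1), max(auc_oracle, 1 - auc_oracle))
  expect_equal(feature_auc(ds3, 1), 8.5 / 9)
})

test_that("feature AUC is direction-folded and monotone-invariant", {
  set.seed(350)
  ds <- random_dataset(30, 4, 2)
  for (j in 1:4) {
    a <- feature_auc(ds, j)
    expect_gte(a, 0.5)
    # flipping the feature's sign leaves the folded AUC unchanged
    dsf <- labeled_dataset(-ds$values, ds$labels)
    expect_equal(feature_auc(dsf, j), a)
    # strictly monotone transform leaves it unchanged
    dsm <- labeled_dataset(exp(ds$values), ds$labels)
    expect_equal(feature_auc(dsm, j), a)
  }
})

test_that("feature AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(360)
  ds <- random_dataset(40, 3, 2)
  for (j in 1:3) {
    ref <- suppressMessages(
      as.numeric(pROC::auc(ds$labels, ds$values[, j], direction = "auto")))
    expect_equal(feature_auc(ds, j), max(ref, 1 - ref))
  }
})
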