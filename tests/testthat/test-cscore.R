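test_that("centroids are per-class feature means", {
  ds <- labeled_dataset(cbind(f = c(0, 0, 2, 2)), c(0, 0, 1, 1))
  expect_equal(unname(compute_centroids(ds)), matrix(c(0, 2), 1))

  # singleton class: centroid is the sample itself
  ds2 <- labeled_dataset(cbind(f = c(1, 3, 7)), c(0, 0, 1))
  expect_equal(unname(compute_centroids(ds2)[1, ]), c(2, 7))

  set.seed(21)
  ds3 <- random_dataset(8, 3, 3)
  med <- compute_centroids(ds3)
  for (j in 1:3)
    for (t in 0:2)
      expect_equal(med[j, t + 1L], mean(ds3$values[ds3$labels == t, j]))
})

test_that("CScore matches hand-worked examples", {
  # perfectly separated: every sample nearest its own centroid
  ds <- labeled_dataset(cbind(f = c(1, 2, 3, 10, 11, 12)),
                        c(0, 0, 0, 1, 1, 1))
  expect_equal(as.numeric(cscore(ds)), 1)

  # centroids 3 and 7: values 6 and 4 land on the wrong centroid
  ds2 <- labeled_dataset(cbind(f = c(1, 2, 6, 4, 8, 9)),
                         c(0, 0, 0, 1, 1, 1))
  expect_equal(as.numeric(cscore(ds2)), 4 / 6)

  # constant feature: all distances tie, tie-break to class 0
  ds3 <- labeled_dataset(cbind(f = rep(5, 6), g = c(1, 2, 3, 4, 5, 6)),
                         c(0, 1, 0, 1, 0, 1))
  expect_equal(as.numeric(cscore(ds3))[1], 0.5)
})

test_that("intermediate matrices satisfy their contracts", {
  set.seed(33)
  ds <- random_dataset(15, 4, 3)
  out <- cscore(ds, details = TRUE)
  expect_true(all(out$m1 %in% 0:(ds$p - 1L)))
  expect_identical(out$m2, (out$m1 == ds$labels) + 0L,
                   ignore_attr = TRUE)
  expect_equal(as.numeric(out$scores), unname(colSums(out$m2)) / ds$n)
  # centroid of class t in feature j lies within that class's value range
  for (j in seq_len(ds$m))
    for (t in 0:(ds$p - 1L)) {
      v <- ds$values[ds$labels == t, j]
      expect_gte(out$centroids[j, t + 1L], min(v))
      expect_lte(out$centroids[j, t + 1L], max(v))
    }
})

test_that("vectorized CScore equals the four-step loop oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    p <- sample(2:4, 1)
    ds <- random_dataset(n, sample(1:10, 1), p)
    expect_equal(as.numeric(cscore(ds)),
                 oracle_cscore(ds$values, ds$labels))
  }
})

test_that("CScore lies in [0,1] and is affine- and permutation-invariant", {
  set.seed(77)
  for (rep in 1:10) {
    ds <- random_dataset(sample(4:25, 1), sample(2:8, 1), sample(2:3, 1))
    s <- as.numeric(cscore(ds))
    expect_true(all(s >= 0 & s <= 1))

    # affine map per feature: scores unchanged
    a <- runif(ds$m, 0.5, 3) * sample(c(-1, 1), ds$m, TRUE)
    b <- rnorm(ds$m)
    v2 <- sweep(sweep(ds$values, 2, a, "*"), 2, b, "+")
    ds2 <- labeled_dataset(v2, ds$labels)
    expect_equal(as.numeric(cscore(ds2)), s)

    # permuting samples (with labels) leaves scores unchanged
    perm <- sample(ds$n)
    ds3 <- labeled_dataset(ds$values[perm, , drop = FALSE], ds$labels[perm])
    expect_equal(as.numeric(cscore(ds3)), s)

    # permuting feature columns permutes the scores identically
    fp <- sample(ds$m)
    ds4 <- labeled_dataset(ds$values[, fp, drop = FALSE], ds$labels)
    expect_equal(as.numeric(cscore(ds4)), s[fp])
  }
})

test_that("a non-overlapping feature with distinct means scores exactly 1", {
  ds <- labeled_dataset(cbind(f = c(0.1, 0.4, 0.2, 5.3, 5.1, 5.8)),
                        c(0, 0, 0, 1, 1, 1))
  expect_equal(as.numeric(cscore(ds)), 1)
  # counterexample: tight class nested inside a wide one is NOT scored 1
  # even though the class ranges barely overlap
  wide <- c(-4, -2, 0, 2, 4)
  tight <- c(1.9, 2.0, 2.1)
  ds2 <- labeled_dataset(cbind(f = c(wide, tight)), rep(0:1, c(5, 3)))
  expect_lt(as.numeric(cscore(ds2)), 1)
})

test_that("rank_features is stable and honors orientation", {
  expect_identical(rank_features(score_vector(c(0.2, 0.9, 0.9))),
                   c(2L, 3L, 1L))
  expect_identical(rank_features(score_vector(rep(0.5, 4))), 1:4)
  expect_identical(
    rank_features(score_vector(c(0.3, 0.1, 0.3), "lower_better")),
    c(2L, 1L, 3L))
  set.seed(55)
  for (rep in 1:10) {
    s <- round(runif(sample(2:30, 1)), 1)  # coarse grid forces ties
    expect_identical(rank_features(score_vector(s)), naive_rank(s, TRUE))
    expect_identical(rank_features(score_vector(s, "lower_better")),
                     naive_rank(s, FALSE))
  }
  expect_error(rank_features(numeric(0)), "empty")
})
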