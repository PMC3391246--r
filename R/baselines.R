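#' FSDD distance-discriminant feature scores
#'
#' Scores each feature by the prior-weighted between-class spread of its
#' class centroids minus \code{beta} times the prior-weighted within-class
#' variance: \code{d_b - beta * d_w} with
#' \code{d_b = sum_t p_t (mu_jt - mu_j)^2} and
#' \code{d_w = sum_t p_t var_t(f_j)}, where \code{p_t} is the class-t sample
#' fraction, \code{mu_jt} the class centroid, \code{mu_j} the grand mean and
#' \code{var_t} the within-class mean squared deviation (denominator
#' \code{n_t}, so singleton classes contribute zero spread). Higher is
#' better. \code{beta} controls how heavily within-class scatter is
#' penalized.
#'
#' Unlike CScore, FSDD is translation-invariant but not scale-invariant:
#' rescaling a feature by \code{c} multiplies its score by \code{c^2}.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @param beta non-negative weight on the within-class term (default 3).
#' @return A \code{\link{score_vector}} (higher is better).
#' @export
fsdd_score <- function(ds, beta = 3) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("'beta' must be a single non-negative number")
  med <- compute_centroids(ds)
  grand <- colMeans(ds$values)
  d_b <- numeric(ds$m)
  d_w <- numeric(ds$m)
  for (t in 0:(ds$p - 1L)) {
    rows <- ds$labels == t
    p_t <- sum(rows) / ds$n
    mu_t <- med[, t + 1L]
    d_b <- d_b + p_t * (mu_t - grand)^2
    cls <- ds$values[rows, , drop = FALSE]
    d_w <- d_w + p_t * colMeans(sweep(cls, 2L, mu_t, "-")^2)
  }
  scores <- d_b - beta * d_w
  names(scores) <- ds$feature_ids
  out <- score_vector(scores, "higher_better", "fsdd")
  attr(out, "beta") <- beta
  out
}

#' ReliefF feature weights
#'
#' Estimates the weight of each feature by how well it discriminates between
#' neighboring samples. For each visited sample, the \code{k} nearest
#' same-class samples (hits) and, for every other class, the \code{k} nearest
#' samples of that class (misses) are located; the feature weight is
#' decreased by the average hit difference and increased by the
#' prior-weighted average miss difference. Differences are per-feature
#' absolute differences normalized by the feature's range, so weights lie in
#' [-1, 1]; higher is better. Neighbor search uses the range-normalized
#' Manhattan distance over all features; distance ties break by ascending
#' sample index.
#'
#' By default every sample is visited exactly once in index order, making the
#' weights deterministic. Classical random instance sampling is available by
#' setting \code{iterations} below \code{n} with a \code{seed}.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @param k neighbor count per class (default 7); clipped per class when a
#'   class has too few samples.
#' @param iterations number of samples visited; default \code{ds$n} visits
#'   every sample once (deterministic full pass). Smaller values sample
#'   instances at random.
#' @param seed RNG seed for the sampled variant; ignored by the full pass.
#' @return A \code{\link{score_vector}} (higher is better).
#' @export
relieff_score <- function(ds, k = 7L, iterations = ds$n, seed = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"))
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1")
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("'iterations' must be >= 1")
  if (any(table(ds$labels) < 2L))
    stop("every class needs >= 2 samples for hit search")

  rng <- apply(ds$values, 2L, function(v) diff(range(v)))
  denom <- ifelse(rng > 0, rng, 1)  # constant feature: all diffs are 0
  norm <- sweep(ds$values, 2L, denom, "/")
  priors <- as.numeric(table(factor(ds$labels, levels = 0:(ds$p - 1L)))) / ds$n

  if (iterations >= ds$n) {
    visits <- seq_len(ds$n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    visits <- sample.int(ds$n, iterations, replace = FALSE)
  }

  w <- numeric(ds$m)
  nv <- length(visits)
  for (i in visits) {
    d <- colSums(abs(t(norm) - norm[i, ]))
    d[i] <- Inf
    ci <- ds$labels[i]
    ord <- order(d, method = "radix")
    for (t in 0:(ds$p - 1L)) {
      pool <- ord[ds$labels[ord] == t & ord != i]
      kk <- min(k, length(pool))
      nb <- pool[seq_len(kk)]
      diffs <- colMeans(abs(norm[nb, , drop = FALSE] -
                              matrix(norm[i, ], kk, ds$m, byrow = TRUE)))
      if (t == ci) {
        w <- w - diffs / nv
      } else {
        w <- w + (priors[t + 1L] / (1 - priors[ci + 1L])) * diffs / nv
      }
    }
  }
  names(w) <- ds$feature_ids
  out <- score_vector(w, "higher_better", "relieff")
  attr(out, "k") <- k
  out
}
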