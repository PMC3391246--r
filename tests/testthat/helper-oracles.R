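# Independent brute-force oracles, written as literal loop transcriptions of
# the scoring definitions. They deliberately avoid the vectorized code paths
# of the package (sweep/colMeans/order-based ranking).

random_dataset <- function(n, m, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- c(0:(p - 1L), sample(0:(p - 1L), n - p, replace = TRUE))
  labeled_dataset(matrix(rnorm(n * m), n, m), labels)
}

# four-step loop transcription: centroids, nearest-centroid prediction,
# match matrix, per-feature matching fraction
oracle_cscore <- function(values, labels) {
  n <- nrow(values); m <- ncol(values); p <- max(labels) + 1L
  med <- matrix(NA_real_, m, p)
  for (j in seq_len(m))
    for (t in 0:(p - 1L))
      med[j, t + 1L] <- mean(values[labels == t, j])
  scores <- numeric(m)
  for (j in seq_len(m)) {
    correct <- 0L
    for (i in seq_len(n)) {
      best <- Inf; pred <- NA_integer_
      for (t in 0:(p - 1L)) {
        d <- abs(values[i, j] - med[j, t + 1L])
        if (d < best) { best <- d; pred <- t }
      }
      if (pred == labels[i]) correct <- correct + 1L
    }
    scores[j] <- correct / n
  }
  scores
}

# exhaustive O(n^2) neighbor search; k nearest by repeated min-scan so the
# index tie-break is explicit
oracle_rvalue <- function(values, labels, k, theta) {
  n <- nrow(values); m <- ncol(values)
  scores <- numeric(m)
  for (j in seq_len(m)) {
    congested <- 0L
    for (i in seq_len(n)) {
      d <- abs(values[, j] - values[i, j])
      d[i] <- NA
      nb <- integer(k)
      for (q in seq_len(k)) {
        best <- Inf; pick <- NA_integer_
        for (i2 in seq_len(n)) {
          if (is.na(d[i2])) next
          if (d[i2] < best) { best <- d[i2]; pick <- i2 }
        }
        nb[q] <- pick
        d[pick] <- NA
      }
      if (sum(labels[nb] != labels[i]) >= theta) congested <- congested + 1L
    }
    scores[j] <- congested / n
  }
  scores
}

# two-loop weighted between/within variance decomposition
oracle_fsdd <- function(values, labels, beta) {
  n <- nrow(values); m <- ncol(values); p <- max(labels) + 1L
  scores <- numeric(m)
  for (j in seq_len(m)) {
    grand <- mean(values[, j])
    d_b <- 0; d_w <- 0
    for (t in 0:(p - 1L)) {
      v <- values[labels == t, j]
      p_t <- length(v) / n
      mu_t <- mean(v)
      d_b <- d_b + p_t * (mu_t - grand)^2
      d_w <- d_w + p_t * mean((v - mu_t)^2)
    }
    scores[j] <- d_b - beta * d_w
  }
  scores
}

# brute-force hit/miss transcription of the deterministic full-pass update
oracle_relieff <- function(values, labels, k) {
  n <- nrow(values); m <- ncol(values); p <- max(labels) + 1L
  rng <- numeric(m)
  for (j in seq_len(m)) rng[j] <- max(values[, j]) - min(values[, j])
  denom <- ifelse(rng > 0, rng, 1)
  priors <- numeric(p)
  for (t in 0:(p - 1L)) priors[t + 1L] <- sum(labels == t) / n
  diff_jab <- function(j, a, b) abs(values[a, j] - values[b, j]) / denom[j]
  dist_ab <- function(a, b) {
    s <- 0
    for (j in seq_len(m)) s <- s + diff_jab(j, a, b)
    s
  }
  w <- numeric(m)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (i2 in seq_len(n)) if (i2 != i) d[i2] <- dist_ab(i, i2)
    for (t in 0:(p - 1L)) {
      pool <- which(labels == t & seq_len(n) != i)
      pool <- pool[order(d[pool], pool)]
      nb <- pool[seq_len(min(k, length(pool)))]
      avg <- numeric(m)
      for (j in seq_len(m)) avg[j] <- mean(sapply(nb, function(b)
        diff_jab(j, i, b)))
      if (t == labels[i]) {
        w <- w - avg / n
      } else {
        w <- w + (priors[t + 1L] / (1 - priors[labels[i] + 1L])) * avg / n
      }
    }
  }
  w
}

# best-to-worst ranking by repeated best-pick scan (stable index tie-break)
naive_rank <- function(scores, higher_better = TRUE) {
  s <- as.numeric(scores)
  out <- integer(length(s))
  taken <- rep(FALSE, length(s))
  for (q in seq_along(s)) {
    pick <- NA_integer_; best <- if (higher_better) -Inf else Inf
    for (j in seq_along(s)) {
      if (taken[j]) next
      better <- if (higher_better) s[j] > best else s[j] < best
      if (better) { best <- s[j]; pick <- j }
    }
    out[q] <- pick
    taken[pick] <- TRUE
  }
  out
}

# literal transcription of the five boxed steps of the exact combiner
oracle_cbfs_exact <- function(cs, rs, m) {
  total <- length(cs)
  extract <- integer(0)
  n <- m
  while (length(extract) < m) {
    s1 <- naive_rank(cs, TRUE)[seq_len(n)]
    s2 <- naive_rank(rs, FALSE)[seq_len(n)]
    inter <- s1[s1 %in% s2]
    for (f in inter) if (!f %in% extract) extract <- c(extract, f)
    if (length(extract) < m) n <- n + 1L
    stopifnot(n <= total)
  }
  extract[seq_len(m)]
}

random_score_pair <- function(m) {
  list(cs = score_vector(round(runif(m), 2), "higher_better", "cscore"),
       rs = score_vector(round(runif(m), 2), "lower_better", "rvalue"))
}
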