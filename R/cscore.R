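#' Per-class centroids of every feature
#'
#' The centroid of class \code{t} in feature \code{j} is the arithmetic mean
#' of that class's values in that feature. Defined for every (feature, class)
#' pair because every class carries at least one sample; a singleton class's
#' centroid is the sample value itself.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @return An \code{m x p} numeric matrix; rows are features, column \code{t}
#'   holds the centroids of class \code{t - 1}.
#' @export
compute_centroids <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  med <- matrix(NA_real_, ds$m, ds$p,
                dimnames = list(ds$feature_ids, 0:(ds$p - 1L)))
  for (t in 0:(ds$p - 1L)) {
    rows <- ds$labels == t
    med[, t + 1L] <- colMeans(ds$values[rows, , drop = FALSE])
  }
  med
}

#' CScore: clearness of each feature
#'
#' CScore measures how well the classes separate within a single feature. For
#' each sample and feature, the sample's value is assigned to the nearest
#' class centroid by one-dimensional absolute distance; CScore of the feature
#' is the fraction of samples whose nearest centroid belongs to their own
#' class. It lies in [0, 1]; 1 means every sample clusters to its own class
#' centroid. Ties in the nearest-centroid assignment go to the smallest class
#' label, so a constant feature with balanced two-class labels scores exactly
#' the class-0 fraction.
#'
#' The statistic is invariant under affine rescaling of a feature (centroids
#' and distances transform together), so no standardization is applied.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @param details if \code{TRUE}, also return the centroid table and the
#'   intermediate prediction (\code{m1}) and match (\code{m2}) matrices.
#' @return A \code{\link{score_vector}} (higher is better), or when
#'   \code{details = TRUE} a list with \code{scores}, \code{centroids},
#'   \code{m1} (n x m predicted class labels) and \code{m2} (n x m 0/1
#'   matches).
#' @examples
#' ds <- labeled_dataset(cbind(x = c(1, 2, 3, 10, 11, 12)),
#'                       c(0, 0, 0, 1, 1, 1))
#' cscore(ds)  # perfectly separated: 1
#' @export
cscore <- function(ds, details = FALSE) {
  stopifnot(inherits(ds, "labeled_dataset"))
  med <- compute_centroids(ds)
  # nearest centroid per (sample, feature); iterate classes in ascending
  # label order with a strict improvement test so ties keep the smallest
  # label. Features are processed in column blocks to keep the working set
  # cache-resident on wide matrices.
  scores <- numeric(ds$m)
  m1 <- if (details) matrix(0L, ds$n, ds$m) else NULL
  block <- 256L
  for (start in seq.int(1L, ds$m, by = block)) {
    cols <- start:min(start + block - 1L, ds$m)
    x <- ds$values[, cols, drop = FALSE]
    best_dist <- matrix(Inf, ds$n, length(cols))
    pred <- matrix(0L, ds$n, length(cols))
    for (t in 0:(ds$p - 1L)) {
      d <- abs(sweep(x, 2L, med[cols, t + 1L], "-"))
      upd <- d < best_dist
      best_dist[upd] <- d[upd]
      pred[upd] <- t
    }
    scores[cols] <- colSums(pred == ds$labels) / ds$n
    if (details) m1[, cols] <- pred
  }
  names(scores) <- ds$feature_ids
  sv <- score_vector(scores, "higher_better", "cscore")
  if (!details) return(sv)
  m2 <- (m1 == ds$labels) + 0L
  dimnames(m1) <- dimnames(m2) <- list(ds$sample_ids, ds$feature_ids)
  list(scores = sv, centroids = med, m1 = m1, m2 = m2)
}
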