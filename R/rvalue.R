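#' R-value: per-feature class congestion
#'
#' A neighbor-based clearness score that is sensitive to geometries where a
#' nearest-centroid rule fails, e.g. a tight class nested inside the value
#' range of a wide one. For each feature, a sample lies in the overlap
#' (congestion) area if at least \code{theta} of its \code{k} nearest other
#' samples -- by one-dimensional absolute distance within that feature --
#' carry a different class label. The R-value of the feature is the fraction
#' of samples in the overlap area: lower means clearer.
#'
#' Distance ties among candidate neighbors are broken by ascending sample
#' index, so the score is deterministic. Like CScore, the R-value is invariant
#' under affine rescaling of a feature.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @param k number of nearest neighbors examined per sample
#'   (default 7); must be smaller than the number of samples.
#' @param theta minimum count of other-class neighbors that marks a sample as
#'   congested; default \code{ceiling(k / 2)}, i.e. an other-class majority.
#' @return A \code{\link{score_vector}} with orientation
#'   \code{"lower_better"}; entries lie in [0, 1]. Attributes \code{k} and
#'   \code{theta} record the parameters.
#' @examples
#' ds <- labeled_dataset(cbind(x = c(1, 2, 3, 10, 11, 12)),
#'                       c(0, 0, 0, 1, 1, 1))
#' rvalue_score(ds, k = 2, theta = 1)  # fully separated: 0
#' @export
rvalue_score <- function(ds, k = 7L, theta = ceiling(k / 2)) {
  stopifnot(inherits(ds, "labeled_dataset"))
  k <- as.integer(k)
  theta <- as.integer(theta)
  if (k < 1L || k >= ds$n) stop("'k' must satisfy 1 <= k <= n - 1")
  if (theta < 1L || theta > k) stop("'theta' must satisfy 1 <= theta <= k")
  scores <- numeric(ds$m)
  for (j in seq_len(ds$m)) {
    v <- ds$values[, j]
    congested <- 0L
    for (i in seq_len(ds$n)) {
      d <- abs(v - v[i])
      d[i] <- Inf
      nb <- order(d, method = "radix")[seq_len(k)]  # stable: index tie-break
      if (sum(ds$labels[nb] != ds$labels[i]) >= theta)
        congested <- congested + 1L
    }
    scores[j] <- congested / ds$n
  }
  names(scores) <- ds$feature_ids
  out <- score_vector(scores, "lower_better", "rvalue")
  attr(out, "k") <- k
  attr(out, "theta") <- theta
  out
}
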