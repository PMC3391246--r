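#' Construct a score vector
#'
#' A numeric vector of per-feature scores tagged with its orientation:
#' \code{"higher_better"} (CScore, FSDD, ReliefF) or \code{"lower_better"}
#' (R-value). The orientation travels with the scores so that
#' \code{\link{rank_features}} and the combination algorithms always sort in
#' the right direction.
#'
#' @param scores numeric vector, one entry per feature.
#' @param orientation \code{"higher_better"} or \code{"lower_better"}.
#' @param method character tag naming the scoring scheme.
#' @return A numeric vector of class \code{score_vector} with attributes
#'   \code{orientation} and \code{method}. Names are feature ids when known.
#' @export
score_vector <- function(scores,
                         orientation = c("higher_better", "lower_better"),
                         method = "custom") {
  orientation <- match.arg(orientation)
  if (!is.numeric(scores) || !length(scores))
    stop("'scores' must be a non-empty numeric vector")
  structure(as.numeric(scores),
            names = names(scores),
            orientation = orientation,
            method = method,
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat("score_vector [", attr(x, "method"), ", ",
      attr(x, "orientation"), "], ", length(x), " features\n", sep = "")
  print(unclass(structure(as.numeric(x), names = names(x))), ...)
  invisible(x)
}

score_orientation <- function(scores) {
  o <- attr(scores, "orientation")
  if (is.null(o)) "higher_better" else o
}

#' Rank features by score
#'
#' Orders feature indices from best to worst according to the score vector's
#' orientation. Ties keep ascending feature-index order (a stable sort), so
#' the ranking is fully deterministic.
#'
#' @param scores a \code{\link{score_vector}} (or plain numeric vector, taken
#'   as higher-is-better).
#' @return Integer vector of feature indices (1-based), best feature first.
#' @examples
#' rank_features(score_vector(c(0.2, 0.9, 0.9), "higher_better"))  # 2 3 1
#' @export
rank_features <- function(scores) {
  if (!length(scores)) stop("empty score vector")
  s <- as.numeric(scores)
  decreasing <- score_orientation(scores) == "higher_better"
  # order() is stable: equal scores stay in ascending index order
  order(s, decreasing = decreasing, method = "radix")
}
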