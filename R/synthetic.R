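#' Generate a labeled dataset with controlled class separability
#'
#' Produces a synthetic sample-by-feature matrix for exercising the scoring
#' and selection machinery without external downloads. Three geometries:
#' \describe{
#'   \item{\code{"gaussian"}}{informative features draw class \code{t} from
#'     Normal(\code{t * delta}, 1) -- class means on a line, spacing
#'     \code{delta} in within-class SD units; \code{delta = 0} makes
#'     informative features indistinguishable from noise.}
#'   \item{\code{"fig4_case1"}}{two classes; a wide class (Normal(0, 3))
#'     with a tight class (Normal(2, 0.1)) nested inside its span. The
#'     classes barely overlap, yet wide-class samples falling near the tight
#'     cluster are assigned to the wrong centroid, deflating CScore while a
#'     neighbor-based score stays low -- the geometry that motivates
#'     combining the two schemes.}
#'   \item{\code{"fig4_case2"}}{two classes, Normal(0, 1.5) and
#'     Normal(1, 1.5): heavy overlap around the midpoint.}
#' }
#' Noise features are Normal(0, 1) regardless of class. Class sizes are as
#' equal as integer division allows; labels are \code{0..n_classes-1} in
#' block order. Output is fully reproducible under \code{seed}.
#'
#' @param n_samples total number of samples.
#' @param n_classes number of classes (fixed at 2 for the fig4 geometries).
#' @param n_informative number of class-dependent features.
#' @param n_noise number of label-independent noise features.
#' @param delta class-mean spacing in within-class SD units
#'   (\code{"gaussian"} geometry only).
#' @param seed RNG seed.
#' @param geometry \code{"gaussian"}, \code{"fig4_case1"} or
#'   \code{"fig4_case2"}.
#' @return List with \code{dataset} (a \code{\link{labeled_dataset}};
#'   informative columns first, named \code{inf1..}, then \code{noise1..})
#'   and \code{informative} (the true informative column indices).
#' @examples
#' synth <- make_dataset(n_samples = 60, n_informative = 2, n_noise = 8,
#'                       delta = 3, seed = 1)
#' cscore(synth$dataset)[synth$informative]
#' @export
make_dataset <- function(n_samples = 100L, n_classes = 2L,
                         n_informative = 10L, n_noise = 490L,
                         delta = 2, seed = NULL,
                         geometry = c("gaussian", "fig4_case1",
                                      "fig4_case2")) {
  geometry <- match.arg(geometry)
  n_samples <- as.integer(n_samples)
  n_classes <- as.integer(n_classes)
  n_informative <- as.integer(n_informative)
  n_noise <- as.integer(n_noise)
  if (n_informative + n_noise < 1L) stop("need at least one feature")
  if (n_informative < 0L || n_noise < 0L) stop("feature counts must be >= 0")
  if (delta < 0) stop("'delta' must be >= 0")
  if (geometry != "gaussian") n_classes <- 2L
  if (n_classes < 2L || n_samples < n_classes)
    stop("need >= 2 classes and at least one sample per class")
  if (!is.null(seed)) set.seed(seed)

  sizes <- rep(n_samples %/% n_classes, n_classes)
  extra <- n_samples %% n_classes
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(0:(n_classes - 1L), times = sizes)

  m <- n_informative + n_noise
  values <- matrix(NA_real_, n_samples, m)
  if (n_informative > 0L) {
    for (j in seq_len(n_informative)) {
      values[, j] <- switch(
        geometry,
        gaussian   = stats::rnorm(n_samples, mean = labels * delta, sd = 1),
        fig4_case1 = ifelse(labels == 0L,
                            stats::rnorm(n_samples, 0, 3),
                            stats::rnorm(n_samples, 2, 0.1)),
        fig4_case2 = stats::rnorm(n_samples, mean = labels, sd = 1.5)
      )
    }
  }
  if (n_noise > 0L)
    values[, n_informative + seq_len(n_noise)] <-
      stats::rnorm(n_samples * n_noise)

  ids <- c(if (n_informative > 0L) paste0("inf", seq_len(n_informative)),
           if (n_noise > 0L) paste0("noise", seq_len(n_noise)))
  ds <- labeled_dataset(values, labels, feature_ids = ids)
  list(dataset = ds,
       informative = if (n_informative > 0L) seq_len(n_informative)
                     else integer(0))
}
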