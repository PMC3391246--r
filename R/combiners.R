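#' Combine CScore and R-value rankings by top-n intersection
#'
#' Takes the \code{n} best features by CScore (higher better) and the
#' \code{n} best by R-value (lower better), intersects the two sets, orders
#' the intersection by CScore rank and returns its first \code{m} members.
#' Because the size of the intersection cannot be known in advance, the
#' result may hold fewer than \code{m} features -- the limitation that
#' motivates \code{\link{cbfs_exact}}.
#'
#' @param cs a \code{\link{score_vector}} of CScores (higher better).
#' @param rs a \code{\link{score_vector}} of R-values (lower better).
#' @param m number of features requested.
#' @param n size of each top list intersected (default 100, clipped to the
#'   total number of features); must be at least \code{m}.
#' @return Integer vector of at most \code{m} feature indices, ordered by
#'   CScore rank (possibly empty).
#' @seealso \code{\link{cbfs_exact}} for a variant that always returns
#'   exactly \code{m} features.
#' @export
cbfs_intersection <- function(cs, rs, m, n = 100L) {
  total <- length(cs)
  if (length(rs) != total) stop("score vectors have different lengths")
  n <- as.integer(n)
  m <- as.integer(m)
  if (n > total) stop("'n' exceeds the number of features")
  if (m < 1L || m > n) stop("'m' must satisfy 1 <= m <= n")
  s1 <- rank_features(cs)[seq_len(n)]
  s2 <- rank_features(rs)[seq_len(n)]
  inter <- s1[s1 %in% s2]          # keeps CScore-rank order
  inter[seq_len(min(m, length(inter)))]
}

#' Combine CScore and R-value rankings, returning exactly m features
#'
#' Grows the list-size threshold \code{n} from \code{m} upward: each round
#' intersects the top-\code{n} features by CScore with the top-\code{n} by
#' R-value and appends members not yet collected, in CScore-rank order, to a
#' running extract list. The loop stops as soon as the list holds at least
#' \code{m} features and returns the first \code{m} in insertion order.
#' Termination is guaranteed: once \code{n} reaches the total number of
#' features both top lists contain every feature.
#'
#' @inheritParams cbfs_intersection
#' @return Integer vector of exactly \code{m} distinct feature indices, in
#'   insertion order.
#' @examples
#' cs <- score_vector(c(.9, .8, .7, .6, .5), "higher_better")
#' rs <- score_vector(c(.5, .1, .4, .2, .3), "lower_better")
#' cbfs_exact(cs, rs, 3)
#' @export
cbfs_exact <- function(cs, rs, m) {
  total <- length(cs)
  if (length(rs) != total) stop("score vectors have different lengths")
  m <- as.integer(m)
  if (m < 1L || m > total) stop("'m' must satisfy 1 <= m <= number of features")
  r1 <- rank_features(cs)
  r2 <- rank_features(rs)
  extract <- integer(0)
  n <- m
  repeat {
    s1 <- r1[seq_len(n)]
    s2 <- r2[seq_len(n)]
    inter <- s1[s1 %in% s2]
    extract <- c(extract, setdiff(inter, extract))
    if (length(extract) >= m) break
    n <- n + 1L
    if (n > total)
      stop("internal error: threshold exceeded feature count before ",
           "collecting m features")  # unreachable for consistent inputs
  }
  extract[seq_len(m)]
}
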