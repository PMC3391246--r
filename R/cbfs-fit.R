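#' Clearness-based feature selection
#'
#' Fits a feature selector to a labeled dataset and returns the ranked
#' selection together with the per-feature scores that produced it. Methods:
#' \describe{
#'   \item{\code{"cbfs_org"}}{rank by \code{\link{cscore}} alone and take the
#'     top \code{m}.}
#'   \item{\code{"cbfs_intersection"}}{intersect the top-\code{n} features by
#'     CScore with the top-\code{n} by R-value
#'     (\code{\link{cbfs_intersection}}); may return fewer than \code{m}.}
#'   \item{\code{"cbfs_exact"}}{grow the threshold until exactly \code{m}
#'     features are collected (\code{\link{cbfs_exact}}).}
#'   \item{\code{"fsdd"}, \code{"relieff"}, \code{"rvalue"}}{top \code{m} by
#'     the corresponding single score.}
#' }
#'
#' @param x a \code{\link{labeled_dataset}}, a numeric matrix/data frame of
#'   features (with \code{y} supplied), or a formula such as
#'   \code{class ~ .}.
#' @param ... arguments passed on to methods.
#' @return An object of class \code{"cbfs"}; see \code{\link{cbfs.default}}.
#' @examples
#' synth <- make_dataset(n_samples = 60, n_informative = 3, n_noise = 20,
#'                       delta = 3, seed = 7)
#' fit <- cbfs(synth$dataset, method = "cbfs_exact", m = 3)
#' fit$selected
#' @export
cbfs <- function(x, ...) UseMethod("cbfs")

#' @rdname cbfs
#' @param formula a formula naming the label column, e.g. \code{class ~ .}
#'   (only the intercept-free full set of remaining columns is supported).
#' @param data a data frame holding features and the label column.
#' @export
cbfs.formula <- function(formula, data, ...) {
  label_col <- all.vars(formula[[2]])
  if (length(label_col) != 1L || !label_col %in% names(data))
    stop("formula must name one label column present in 'data'")
  feat <- data[setdiff(names(data), label_col)]
  rhs <- formula[[3]]
  if (!identical(rhs, as.name(".")))
    feat <- feat[intersect(all.vars(rhs), names(feat))]
  cbfs.default(as.matrix(feat), data[[label_col]], ...)
}

#' @rdname cbfs
#' @param y class labels (one per row of \code{x}); ignored when \code{x} is
#'   already a \code{labeled_dataset}.
#' @param method selection method, see Details.
#' @param m number of features to select (default
#'   \code{min(20, total features)}).
#' @param n top-list size for \code{"cbfs_intersection"} (default 100,
#'   clipped to the number of features).
#' @param beta FSDD within-class weight (default 3).
#' @param relief_k ReliefF neighbor count (default 7).
#' @param rvalue_k R-value neighbor count (default 7).
#' @param theta R-value congestion threshold (default
#'   \code{ceiling(rvalue_k / 2)}).
#' @export
cbfs.default <- function(x, y = NULL,
                         method = c("cbfs_org", "cbfs_intersection",
                                    "cbfs_exact", "fsdd", "relieff",
                                    "rvalue"),
                         m = NULL, n = 100L, beta = 3, relief_k = 7L,
                         rvalue_k = 7L, theta = ceiling(rvalue_k / 2), ...) {
  method <- match.arg(method)
  ds <- if (inherits(x, "labeled_dataset")) x else labeled_dataset(x, y)
  if (is.null(m)) m <- min(20L, ds$m)
  m <- as.integer(m)
  if (m < 1L || m > ds$m) stop("'m' must satisfy 1 <= m <= number of features")

  needs_cs <- method %in% c("cbfs_org", "cbfs_intersection", "cbfs_exact")
  needs_rv <- method %in% c("cbfs_intersection", "cbfs_exact", "rvalue")
  cs <- if (needs_cs) cscore(ds) else NULL
  rv <- if (needs_rv) rvalue_score(ds, k = rvalue_k, theta = theta) else NULL

  params <- list(m = m)
  if (method == "cbfs_intersection") {
    n <- min(as.integer(n), ds$m)
    if (n < m) n <- m
    params$n <- n
  }
  selected <- switch(
    method,
    cbfs_org = rank_features(cs)[seq_len(m)],
    cbfs_intersection = cbfs_intersection(cs, rv, m = m, n = params$n),
    cbfs_exact = cbfs_exact(cs, rv, m = m),
    fsdd = {
      sv <- fsdd_score(ds, beta = beta)
      params$beta <- beta
      cs <- sv
      rank_features(sv)[seq_len(m)]
    },
    relieff = {
      sv <- relieff_score(ds, k = relief_k)
      params$k <- relief_k
      cs <- sv
      rank_features(sv)[seq_len(m)]
    },
    rvalue = {
      params$k <- rvalue_k
      params$theta <- theta
      rank_features(rv)[seq_len(m)]
    }
  )
  if (needs_rv && method != "rvalue") {
    params$rvalue_k <- rvalue_k
    params$theta <- theta
  }
  scores <- if (method == "rvalue") rv else cs
  structure(
    list(selected = as.integer(selected),
         feature_ids = ds$feature_ids[selected],
         scores = scores, rvalue = if (method != "rvalue") rv else NULL,
         method = method, params = params,
         n_samples = ds$n, n_features = ds$m, n_classes = ds$p,
         call = match.call()),
    class = "cbfs"
  )
}

#' @export
print.cbfs <- function(x, ...) {
  cat("Feature selection by", x$method, "\n")
  cat(sprintf("data: %d samples x %d features, %d classes\n",
              x$n_samples, x$n_features, x$n_classes))
  cat(sprintf("selected %d feature(s): %s\n", length(x$selected),
              paste(utils::head(x$feature_ids, 10L), collapse = ", ")))
  if (length(x$selected) > 10L) cat("  ... and", length(x$selected) - 10L,
                                    "more\n")
  invisible(x)
}

#' @export
summary.cbfs <- function(object, ...) {
  sel_scores <- as.numeric(object$scores)[object$selected]
  cat("Feature selection by", object$method, "\n")
  cat("parameters:",
      paste(names(object$params), unlist(object$params), sep = "=",
            collapse = ", "), "\n")
  df <- data.frame(rank = seq_along(object$selected),
                   feature_id = object$feature_ids,
                   score = sel_scores)
  print(utils::head(df, 20L), row.names = FALSE)
  if (nrow(df) > 20L) cat("  ...", nrow(df) - 20L, "more rows\n")
  invisible(df)
}

#' @export
coef.cbfs <- function(object, ...) {
  structure(as.numeric(object$scores), names = names(object$scores))
}

#' @export
plot.cbfs <- function(x, ...) {
  s <- as.numeric(x$scores)
  ord <- rank_features(x$scores)
  graphics::plot(seq_along(s), s[ord], type = "h", xlab = "feature rank",
                 ylab = paste0(attr(x$scores, "method"), " score"),
                 main = paste("Score profile -", x$method), ...)
  sel_pos <- match(x$selected, ord)
  graphics::points(sel_pos, s[x$selected], col = "red", pch = 16)
  invisible(x)
}

#' Write a feature selection to delimited text
#'
#' One row per selected feature with columns \code{rank}, \code{feature_id},
#' \code{score}, \code{method} and \code{params} (semicolon-separated
#' \code{key=value} pairs). An empty selection writes a header-only file.
#' Round-trips through \code{\link{read_selection}} losslessly.
#'
#' @param result a \code{\link{cbfs}} fit.
#' @param path output file path.
#' @export
write_selection <- function(result, path) {
  stopifnot(inherits(result, "cbfs"))
  params <- paste(names(result$params), unlist(result$params), sep = "=",
                  collapse = ";")
  df <- data.frame(
    rank = seq_along(result$selected),
    feature_id = result$feature_ids,
    score = as.numeric(result$scores)[result$selected],
    method = rep(result$method, length(result$selected)),
    params = rep(params, length(result$selected)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature selection written by \code{\link{write_selection}}
#'
#' @param path path to the CSV file.
#' @return Data frame with columns \code{rank}, \code{feature_id},
#'   \code{score}, \code{method}, \code{params} (zero rows for an empty
#'   selection).
#' @export
read_selection <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(rank = "integer", feature_id = "character",
                                 score = "numeric", method = "character",
                                 params = "character"))
}
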