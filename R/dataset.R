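#' Construct a labeled dataset
#'
#' The container every scoring and selection function in this package
#' operates on: an \code{n x m} numeric matrix (samples in rows, features in
#' columns) plus one class label per sample. Labels of any type (character,
#' factor, numeric) are re-encoded to consecutive integers \code{0..p-1} in
#' order of first appearance, so row order alone determines the encoding; the
#' original values are kept in \code{label_levels} for output.
#'
#' @param values numeric matrix or data frame, \code{n} samples by \code{m}
#'   features. Column names become feature ids; missing names are filled with
#'   \code{f1..fm}.
#' @param labels length-\code{n} vector of class labels; at least two distinct
#'   classes are required and every class must have at least one sample.
#' @param feature_ids optional character vector of unique feature identifiers
#'   (defaults to column names).
#' @param sample_ids optional character vector of unique sample identifiers
#'   (defaults to row names).
#' @param impute if \code{TRUE}, missing feature values are replaced by the
#'   mean of the observed values of the same feature within the same class
#'   (falling back to the feature's overall mean if the class has none).
#'   If \code{FALSE} (default), missing values are an error.
#'
#' @return An object of class \code{labeled_dataset}: a list with elements
#'   \code{values} (numeric matrix), \code{labels} (integer vector in
#'   \code{0..p-1}), \code{feature_ids}, \code{sample_ids},
#'   \code{label_levels} (original label value for each encoded class),
#'   and counts \code{n}, \code{m}, \code{p}.
#' @examples
#' ds <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(c("A", "B"), 5))
#' ds$p
#' @export
labeled_dataset <- function(values, labels, feature_ids = NULL,
                            sample_ids = NULL, impute = FALSE) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix or data frame")
  n <- nrow(values)
  m <- ncol(values)
  if (n < 2L) stop("need at least 2 samples")
  if (m < 1L) stop("need at least 1 feature")
  if (length(labels) != n)
    stop("length(labels) must equal nrow(values)")
  if (anyNA(labels)) stop("labels must not contain missing values")

  # first-appearance encoding to 0..p-1
  label_levels <- unique(labels)
  p <- length(label_levels)
  if (p < 2L) stop("need >=2 classes")
  enc <- match(labels, label_levels) - 1L

  if (is.null(feature_ids)) feature_ids <- colnames(values)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(m))
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != m || anyDuplicated(feature_ids))
    stop("feature_ids must be unique and of length ncol(values)")
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and of length nrow(values)")

  if (anyNA(values)) {
    if (!impute)
      stop("missing feature values; set impute = TRUE to use ",
           "per-feature class-mean imputation")
    for (j in seq_len(m)) {
      miss <- which(is.na(values[, j]))
      if (!length(miss)) next
      overall <- mean(values[, j], na.rm = TRUE)
      if (is.nan(overall)) stop("feature ", feature_ids[j], " is all-missing")
      for (i in miss) {
        same <- values[enc == enc[i], j]
        fill <- mean(same, na.rm = TRUE)
        values[i, j] <- if (is.nan(fill)) overall else fill
      }
    }
  }

  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, labels = enc, feature_ids = feature_ids,
         sample_ids = sample_ids, label_levels = label_levels,
         n = n, m = m, p = p),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", x$n, "samples x", x$m, "features,",
      x$p, "classes\n")
  tab <- table(factor(x$labels, levels = 0:(x$p - 1L)))
  cat("class sizes:",
      paste(sprintf("%s=%d", x$label_levels, as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read a labeled dataset from delimited text
#'
#' Expects a header row, samples as rows, one label column, and all remaining
#' columns numeric. Class labels are re-encoded to \code{0..p-1} by first
#' appearance (see \code{\link{labeled_dataset}}).
#'
#' @param path path to a CSV/TSV file.
#' @param label_column name of the label column (default \code{"class"}).
#' @param delimiter field separator; default \code{","}, use \code{"\t"} for
#'   TSV.
#' @param impute passed to \code{\link{labeled_dataset}}.
#' @return A \code{\link{labeled_dataset}}.
#' @export
read_dataset <- function(path, label_column = "class", delimiter = ",",
                         impute = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found")
  labels <- df[[label_column]]
  feat <- df[names(df) != label_column]
  bad <- names(feat)[!vapply(feat, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
  labeled_dataset(as.matrix(feat), labels, impute = impute)
}

#' Write a labeled dataset to delimited text
#'
#' Inverse of \code{\link{read_dataset}}: one row per sample, features as
#' columns, plus the label column carrying the original (pre-encoding) label
#' values. \code{read_dataset(write_dataset(ds))} preserves values, label
#' encoding and orderings.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @param path output file path.
#' @param label_column name for the label column.
#' @param delimiter field separator.
#' @export
write_dataset <- function(ds, path, label_column = "class", delimiter = ",") {
  stopifnot(inherits(ds, "labeled_dataset"))
  df <- as.data.frame(ds$values)
  df[[label_column]] <- ds$label_levels[ds$labels + 1L]
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
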