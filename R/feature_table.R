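#' Construct a feature table
#'
#' A feature table bundles a numeric sample-by-feature matrix with a
#' two-level class label vector. It is the object every other function in
#' the package selects over: normalization rescales its columns, the
#' optimizer searches over subsets of its columns, and the wrapper fitness
#' trains a classifier on masked views of it.
#'
#' @param x Numeric matrix or data frame, samples in rows, features in
#'   columns. Column names are kept (or generated as `V1..Vd`).
#' @param labels Vector of class labels with exactly two distinct values;
#'   coerced to a factor.
#' @param label_name Name of the label column, used when writing to disk.
#' @param positive Which label value counts as the positive class
#'   (e.g. "patient"). Defaults to the lexicographically larger level, which
#'   matches the usual 0 = control / 1 = case coding.
#'
#' @return An object of class `feature_table`: a list with elements `x`
#'   (numeric matrix), `y` (two-level factor), `feature_names`,
#'   `label_name` and `positive`.
#' @export
feature_table <- function(x, labels, label_name = "label", positive = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    bad <- which(!apply(x, 2, function(col) all(!is.na(suppressWarnings(as.numeric(col))))))
    stop_input("feature columns must be numeric; offending column(s): ",
               paste(colnames(x)[bad] %||% bad, collapse = ", "))
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop_input("feature table needs at least one sample and one feature")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    idx <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop_input("non-finite cell at row ", idx[1], ", column ",
               colnames(x)[idx[2]] %||% idx[2])
  }
  if (length(labels) != nrow(x)) {
    stop_input("labels length (", length(labels),
               ") does not match sample count (", nrow(x), ")")
  }
  y <- factor(labels)
  if (nlevels(y) != 2L) {
    stop_input("labels must take exactly two distinct values, found ",
               nlevels(y), ": ", paste(levels(y), collapse = ", "))
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop_input("duplicate feature names")
  if (is.null(positive)) positive <- max(levels(y))
  positive <- as.character(positive)
  if (!positive %in% levels(y)) stop_input("positive label '", positive,
                                           "' not among label values")
  structure(list(x = x, y = y, feature_names = colnames(x),
                 label_name = label_name, positive = positive),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table: ", nrow(x$x), " samples x ", ncol(x$x), " features\n",
      sep = "")
  cat("Labels (", x$label_name, "): ",
      paste(sprintf("%s=%d", levels(x$y), tabulate(x$y)), collapse = ", "),
      "; positive = ", x$positive, "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' Read a feature table from delimited text
#'
#' Reads a CSV/TSV file with a header row, coerces every non-label column
#' to numeric, and validates the label column has exactly two values.
#' Missing or non-numeric cells are rejected with the offending row and
#' column named.
#'
#' @param path Path to the file.
#' @param label_col Name of the label column (must appear in the header).
#' @param delimiter Field delimiter, `","` or `"\t"` (also accepts the
#'   words `"comma"` and `"tab"`).
#' @param positive Optional positive-class label; see [feature_table()].
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, label_col = "label", delimiter = ",",
                               positive = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  delimiter <- switch(delimiter, comma = ",", tab = "\t", delimiter)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(df))) stop_input("duplicate column headers in ", path)
  if (!label_col %in% names(df)) {
    stop_input("label column '", label_col, "' not found; headers: ",
               paste(utils::head(names(df), 10), collapse = ", "))
  }
  labels <- df[[label_col]]
  feats <- df[names(df) != label_col]
  for (nm in names(feats)) {
    v <- suppressWarnings(as.numeric(feats[[nm]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop_input("non-numeric or missing cell at row ", bad[1],
                 ", column '", nm, "'")
    }
    feats[[nm]] <- v
  }
  feature_table(as.matrix(feats), labels, label_name = label_col,
                positive = positive)
}

#' Write a feature table to delimited text
#'
#' Inverse of [read_feature_table()]: the label column is appended last
#' under the table's `label_name`, full precision is kept so a written
#' table re-reads bit-identically.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "feature_table"))
  delimiter <- switch(delimiter, comma = ",", tab = "\t", delimiter)
  df <- as.data.frame(table$x, check.names = FALSE)
  df[[table$label_name]] <- as.character(table$y)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Masked view used by the wrapper fitness: keep the selected columns only.
mask_table <- function(table, mask) {
  bits <- if (inherits(mask, "feature_mask")) mask$bits else as.integer(mask)
  if (length(bits) != ncol(table$x)) {
    stop_input("mask length (", length(bits), ") does not match feature count (",
               ncol(table$x), ")")
  }
  keep <- which(bits == 1L)
  list(x = table$x[, keep, drop = FALSE], y = table$y, keep = keep)
}
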