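#' Fit a column-wise min-max normalizer
#'
#' Records, for every feature column, its observed minimum and maximum and
#' the target interval. Applying the fitted spec rescales each value `V`
#' affinely:
#' \deqn{NewValue = new\_min + \frac{V - MinX}{MaxX - MinX}(new\_max - new\_min)}
#' so observed minima map to `new_min` and observed maxima to `new_max`.
#'
#' By default the spec is fitted on the full table (the convention for
#' these feature-selection pipelines); fit it on the training rows only and
#' apply with `clip = TRUE` if leakage hygiene matters for your protocol.
#'
#' @param table A [feature_table()] or numeric matrix.
#' @param new_min,new_max Target interval bounds, `new_min < new_max`.
#' @return An object of class `minmax_spec` with fields `new_min`,
#'   `new_max`, `per_column_min`, `per_column_max`, `feature_names`.
#' @seealso [apply_minmax()]
#' @export
fit_minmax <- function(table, new_min = 0, new_max = 1) {
  if (!is.numeric(new_min) || !is.numeric(new_max) || new_min >= new_max) {
    stop_config("require new_min < new_max, got (", new_min, ", ", new_max, ")")
  }
  x <- if (inherits(table, "feature_table")) table$x else as.matrix(table)
  if (nrow(x) < 1L || ncol(x) < 1L) stop_input("need >= 1 sample and >= 1 feature")
  if (any(!is.finite(x))) {
    idx <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop_input("non-finite cell at row ", idx[1], ", column ",
               colnames(x)[idx[2]] %||% idx[2])
  }
  structure(list(new_min = new_min, new_max = new_max,
                 per_column_min = apply(x, 2, min),
                 per_column_max = apply(x, 2, max),
                 feature_names = colnames(x)),
            class = "minmax_spec")
}

#' Apply a fitted min-max normalizer
#'
#' Rescales every feature column of `table` into the spec's target
#' interval. Labels pass through untouched. Constant columns (observed
#' `MaxX = MinX`, where the affine map is undefined) map to `new_min` with
#' a warning. Values outside the fitted range -- possible when the spec was
#' fitted on a training subset -- are clipped to the target interval when
#' `clip = TRUE`, which keeps downstream sigmoid inputs bounded.
#'
#' @param spec A `minmax_spec` from [fit_minmax()].
#' @param table A [feature_table()] or numeric matrix with the same columns
#'   the spec was fitted on.
#' @param clip Clip out-of-range values into the target interval.
#' @return Same type as `table`, rescaled.
#' @export
apply_minmax <- function(spec, table, clip = FALSE) {
  stopifnot(inherits(spec, "minmax_spec"))
  is_ft <- inherits(table, "feature_table")
  x <- if (is_ft) table$x else as.matrix(table)
  if (ncol(x) != length(spec$per_column_min) ||
      (!is.null(spec$feature_names) && !is.null(colnames(x)) &&
       !identical(colnames(x), spec$feature_names))) {
    stop_config("table columns do not match the columns the spec was fitted on")
  }
  rng <- spec$per_column_max - spec$per_column_min
  const <- rng == 0
  if (any(const)) {
    warning("constant column(s) mapped to new_min: ",
            paste(colnames(x)[const] %||% which(const), collapse = ", "))
  }
  scale <- ifelse(const, 0, (spec$new_max - spec$new_min) / ifelse(const, 1, rng))
  out <- sweep(x, 2, spec$per_column_min, "-")
  out <- sweep(out, 2, scale, "*") + spec$new_min
  if (clip) out <- pmin(pmax(out, spec$new_min), spec$new_max)
  if (is_ft) { table$x <- out; table } else out
}

#' Min-max normalize a feature table in one step
#'
#' Convenience wrapper: fit on `table`, apply to `table`.
#'
#' @inheritParams fit_minmax
#' @return A list with the normalized `table` and the fitted `spec`.
#' @export
minmax_normalize <- function(table, new_min = 0, new_max = 1) {
  spec <- fit_minmax(table, new_min, new_max)
  list(table = apply_minmax(spec, table), spec = spec)
}

#' @export
print.minmax_spec <- function(x, ...) {
  cat("Min-max normalization spec: ", length(x$per_column_min),
      " columns -> [", x$new_min, ", ", x$new_max, "]\n", sep = "")
  invisible(x)
}
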