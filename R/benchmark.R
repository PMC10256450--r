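#' Compare classifiers with and without a feature mask
#'
#' Evaluates a set of classifiers on the full feature set and, when a
#' mask is supplied, on the selected subset, under a common frozen split.
#' Produces the comparison table usually reported alongside wrapper
#' feature selection: one row per classifier x feature-set combination
#' with the four diagnostic metrics.
#'
#' @param table A [feature_table()].
#' @param mask Optional [feature_mask()] (or 0/1 vector); when supplied,
#'   each classifier is also evaluated on the masked subset.
#' @param classifiers Character vector of classifier names (see
#'   [classifier_spec()]).
#' @param config A [fitness_config()] supplying the evaluation protocol.
#' @param seed Seed for stochastic classifiers.
#' @return A data frame with columns `classifier`, `features`
#'   (`"all"`/`"selected"`), `n_features`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
benchmark_classifiers <- function(table, mask = NULL,
                                  classifiers = c("dt", "knn", "nb"),
                                  config = fitness_config(), seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  split <- make_split(table$y, config)
  full <- feature_mask(rep(1L, ncol(table$x)))
  sets <- list(all = full)
  if (!is.null(mask)) {
    if (!inherits(mask, "feature_mask")) mask <- feature_mask(mask)
    sets$selected <- mask
  }
  rows <- list()
  for (cname in classifiers) {
    spec <- classifier_spec(cname, seed = derive_seed(seed, 7))
    for (set_name in names(sets)) {
      rep_ <- evaluate_mask(table, sets[[set_name]], spec, config, split)
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = cname, features = set_name,
        n_features = sets[[set_name]]$n_selected,
        accuracy = rep_$accuracy, precision = rep_$precision,
        recall = rep_$recall, f1 = rep_$f1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
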