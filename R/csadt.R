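#' Crow-search feature selection with a decision-tree wrapper (CSADT)
#'
#' Fits the complete pipeline on a binary-labelled feature table:
#' column-wise min-max normalization, crow search over continuous
#' positions, sigmoid/random-threshold binarization into feature masks,
#' and a classifier-error wrapper fitness
#' `alpha * error + beta * |R|/|N|` minimised on a frozen stratified
#' split. After selection the classifier is refitted on all samples
#' restricted to the selected features, so the returned object can
#' predict on new data.
#'
#' All randomness derives from `seed`: the train/evaluation split, the
#' optimizer stream (positions, follow/escape draws, binarization
#' thresholds) and any stochastic classifier each get a distinct derived
#' child seed, so runs are bit-reproducible.
#'
#' @param formula Model formula, e.g. `status ~ .`; the response is the
#'   two-valued class label.
#' @param data Data frame holding the label and numeric feature columns.
#' @param normalize Min-max normalize features into `range` before
#'   searching (recommended; the sigmoid adapter assumes bounded inputs).
#' @param range Length-2 target interval for normalization.
#' @param crows,iterations,flight_length,awareness_prob,bound CSA
#'   parameters; positions live in `[-bound, bound]^d`. See
#'   [csa_config()].
#' @param alpha,beta Fitness weights, `alpha + beta = 1`. See
#'   [fitness_config()].
#' @param protocol,holdout_fraction,n_folds Evaluation protocol of the
#'   wrapper fitness.
#' @param classifier Inner classifier name or a [classifier_spec()].
#' @param direction Transfer-rule direction, see [binarize()].
#' @param empty_mask_policy `"penalty"` or `"repair"`, see
#'   [fitness_config()].
#' @param positive Positive-class label (defaults to the
#'   lexicographically larger level).
#' @param seed Integer master seed.
#' @param verbose Log per-iteration best fitness.
#'
#' @return An object of class `csadt`: the selection result, the holdout
#'   evaluation report of the selected subset, the normalization spec, the
#'   refitted final classifier, and the resolved configuration. Methods:
#'   `print`, `summary`, `coef` (0/1 mask named by feature),
#'   `predict`, `plot` (fitness-history trace).
#'
#' @examples
#' g <- generate_synth(n_samples = 120, n_informative = 3, n_noise = 7,
#'                     class_separation = 3, seed = 2)
#' df <- as.data.frame(g$table$x)
#' df$label <- g$table$y
#' fit <- csadt(label ~ ., df, crows = 10, iterations = 20, seed = 2)
#' fit
#' coef(fit)
#' @export
csadt <- function(formula, data, normalize = TRUE, range = c(0, 1),
                  crows = 20, iterations = 100, flight_length = 2,
                  awareness_prob = 0.1, bound = 4,
                  alpha = 0.99, beta = 0.01,
                  protocol = c("holdout", "kfold"), holdout_fraction = 0.2,
                  n_folds = 5, classifier = "dt",
                  direction = c("paper", "standard"),
                  empty_mask_policy = c("penalty", "repair"),
                  positive = NULL, seed = 1, verbose = FALSE) {
  cl <- match.call()
  protocol <- match.arg(protocol)
  direction <- match.arg(direction)
  empty_mask_policy <- match.arg(empty_mask_policy)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  feats <- mf[-1L]
  if (!all(vapply(feats, is.numeric, logical(1)))) {
    stop_input("all feature columns must be numeric")
  }
  table <- feature_table(as.matrix(feats), y, positive = positive,
                         label_name = deparse(formula[[2]]))
  norm_spec <- NULL
  if (normalize) {
    norm_spec <- fit_minmax(table, range[1], range[2])
    table <- apply_minmax(norm_spec, table)
  }
  if (!inherits(classifier, "classifier_spec")) {
    classifier <- classifier_spec(classifier, seed = derive_seed(seed, 3))
  }
  fit_cfg <- fitness_config(alpha = alpha, beta = beta,
                            eval_protocol = protocol,
                            holdout_fraction = holdout_fraction,
                            n_folds = n_folds,
                            split_seed = derive_seed(seed, 1),
                            empty_mask_policy = empty_mask_policy)
  csa_cfg <- csa_config(n_dims = ncol(table$x), n_crows = crows,
                        iter_max = iterations,
                        flight_length = flight_length,
                        awareness_prob = awareness_prob,
                        lower_bound = -bound, upper_bound = bound,
                        seed = derive_seed(seed, 2))
  sel <- select_features(table, csa_cfg, fit_cfg, classifier, direction,
                         verbose = verbose)
  report <- evaluate_mask(table, sel$mask, classifier, fit_cfg,
                          split = sel$split)
  final_fit <- fit_classifier(classifier,
                              mask_table(table, sel$mask)$x, table$y)
  structure(list(call = cl, selection = sel, report = report,
                 norm_spec = norm_spec, final_fit = final_fit,
                 feature_names = table$feature_names,
                 levels = levels(table$y), positive = table$positive,
                 seed = seed, n_samples = nrow(table$x)),
            class = "csadt")
}

#' Evaluate a feature mask on the held-out partition
#'
#' Trains the classifier on the training partition restricted to the
#' selected features, predicts the evaluation partition, and returns the
#' confusion counts with accuracy, precision, recall and F1 (for k-fold,
#' counts are pooled across folds).
#'
#' @inheritParams evaluate_error_rate
#' @return An `eval_report` (see [compute_metrics()]).
#' @export
evaluate_mask <- function(table, mask, classifier = classifier_spec("dt"),
                          config = fitness_config(), split = NULL) {
  stopifnot(inherits(table, "feature_table"))
  masked <- mask_table(table, mask)
  if (length(masked$keep) == 0L) stop_input("empty mask: no features selected")
  if (is.null(split)) split <- make_split(table$y, config)
  pool_truth <- character(0)
  pool_pred <- character(0)
  folds <- if (split$type == "holdout") list(split$test) else {
    lapply(seq_len(max(split$fold)), function(k) which(split$fold == k))
  }
  for (test in folds) {
    train <- setdiff(seq_along(table$y), test)
    fit <- fit_classifier(classifier, masked$x[train, , drop = FALSE],
                          table$y[train])
    pred <- predict_classifier(fit, masked$x[test, , drop = FALSE])
    pool_truth <- c(pool_truth, as.character(table$y[test]))
    pool_pred <- c(pool_pred, as.character(pred))
  }
  classification_report(pool_truth, pool_pred, table$positive)
}

#' @export
print.csadt <- function(x, ...) {
  cat("CSADT feature selection\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat("Selected ", x$selection$mask$n_selected, " of ",
      length(x$selection$mask$bits), " features\n", sep = "")
  cat(sprintf("Fitness %.6g (error %.4f, subset ratio %.4f)\n",
              x$selection$fitness$total, x$selection$fitness$error_rate,
              x$selection$fitness$subset_ratio))
  cat(sprintf("Holdout: accuracy %.4f, F1 %.4f (positive = %s)\n",
              x$report$accuracy, x$report$f1, x$positive))
  invisible(x)
}

#' @export
summary.csadt <- function(object, ...) {
  structure(list(fit = object), class = "summary.csadt")
}

#' @export
print.summary.csadt <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nSelected features:\n")
  print(f$selection$selected)
  h <- f$selection$history
  cat(sprintf("\nFitness history: start %.6g -> end %.6g over %d iterations (%d evaluations)\n",
              h[1], h[length(h)], length(h), f$selection$n_evals))
  r <- f$report
  cat("Holdout confusion: TP=", r$counts$tp, " TN=", r$counts$tn,
      " FP=", r$counts$fp, " FN=", r$counts$fn, "\n", sep = "")
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
              r$accuracy, r$precision, r$recall, r$f1))
  invisible(x)
}

#' @export
coef.csadt <- function(object, ...) {
  stats::setNames(object$selection$mask$bits, object$feature_names)
}

#' @export
predict.csadt <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  if (!is.null(object$norm_spec)) {
    x <- apply_minmax(object$norm_spec, x, clip = TRUE)
  }
  keep <- which(object$selection$mask$bits == 1L)
  predict_classifier(object$final_fit, x[, keep, drop = FALSE])
}

#' @export
plot.csadt <- function(x, ...) {
  h <- x$selection$history
  graphics::plot(seq_along(h), h, type = "s", xlab = "Iteration",
                 ylab = "Best fitness",
                 main = "CSADT best-fitness trace", ...)
  invisible(x)
}
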