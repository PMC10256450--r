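#' Wrapper-fitness configuration
#'
#' Everything the feature-selection objective needs beyond the mask
#' itself: the weights of the two fitness terms, the evaluation protocol,
#' and the empty-mask policy. The fitness of a mask `R` over a dataset
#' `D` with `|N|` features is
#' \deqn{Fitness = \alpha \, \gamma_R(D) + \beta \, |R| / |N|}
#' where `gamma_R(D)` is the classifier error rate on the evaluation
#' partition using only the selected features, and `|R|/|N|` is the
#' selected-feature fraction. Lower is better: the objective trades
#' classification quality against parsimony.
#'
#' @param alpha Weight of the error-rate term, in `[0, 1]`. The default
#'   0.99 makes classification quality dominate, the usual convention in
#'   wrapper feature selection.
#' @param beta Weight of the subset-size term; `alpha + beta` must equal 1.
#' @param eval_protocol `"holdout"` (single stratified split, the
#'   default — a frozen split makes the objective deterministic, which the
#'   optimizer's monotone-history guarantee requires) or `"kfold"`
#'   (mean error across stratified folds).
#' @param holdout_fraction Fraction of samples held out for evaluation.
#' @param n_folds Number of folds for the k-fold protocol.
#' @param stratified Stratify splits by class (keeps both classes present
#'   in every partition).
#' @param split_seed Seed for the split; shared across every fitness
#'   evaluation in a run so all masks are compared on identical splits.
#' @param empty_mask_policy `"penalty"` scores an all-zero mask at the
#'   worst possible fitness (`alpha + beta = 1`) without training;
#'   `"repair"` sets one random bit instead (see [guard_nonempty()]).
#' @return An object of class `fitness_config`.
#' @export
fitness_config <- function(alpha = 0.99, beta = 0.01,
                           eval_protocol = c("holdout", "kfold"),
                           holdout_fraction = 0.2, n_folds = 5,
                           stratified = TRUE, split_seed = 1,
                           empty_mask_policy = c("penalty", "repair")) {
  eval_protocol <- match.arg(eval_protocol)
  empty_mask_policy <- match.arg(empty_mask_policy)
  if (alpha < 0 || alpha > 1 || beta < 0 || beta > 1) {
    stop_config("alpha and beta must lie in [0, 1]")
  }
  if (abs(alpha + beta - 1) > 1e-9) {
    stop_config("alpha + beta must equal 1, got ", alpha + beta)
  }
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop_config("holdout_fraction must lie in (0, 1)")
  }
  if (n_folds < 2) stop_config("n_folds must be >= 2")
  structure(list(alpha = alpha, beta = beta, eval_protocol = eval_protocol,
                 holdout_fraction = holdout_fraction,
                 n_folds = as.integer(n_folds), stratified = stratified,
                 split_seed = as.integer(split_seed),
                 empty_mask_policy = empty_mask_policy),
            class = "fitness_config")
}

#' Specify the inner classifier
#'
#' The wrapper fitness is classifier-agnostic; the decision tree is the
#' default (and the classifier the method is defined with), others are
#' available for benchmark-style comparisons. All classifiers are fitted
#' with deterministic settings or an explicit seed so the wrapper
#' objective stays reproducible; the decision tree in particular runs with
#' internal cross-validation disabled (`xval = 0`), which also makes the
#' fit consume no randomness.
#'
#' @param name One of `"dt"` (decision tree, rpart), `"knn"`, `"nb"`
#'   (naive Bayes), `"mlp"` (single-hidden-layer network), `"svm_linear"`,
#'   `"svm_rbf"`, `"rf"` (random forest). Classifiers other than `"dt"`
#'   require the corresponding suggested package (class, e1071, nnet,
#'   randomForest).
#' @param seed Seed for classifiers with stochastic fitting (mlp, rf).
#' @param ... Hyperparameters passed to the underlying fitter (e.g.
#'   `k` for knn, `size` for mlp, `cp`/`minsplit` for the tree).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("dt", "knn", "nb", "mlp", "svm_linear",
                                     "svm_rbf", "rf"),
                            seed = 0, ...) {
  name <- match.arg(name)
  structure(list(name = name, seed = as.integer(seed), params = list(...)),
            class = "classifier_spec")
}

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop_config("classifier requires the '", pkg, "' package")
  }
}

# Fit/predict behind neutral column names so arbitrary feature names never
# break formula interfaces.
fit_classifier <- function(spec, x, y) {
  colnames(x) <- paste0("X", seq_len(ncol(x)))
  df <- data.frame(x, check.names = FALSE)
  df$.y <- y
  p <- spec$params
  model <- switch(spec$name,
    dt = rpart::rpart(.y ~ ., data = df, method = "class",
                      control = do.call(rpart::rpart.control,
                                        c(list(xval = 0), p))),
    knn = { need_pkg("class"); list(x = x, y = y, k = p$k %||% 5L) },
    nb = { need_pkg("e1071"); e1071::naiveBayes(x, y) },
    mlp = {
      need_pkg("nnet")
      with_seed(spec$seed,
                nnet::nnet(x, class.ind(y), size = p$size %||% 8L,
                           softmax = TRUE, trace = FALSE,
                           maxit = p$maxit %||% 200L,
                           MaxNWts = 1e5))
    },
    svm_linear = { need_pkg("e1071"); e1071::svm(x, y, kernel = "linear") },
    svm_rbf = { need_pkg("e1071"); e1071::svm(x, y, kernel = "radial") },
    rf = {
      need_pkg("randomForest")
      with_seed(spec$seed,
                randomForest::randomForest(x, y,
                                           ntree = p$ntree %||% 200L))
    })
  list(spec = spec, model = model, levels = levels(y))
}

class.ind <- function(y) {
  m <- stats::model.matrix(~ y - 1)
  colnames(m) <- levels(y)
  m
}

predict_classifier <- function(fit, x) {
  colnames(x) <- paste0("X", seq_len(ncol(x)))
  df <- data.frame(x, check.names = FALSE)
  out <- switch(fit$spec$name,
    dt = as.character(predict(fit$model, newdata = df, type = "class")),
    knn = as.character(class::knn(fit$model$x, x, fit$model$y,
                                  k = fit$model$k)),
    nb = as.character(predict(fit$model, x)),
    mlp = fit$levels[max.col(predict(fit$model, x), ties.method = "first")],
    svm_linear = as.character(predict(fit$model, x)),
    svm_rbf = as.character(predict(fit$model, x)),
    rf = as.character(predict(fit$model, x)))
  factor(out, levels = fit$levels)
}

#' Build a frozen train/evaluation split
#'
#' Stratified holdout or stratified k-fold assignment, determined entirely
#' by `split_seed`. Computed once per selection run and reused for every
#' fitness evaluation, so different masks are always compared on the same
#' partitions.
#'
#' @param y Two-level factor of class labels.
#' @param config A [fitness_config()].
#' @return For holdout, `list(type = "holdout", test = <indices>)`; for
#'   k-fold, `list(type = "kfold", fold = <assignment vector>)`.
#' @export
make_split <- function(y, config) {
  stopifnot(inherits(config, "fitness_config"))
  y <- factor(y)
  n <- length(y)
  with_seed(config$split_seed, {
    if (config$eval_protocol == "holdout") {
      test <- integer(0)
      groups <- if (config$stratified) split(seq_len(n), y) else list(seq_len(n))
      for (idx in groups) {
        n_test <- max(1L, round(config$holdout_fraction * length(idx)))
        if (n_test >= length(idx)) {
          stop_input("too few samples in a class to hold out ",
                     config$holdout_fraction, " of them; use stratified ",
                     "splitting or more samples")
        }
        test <- c(test, sample(idx, n_test))
      }
      split <- list(type = "holdout", test = sort(test))
      check_both_classes(y, split)
      split
    } else {
      fold <- integer(n)
      groups <- if (config$stratified) split(seq_len(n), y) else list(seq_len(n))
      for (idx in groups) {
        fold[sample(idx)] <- rep_len(seq_len(config$n_folds), length(idx))
      }
      list(type = "kfold", fold = fold)
    }
  })
}

check_both_classes <- function(y, split) {
  train <- setdiff(seq_along(y), split$test)
  if (nlevels(droplevels(y[train])) < 2L || nlevels(droplevels(y[split$test])) < 2L) {
    stop_input("a partition contains a single class; use stratified ",
               "splitting (stratified = TRUE) or a different split seed")
  }
  invisible(TRUE)
}

#' Classifier error rate on a masked feature subset
#'
#' Trains the classifier on the training partition restricted to the
#' selected columns and returns `1 - accuracy` on the evaluation partition
#' (or the mean across folds). This is the `gamma_R(D)` term of the
#' wrapper fitness.
#'
#' @param table A [feature_table()].
#' @param mask A [feature_mask()] (or 0/1 vector) with at least one bit
#'   set.
#' @param classifier A [classifier_spec()].
#' @param config A [fitness_config()].
#' @param split Optional precomputed [make_split()] result; built from
#'   `config$split_seed` when `NULL`.
#' @return Error rate in `[0, 1]`.
#' @export
evaluate_error_rate <- function(table, mask,
                                classifier = classifier_spec("dt"),
                                config = fitness_config(), split = NULL) {
  stopifnot(inherits(table, "feature_table"))
  masked <- mask_table(table, mask)
  if (length(masked$keep) == 0L) stop_input("empty mask: no features selected")
  if (is.null(split)) split <- make_split(table$y, config)
  if (split$type == "holdout") {
    test <- split$test
    train <- setdiff(seq_along(table$y), test)
    fit <- fit_classifier(classifier, masked$x[train, , drop = FALSE],
                          table$y[train])
    pred <- predict_classifier(fit, masked$x[test, , drop = FALSE])
    mean(pred != table$y[test])
  } else {
    errs <- vapply(seq_len(max(split$fold)), function(k) {
      test <- which(split$fold == k)
      train <- which(split$fold != k)
      fit <- fit_classifier(classifier, masked$x[train, , drop = FALSE],
                            table$y[train])
      pred <- predict_classifier(fit, masked$x[test, , drop = FALSE])
      mean(pred != table$y[test])
    }, numeric(1))
    mean(errs)
  }
}

#' Wrapper fitness of a feature mask
#'
#' Scores a mask directly (without binarization):
#' `alpha * error_rate + beta * n_selected / n_features`. An empty mask
#' under the penalty policy scores `alpha + beta` (the worst value) with
#' no classifier trained.
#'
#' @inheritParams evaluate_error_rate
#' @return An object of class `fitness_value`: `total`, `error_rate`,
#'   `subset_ratio`, `mask`.
#' @export
mask_fitness <- function(mask, table, classifier = classifier_spec("dt"),
                         config = fitness_config(), split = NULL) {
  if (!inherits(mask, "feature_mask")) mask <- feature_mask(mask)
  d <- ncol(table$x)
  if (mask$n_selected == 0L) {
    if (config$empty_mask_policy == "repair") {
      mask <- guard_nonempty(mask)
    } else {
      return(structure(list(total = config$alpha + config$beta,
                            error_rate = NA_real_, subset_ratio = 0,
                            mask = mask),
                       class = "fitness_value"))
    }
  }
  err <- evaluate_error_rate(table, mask, classifier, config, split)
  structure(list(total = config$alpha * err +
                   config$beta * mask$n_selected / d,
                 error_rate = err,
                 subset_ratio = mask$n_selected / d,
                 mask = mask),
            class = "fitness_value")
}

#' Wrapper fitness of a continuous position
#'
#' The full objective the optimizer minimises: binarize the position into
#' a mask (consuming one RNG draw per dimension), apply the empty-mask
#' policy, then score the mask with [mask_fitness()].
#'
#' @param position Numeric vector, one coordinate per feature column.
#' @param direction Transfer-rule direction, see [binarize()].
#' @inheritParams mask_fitness
#' @return A `fitness_value`.
#' @export
fs_fitness <- function(position, table, classifier = classifier_spec("dt"),
                       config = fitness_config(), split = NULL,
                       direction = c("paper", "standard")) {
  direction <- match.arg(direction)
  if (length(position) != ncol(table$x)) {
    stop_input("position length (", length(position),
               ") must equal the feature count (", ncol(table$x), ")")
  }
  mask <- binarize(position, direction)
  mask_fitness(mask, table, classifier, config, split)
}

#' @export
print.fitness_value <- function(x, ...) {
  if (is.na(x$error_rate)) {
    cat("Fitness", format(x$total, digits = 6), "(empty mask, penalty)\n")
  } else {
    cat(sprintf("Fitness %.6g = error %.4f + subset ratio %.4f (%d features)\n",
                x$total, x$error_rate, x$subset_ratio, x$mask$n_selected))
  }
  invisible(x)
}

#' Select features with the crow search algorithm
#'
#' The complete wrapper pipeline: run the continuous crow search over
#' `[lower_bound, upper_bound]^d`, binarizing every evaluated position
#' into a feature mask and scoring it with the decision-tree (or other
#' classifier) wrapper fitness on a frozen split. Returns the best mask
#' ever evaluated — recorded at evaluation time, so the reported mask and
#' fitness are exactly the pair the optimizer saw.
#'
#' Most users will prefer the [csadt()] modelling interface, which wraps
#' this together with normalization and a final refit.
#'
#' @param table A [feature_table()] (normalize first, or accept raw scale).
#' @param csa A [csa_config()] with `n_dims` equal to the feature count;
#'   built with defaults when `NULL`.
#' @param config A [fitness_config()].
#' @param classifier A [classifier_spec()].
#' @param direction Transfer-rule direction, see [binarize()].
#' @param verbose Log per-iteration best fitness.
#' @return An object of class `selection_result`: `mask`
#'   (a [feature_mask()]), `fitness` (a `fitness_value`),
#'   `selected` (column names), `history`, `n_evals`, `split`, and the
#'   configs used.
#' @export
select_features <- function(table, csa = NULL, config = fitness_config(),
                            classifier = classifier_spec("dt"),
                            direction = c("paper", "standard"),
                            verbose = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  direction <- match.arg(direction)
  d <- ncol(table$x)
  if (is.null(csa)) csa <- csa_config(n_dims = d)
  if (csa$n_dims != d) {
    stop_config("csa$n_dims (", csa$n_dims, ") must equal the feature count (",
                d, ")")
  }
  split <- make_split(table$y, config)
  tracker <- new.env(parent = emptyenv())
  tracker$best <- Inf
  tracker$fv <- NULL
  objective <- function(position) {
    fv <- fs_fitness(position, table, classifier, config, split, direction)
    if (fv$total < tracker$best) {
      tracker$best <- fv$total
      tracker$fv <- fv
    }
    fv$total
  }
  res <- run_csa(objective, csa, verbose = verbose)
  fv <- tracker$fv
  structure(list(mask = fv$mask, fitness = fv,
                 selected = table$feature_names[fv$mask$bits == 1L],
                 history = res$history, n_evals = res$n_evals,
                 best_position = res$par, split = split,
                 csa_config = csa, fitness_config = config,
                 classifier = classifier, direction = direction),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("CSA feature selection: ", x$mask$n_selected, "/",
      length(x$mask$bits), " features selected\n", sep = "")
  print(x$fitness)
  cat("Objective evaluations:", x$n_evals, "\n")
  invisible(x)
}
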