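test_that("fitness configuration enforces its weight and protocol invariants", {
  expect_error(fitness_config(alpha = 0.9, beta = 0.2),
               class = "csadt_config_error")
  expect_error(fitness_config(alpha = 1.2, beta = -0.2),
               class = "csadt_config_error")
  expect_error(fitness_config(holdout_fraction = 0),
               class = "csadt_config_error")
  cfg <- fitness_config(alpha = 0.95, beta = 0.05)
  expect_equal(cfg$alpha + cfg$beta, 1)
})

test_that("splits are frozen, stratified, and keep both classes", {
  y <- factor(rep(c("a", "b"), c(30, 10)))
  cfg <- fitness_config(split_seed = 5)
  s1 <- make_split(y, cfg)
  s2 <- make_split(y, cfg)
  expect_identical(s1, s2)
  expect_equal(length(s1$test), 0.2 * 30 + 0.2 * 10)
  expect_true(all(table(y[s1$test]) >= 1))
  expect_true(all(table(y[-s1$test]) >= 1))

  kcfg <- fitness_config(eval_protocol = "kfold", n_folds = 4, split_seed = 5)
  ks <- make_split(y, kcfg)
  expect_equal(sort(unique(ks$fold)), 1:4)
  for (k in 1:4) expect_true(all(table(y[ks$fold == k]) >= 1))

  tiny <- factor(c("a", "a", "b"))
  expect_error(make_split(tiny, fitness_config(holdout_fraction = 0.5)),
               class = "csadt_input_error")
})

test_that("error rate hits the separable and permutation-null limits", {
  tab <- make_separable_table(n = 80, d = 3, sep = 6, seed = 1)
  full <- feature_mask(rep(1, 3))
  err <- evaluate_error_rate(tab, full, config = fitness_config(split_seed = 2))
  expect_equal(err, 0)

  # shuffled labels: chance-level error across split seeds
  shuf <- tab
  shuf$y <- withr::with_seed(10, sample(tab$y))
  errs <- vapply(1:20, function(s) {
    evaluate_error_rate(shuf, full, config = fitness_config(split_seed = s))
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.1)
})

test_that("informative columns beat pure-noise columns almost always", {
  wins <- 0L
  for (s in 1:10) {
    g <- generate_synth(n_samples = 150, n_informative = 3, n_noise = 3,
                        class_separation = 3, seed = s)
    cfg <- fitness_config(split_seed = s)
    err_inf <- evaluate_error_rate(g$table, feature_mask(c(1, 1, 1, 0, 0, 0)),
                                   config = cfg)
    err_noise <- evaluate_error_rate(g$table, feature_mask(c(0, 0, 0, 1, 1, 1)),
                                     config = cfg)
    if (err_noise >= err_inf) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("the objective combines error and subset size as the formula says", {
  tab <- make_separable_table(n = 80, d = 5, sep = 6, seed = 3)
  cfg <- fitness_config(alpha = 0.99, beta = 0.01, split_seed = 4)
  fv <- mask_fitness(feature_mask(rep(1, 5)), tab, config = cfg)
  expect_equal(fv$error_rate, 0)
  expect_equal(fv$subset_ratio, 1)
  expect_equal(fv$total, 0.01, tolerance = 1e-12) # beta alone

  # 1 of 10 features, zero error: total = 0.99*0 + 0.01*0.1 = 0.001
  tab10 <- make_separable_table(n = 80, d = 10, sep = 8, seed = 6)
  fv1 <- mask_fitness(feature_mask(c(1, rep(0, 9))), tab10, config = cfg)
  expect_equal(fv1$error_rate, 0)
  expect_equal(fv1$total, 0.001, tolerance = 1e-12)

  # identity total = alpha*error + beta*ratio holds in general
  g <- generate_synth(n_samples = 100, n_informative = 2, n_noise = 4,
                      class_separation = 1, seed = 9)
  fvg <- mask_fitness(feature_mask(c(1, 0, 1, 1, 0, 0)), g$table, config = cfg)
  expect_equal(fvg$total, 0.99 * fvg$error_rate + 0.01 * 0.5,
               tolerance = 1e-12)
})

test_that("empty masks follow the configured policy", {
  tab <- make_separable_table(n = 60, d = 4, sep = 6, seed = 2)
  pen <- fitness_config(split_seed = 1, empty_mask_policy = "penalty")
  fv <- mask_fitness(feature_mask(rep(0, 4)), tab, config = pen)
  expect_equal(fv$total, 1)
  expect_true(is.na(fv$error_rate))

  rep_cfg <- fitness_config(split_seed = 1, empty_mask_policy = "repair")
  fvr <- withr::with_seed(5, mask_fitness(feature_mask(rep(0, 4)), tab,
                                          config = rep_cfg))
  expect_equal(fvr$mask$n_selected, 1L)
  expect_false(is.na(fvr$error_rate))

  expect_error(evaluate_error_rate(tab, feature_mask(rep(0, 4))),
               class = "csadt_input_error")
})

test_that("fitness is monotone in error rate and subset size", {
  cfg <- fitness_config(alpha = 0.9, beta = 0.1)
  total <- function(err, k, d) cfg$alpha * err + cfg$beta * k / d
  errs <- seq(0, 1, by = 0.1)
  expect_true(all(diff(vapply(errs, total, numeric(1), k = 3, d = 10)) > 0))
  ks <- 0:10
  expect_true(all(diff(vapply(ks, function(k) total(0.3, k, 10),
                              numeric(1))) > 0))
  # bounds: fitness in [0, 1] whenever alpha + beta = 1
  expect_true(all(outer(errs, ks / 10,
                        function(e, r) 0.99 * e + 0.01 * r) <= 1))
})

test_that("position-level fitness binarizes then scores, deterministically", {
  tab <- make_separable_table(n = 60, d = 4, sep = 6, seed = 8)
  cfg <- fitness_config(split_seed = 3)
  pos <- c(-5, -5, 5, 5) # printed rule selects the negative coordinates
  fv1 <- withr::with_seed(2, fs_fitness(pos, tab, config = cfg))
  fv2 <- withr::with_seed(2, fs_fitness(pos, tab, config = cfg))
  expect_identical(fv1, fv2)
  expect_equal(fv1$mask$bits[1:2], c(1L, 1L))
  expect_error(fs_fitness(c(1, 2), tab, config = cfg),
               class = "csadt_input_error")
})

test_that("selection returns the best mask it actually evaluated", {
  g <- generate_synth(n_samples = 100, n_informative = 2, n_noise = 4,
                      class_separation = 4, seed = 12)
  tab <- minmax_normalize(g$table)$table
  sel <- select_features(tab,
                         csa_config(n_dims = 6, n_crows = 8, iter_max = 25,
                                    seed = 12),
                         fitness_config(split_seed = 13))
  expect_s3_class(sel, "selection_result")
  expect_equal(sel$fitness$total, min(sel$history))
  expect_true(all(diff(sel$history) <= 0))
  expect_equal(sel$n_evals, 8 * 26)
  expect_setequal(sel$selected,
                  tab$feature_names[sel$mask$bits == 1L])
  # re-scoring the returned mask on the frozen split reproduces the fitness
  fv <- mask_fitness(sel$mask, tab, config = sel$fitness_config,
                     split = sel$split)
  expect_equal(fv$total, sel$fitness$total, tolerance = 1e-12)

  sel2 <- select_features(tab,
                          csa_config(n_dims = 6, n_crows = 8, iter_max = 25,
                                     seed = 12),
                          fitness_config(split_seed = 13))
  expect_identical(sel$mask, sel2$mask)
  expect_identical(sel$history, sel2$history)
})

test_that("a single-feature table always returns the one usable mask", {
  g <- generate_synth(n_samples = 60, n_informative = 1, n_noise = 0,
                      class_separation = 4, seed = 3)
  sel <- select_features(g$table,
                         csa_config(n_dims = 1, n_crows = 4, iter_max = 10,
                                    seed = 3),
                         fitness_config(split_seed = 3))
  expect_equal(sel$mask$bits, 1L)
})
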