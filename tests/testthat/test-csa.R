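test_that("flock initialisation respects bounds and memory mirrors positions", {
  cfg <- csa_config(n_dims = 3, n_crows = 5, lower_bound = -4,
                    upper_bound = 4, seed = 11)
  fl <- withr::with_seed(11, init_flock(cfg, sphere))
  expect_equal(dim(fl$positions), c(5, 3))
  expect_true(all(fl$positions >= -4 & fl$positions <= 4))
  expect_identical(fl$memory, fl$positions)
  expect_equal(fl$memory_fitness, apply(fl$positions, 1, sphere))
  expect_equal(fl$n_evals, 5L)

  fl2 <- withr::with_seed(11, init_flock(cfg, sphere))
  expect_identical(fl, fl2)

  tiny <- csa_config(n_dims = 1, n_crows = 2, lower_bound = -1,
                     upper_bound = 1)
  fl3 <- withr::with_seed(3, init_flock(tiny, sphere))
  expect_true(all(fl3$positions >= -1 & fl3$positions <= 1))
})

test_that("the follow move lands where the position-update rule says", {
  cfg <- csa_config(n_dims = 2, flight_length = 1)
  out <- propose_position(c(0, 0), c(1, 1), cfg, branch = "follow", r_i = 0.5)
  expect_equal(out, c(0.5, 0.5), tolerance = 1e-9)

  cfg0 <- csa_config(n_dims = 2, flight_length = 0)
  expect_equal(propose_position(c(0.3, -0.7), c(1, 1), cfg0,
                                branch = "follow", r_i = 0.9),
               c(0.3, -0.7))

  # escape branch: uniform draw inside the box
  cfg4 <- csa_config(n_dims = 50, lower_bound = -4, upper_bound = 4)
  esc <- withr::with_seed(1, propose_position(rep(0, 50), rep(1, 50), cfg4,
                                              branch = "random"))
  expect_true(all(esc >= -4 & esc <= 4))
  expect_gt(stats::sd(esc), 0)
})

test_that("feasibility screening keeps the crow in place when out of bounds", {
  cfg <- csa_config(n_dims = 2, lower_bound = -4, upper_bound = 4)
  expect_equal(screen_position(c(0.5, 0.5), c(1, 1), cfg), c(0.5, 0.5))
  expect_equal(screen_position(c(9, 0), c(1, 1), cfg), c(1, 1))
  expect_equal(screen_position(c(4, -4), c(1, 1), cfg), c(4, -4))
})

test_that("memory updates only on strict improvement", {
  cfg <- csa_config(n_dims = 2, n_crows = 3, seed = 7)
  fl <- withr::with_seed(7, init_flock(cfg, sphere))
  fl$positions <- matrix(0, 3, 2) # best possible point for all crows
  new_fit <- c(0, fl$memory_fitness[2], fl$memory_fitness[3] + 1)
  up <- update_memory(fl, new_fit)
  expect_equal(up$memory[1, ], c(0, 0))
  expect_equal(up$memory_fitness[1], 0)
  # tie and worse cases leave memory untouched
  expect_equal(up$memory[2, ], fl$memory[2, ])
  expect_equal(up$memory[3, ], fl$memory[3, ])

  same <- update_memory(fl, fl$memory_fitness + 1)
  expect_identical(same$memory, fl$memory)
  expect_error(update_memory(fl, c(1, 2)), "length")
})

test_that("the iteration loop optimises the sphere and accounts its budget", {
  cfg <- csa_config(n_dims = 5, n_crows = 20, iter_max = 200,
                    flight_length = 2, awareness_prob = 0.1, seed = 1)
  res <- run_csa(sphere, cfg)
  expect_length(res$history, 200)
  expect_true(all(diff(res$history) <= 0))
  expect_equal(res$n_evals, 20 * 201)
  expect_lt(res$value, 1e-2)
  expect_equal(res$value, sphere(res$par))

  # identical seed, config and objective reproduce the run bit-exactly
  res2 <- run_csa(sphere, cfg)
  expect_identical(res$history, res2$history)
  expect_identical(res$par, res2$par)
})

test_that("loop boundaries and flat landscapes behave", {
  cfg1 <- csa_config(n_dims = 3, n_crows = 4, iter_max = 1, seed = 9)
  res <- run_csa(sphere, cfg1)
  expect_length(res$history, 1)

  const_calls <- new.env(); const_calls$n <- 0L
  const <- function(v) { const_calls$n <- const_calls$n + 1L; 3.5 }
  cfgc <- csa_config(n_dims = 2, n_crows = 3, iter_max = 10, seed = 4)
  resc <- run_csa(const, cfgc)
  expect_equal(resc$value, 3.5)
  expect_true(all(resc$history == 3.5))
  expect_equal(const_calls$n, 3L * 11L)
  # flat landscape: no strict improvement, memory frozen at init
  init <- withr::with_seed(4, init_flock(cfgc, function(v) 3.5))
  expect_identical(resc$flock$memory, init$memory)
})

test_that("awareness-probability extremes both run and stay monotone", {
  for (ap in c(0, 1)) {
    cfg <- csa_config(n_dims = 4, n_crows = 6, iter_max = 30,
                      awareness_prob = ap, seed = 21)
    res <- run_csa(sphere, cfg)
    expect_true(all(diff(res$history) <= 0))
    expect_equal(res$n_evals, 6 * 31)
  }
})

test_that("objective failures abort with the iteration reported", {
  bad <- function(v) if (sum(v) > -Inf) stop("boom") else 0
  cfg <- csa_config(n_dims = 2, n_crows = 3, iter_max = 5, seed = 2)
  expect_error(run_csa(bad, cfg), "iteration 0")
})

test_that("config validation rejects degenerate settings", {
  expect_error(csa_config(n_dims = 2, n_crows = 1), class = "csadt_config_error")
  expect_error(csa_config(n_dims = 2, awareness_prob = 1.5),
               class = "csadt_config_error")
  expect_error(csa_config(n_dims = 2, lower_bound = 1, upper_bound = -1),
               class = "csadt_config_error")
  expect_error(csa_config(n_dims = 2, iter_max = 0),
               class = "csadt_config_error")
})
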