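# Shared fixtures, built in code at test time.

# Two well-separated Gaussian classes: any sane classifier is near-perfect.
make_separable_table <- function(n = 60, d = 3, sep = 6, seed = 42) {
  g <- generate_synth(n_samples = n, n_informative = d, n_noise = 0,
                      class_separation = sep, seed = seed)
  g$table
}

# Small deterministic table for I/O and normalization tests.
make_tiny_table <- function() {
  x <- cbind(a = c(2, 4, 6), b = c(0, 0.5, 1))
  feature_table(x, c("ctrl", "case", "case"), label_name = "status",
                positive = "case")
}

sphere <- function(v) sum(v^2)

# Random search with the same evaluation budget as a CSA run: the
# empirical baseline the optimizer must beat.
random_search <- function(objective, n_evals, d, lower, upper, seed) {
  withr::with_seed(seed, {
    best <- Inf
    for (i in seq_len(n_evals)) {
      v <- runif(d, lower, upper)
      f <- objective(v)
      if (f < best) best <- f
    }
    best
  })
}
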