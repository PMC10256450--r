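# Internal helpers: seed derivation and scoped RNG use.

# All randomness in a run flows from one top-level seed. Child streams
# (data generation, train/test split, optimizer+binarization) get distinct
# derived seeds so that fixing one stage never perturbs another. Derived
# seeds stay below 2^31 - 1.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  as.integer((abs(seed) * 7 + offset * 104729) %% m)
}

# Evaluate expr with the global RNG temporarily seeded, restoring any
# pre-existing state afterwards (so scoped draws never disturb a caller's
# stream).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_input <- function(...) {
  stop(structure(class = c("csadt_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("csadt_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
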