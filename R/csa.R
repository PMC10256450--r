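#' Crow search algorithm configuration
#'
#' Parameters of the continuous crow search algorithm (CSA): `N` crows
#' search a `d`-dimensional box. Each iteration every crow either follows
#' another crow's memorised best position (step scaled by the flight
#' length `fl`) or, with probability `AP` (the awareness probability),
#' relocates uniformly at random -- the exploration control. Small `fl`
#' values give local search between the crow and the followed memory;
#' `fl > 1` can overshoot it.
#'
#' @param n_dims Number of decision variables `d`.
#' @param n_crows Population size `N` (at least 2: a crow needs another
#'   crow to follow).
#' @param iter_max Number of iterations.
#' @param flight_length Step multiplier `fl` toward the followed memory.
#' @param awareness_prob Probability `AP` in `[0, 1]` of a random
#'   relocation instead of a follow move.
#' @param lower_bound,upper_bound Box constraints applied coordinate-wise.
#' @param seed Integer seed; the whole run (initialisation, follow/escape
#'   draws, and any randomness the objective itself consumes, such as
#'   binarization thresholds) derives from this one stream.
#'
#' @details Defaults (`N = 20`, `iter_max = 100`, `fl = 2`, `AP = 0.1`)
#'   are the common CSA settings from the algorithm's original
#'   benchmarking. Default bounds of ±4 suit the sigmoid binary adapter:
#'   `sigmoid(±4) ≈ 0.018/0.982`, spanning near-deterministic bit
#'   probabilities without flat saturation.
#' @return An object of class `csa_config`.
#' @export
csa_config <- function(n_dims, n_crows = 20, iter_max = 100,
                       flight_length = 2, awareness_prob = 0.1,
                       lower_bound = -4, upper_bound = 4, seed = 1) {
  if (n_crows < 2) stop_config("n_crows must be >= 2")
  if (n_dims < 1) stop_config("n_dims must be >= 1")
  if (iter_max < 1) stop_config("iter_max must be >= 1")
  if (flight_length < 0) stop_config("flight_length must be non-negative")
  if (awareness_prob < 0 || awareness_prob > 1) {
    stop_config("awareness_prob must lie in [0, 1]")
  }
  if (lower_bound >= upper_bound) stop_config("lower_bound must be < upper_bound")
  structure(list(n_crows = as.integer(n_crows), n_dims = as.integer(n_dims),
                 iter_max = as.integer(iter_max),
                 flight_length = flight_length,
                 awareness_prob = awareness_prob,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 seed = as.integer(seed)),
            class = "csa_config")
}

#' Initialise a flock
#'
#' Draws crow positions uniformly inside the box and sets each crow's
#' memory equal to its initial position (with no better information yet,
#' crows hide food where they stand). Memory fitness is evaluated once per
#' crow. Draws come from the current RNG state; [run_csa()] seeds it from
#' the config.
#'
#' @param config A [csa_config()].
#' @param objective Function mapping a length-`d` numeric vector to a
#'   scalar to be minimised.
#' @return An object of class `flock`: `positions` and `memory` (`N x d`
#'   matrices), `memory_fitness` (length `N`), `iteration`, `n_evals`.
#' @export
init_flock <- function(config, objective) {
  stopifnot(inherits(config, "csa_config"))
  pos <- matrix(stats::runif(config$n_crows * config$n_dims,
                             config$lower_bound, config$upper_bound),
                nrow = config$n_crows, ncol = config$n_dims, byrow = TRUE)
  fit <- vapply(seq_len(config$n_crows),
                function(i) objective(pos[i, ]), numeric(1))
  structure(list(positions = pos, memory = pos, memory_fitness = fit,
                 iteration = 0L, n_evals = config$n_crows),
            class = "flock")
}

#' Propose a new crow position
#'
#' One move of the CSA position-update rule. In the follow branch (taken
#' when the followed crow does not notice pursuit, i.e. with probability
#' `1 - AP`) the crow steps toward the followed memory:
#' `x_i + r_i * fl * (m_j - x_i)` with `r_i ~ U(0, 1)` drawn fresh per
#' move (scalar, not per-dimension). Otherwise the followed crow escapes
#' and the proposal is a uniform random point in the box.
#'
#' @param x_i Current position of the moving crow.
#' @param m_j Memory of the followed crow.
#' @param config A [csa_config()].
#' @param branch `"auto"` draws `r_j ~ U(0,1)` and follows when
#'   `r_j >= AP`; `"follow"` / `"random"` force a branch (used in tests
#'   and by callers that manage the awareness draw themselves).
#' @param r_i Optional fixed step fraction for the follow branch; drawn
#'   uniformly when `NULL`.
#' @return A candidate position vector of length `d` (not yet screened
#'   for feasibility; see [screen_position()]).
#' @export
propose_position <- function(x_i, m_j, config,
                             branch = c("auto", "follow", "random"),
                             r_i = NULL) {
  branch <- match.arg(branch)
  if (length(x_i) != config$n_dims || length(m_j) != config$n_dims) {
    stop("position/memory length does not match config$n_dims")
  }
  if (branch == "auto") {
    r_j <- stats::runif(1)
    branch <- if (r_j >= config$awareness_prob) "follow" else "random"
  }
  if (branch == "follow") {
    if (is.null(r_i)) r_i <- stats::runif(1)
    x_i + r_i * config$flight_length * (m_j - x_i)
  } else {
    stats::runif(config$n_dims, config$lower_bound, config$upper_bound)
  }
}

#' Feasibility screen for a proposed position
#'
#' A candidate is feasible when every coordinate lies inside the closed
#' box `[lower_bound, upper_bound]`; a feasible candidate replaces the
#' crow's position, an infeasible one leaves the crow where it is.
#'
#' @param candidate Proposed position.
#' @param current Position the crow keeps if the candidate is infeasible.
#' @param config A [csa_config()].
#' @return `candidate` if in-bounds, else `current`.
#' @export
screen_position <- function(candidate, current, config) {
  if (all(candidate >= config$lower_bound & candidate <= config$upper_bound)) {
    candidate
  } else {
    current
  }
}

#' Update flock memories
#'
#' Replaces crow `i`'s memory by its current position exactly when the new
#' fitness is a strict improvement (minimisation: strictly lower). Ties
#' keep the old memory. The position-update equation is sometimes printed
#' in its maximisation form; here the convention is minimisation
#' throughout, matching the wrapper fitness (error rate plus subset
#' penalty) this optimizer exists to drive.
#'
#' @param flock A `flock` from [init_flock()].
#' @param new_fitness Objective values at the current positions, length `N`.
#' @return The updated flock.
#' @export
update_memory <- function(flock, new_fitness) {
  stopifnot(inherits(flock, "flock"))
  if (length(new_fitness) != nrow(flock$positions)) {
    stop("new_fitness length does not match flock size")
  }
  better <- new_fitness < flock$memory_fitness
  if (any(better)) {
    flock$memory[better, ] <- flock$positions[better, , drop = FALSE]
    flock$memory_fitness[better] <- new_fitness[better]
  }
  flock
}

#' Run the crow search algorithm
#'
#' The full iteration loop: initialise positions and memories, then for
#' `iter_max` iterations move every crow (follow or escape), screen the
#' proposals against the box, evaluate the moved positions, and update
#' memories on strict improvement. Returns the best memory row.
#'
#' Randomness is consumed in a fixed, documented order so runs are
#' bit-reproducible: initial positions first, then per iteration and per
#' crow the followed-crow choice `j`, the awareness draw `r_j`, and either
#' the step fraction `r_i` or the `d` escape coordinates; any draws the
#' objective makes (e.g. binarization thresholds) follow within the same
#' stream, crow by crow, after all crows of the iteration have moved.
#'
#' @param objective Function: length-`d` numeric vector -> scalar, lower
#'   is better. Must be deterministic apart from draws it takes from the
#'   shared stream.
#' @param config A [csa_config()].
#' @param callback Optional function called after each iteration as
#'   `callback(iter, best_fitness, flock)`; its return value is ignored.
#' @param verbose Log per-iteration best fitness with `message()`.
#' @return An object of class `csa_result`: `par` (best memory row),
#'   `value` (its fitness), `history` (length-`iter_max` non-increasing
#'   best-memory-fitness trace), `n_evals` (`N * (iter_max + 1)`), and the
#'   final `flock`.
#' @examples
#' sphere <- function(v) sum(v^2)
#' res <- run_csa(sphere, csa_config(n_dims = 3, iter_max = 50, seed = 7))
#' res$value
#' @export
run_csa <- function(objective, config, callback = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "csa_config"), is.function(objective))
  with_seed(config$seed, {
    obj <- function(v, iter) {
      out <- tryCatch(objective(v), error = function(e) {
        stop("objective failed at iteration ", iter, ": ",
             conditionMessage(e), call. = FALSE)
      })
      if (!is.finite(out)) stop("objective returned a non-finite value at iteration ",
                                iter, call. = FALSE)
      out
    }
    flock <- init_flock(config, function(v) obj(v, 0L))
    N <- config$n_crows
    history <- numeric(config$iter_max)
    for (iter in seq_len(config$iter_max)) {
      for (i in seq_len(N)) {
        j <- if (N == 2L) setdiff(1:2, i) else sample(seq_len(N)[-i], 1L)
        cand <- propose_position(flock$positions[i, ], flock$memory[j, ],
                                 config, branch = "auto")
        flock$positions[i, ] <- screen_position(cand, flock$positions[i, ],
                                                config)
      }
      new_fit <- vapply(seq_len(N),
                        function(i) obj(flock$positions[i, ], iter),
                        numeric(1))
      flock <- update_memory(flock, new_fit)
      flock$iteration <- iter
      flock$n_evals <- flock$n_evals + N
      history[iter] <- min(flock$memory_fitness)
      if (verbose) message(sprintf("iter %d: best fitness %.6g", iter,
                                   history[iter]))
      if (!is.null(callback)) callback(iter, history[iter], flock)
    }
    best <- which.min(flock$memory_fitness)
    structure(list(par = flock$memory[best, ],
                   value = flock$memory_fitness[best],
                   history = history, n_evals = flock$n_evals,
                   flock = flock, config = config),
              class = "csa_result")
  })
}

#' @export
print.csa_result <- function(x, ...) {
  cat("CSA run: N =", x$config$n_crows, ", d =", x$config$n_dims,
      ", iterations =", x$config$iter_max, "\n")
  cat("Best fitness:", format(x$value, digits = 6),
      "after", x$n_evals, "objective evaluations\n")
  invisible(x)
}
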