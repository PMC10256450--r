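#' Sigmoid transfer function
#'
#' Maps a continuous optimizer coordinate to the open interval (0, 1):
#' `sigmoid(v) = 1 / (1 + exp(-v))`. Strictly increasing, with
#' `sigmoid(v) + sigmoid(-v) = 1`; extreme inputs saturate to the nearest
#' machine-representable values rather than overflowing.
#'
#' @param value Numeric vector.
#' @return Values in (0, 1), same length as the input.
#' @export
sigmoid_transfer <- function(value) {
  1 / (1 + exp(-value))
}

#' Binarize a continuous position into a feature mask
#'
#' Turns each coordinate into a bit by comparing a fresh uniform draw with
#' the sigmoid of the coordinate (an S-shaped transfer function with a
#' random threshold). Two inequality directions are supported:
#'
#' * `"paper"` (default): bit = 0 when `rand < sigmoid(x)`, bit = 1 when
#'   `rand >= sigmoid(x)`, so `P(bit = 1) = 1 - sigmoid(x)`. This is the
#'   printed rule of the method this package implements; large negative
#'   coordinates mean "select".
#' * `"standard"`: the common binary-metaheuristic convention,
#'   `P(bit = 1) = sigmoid(x)`; large positive coordinates mean "select".
#'
#' The two are mirror encodings (negate the position to swap), so the
#' choice does not change what the search can express, only the sign
#' convention of the continuous space.
#'
#' Consumes exactly `length(position)` draws from the current RNG stream.
#'
#' @param position Numeric vector (a crow position or memory row).
#' @param direction `"paper"` or `"standard"`.
#' @return An object of class `feature_mask`: `bits` (integer 0/1 vector)
#'   and `n_selected`.
#' @export
binarize <- function(position, direction = c("paper", "standard")) {
  direction <- match.arg(direction)
  s <- sigmoid_transfer(position)
  r <- stats::runif(length(position))
  bits <- if (direction == "paper") as.integer(r >= s) else as.integer(r < s)
  feature_mask(bits)
}

#' Construct a feature mask
#'
#' @param bits Vector of 0/1 values, one per feature column; 1 means the
#'   feature is selected.
#' @return An object of class `feature_mask`.
#' @export
feature_mask <- function(bits) {
  bits <- as.integer(bits)
  if (any(is.na(bits)) || any(bits != 0L & bits != 1L)) {
    stop_input("mask bits must be 0 or 1")
  }
  structure(list(bits = bits, n_selected = sum(bits)), class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat("Feature mask: ", x$n_selected, "/", length(x$bits), " selected\n",
      sep = "")
  invisible(x)
}

#' Repair an empty feature mask
#'
#' An all-zero mask selects no features and cannot be scored by a
#' classifier. Under the repair policy this guard sets exactly one
#' uniformly chosen bit; non-empty masks pass through unchanged. (The
#' alternative is the fitness-side penalty, which scores an empty mask at
#' the worst possible value without training; see [fitness_config()].)
#'
#' Consumes one RNG draw only when a repair happens.
#'
#' @param mask A [feature_mask()].
#' @return A non-empty `feature_mask`.
#' @export
guard_nonempty <- function(mask) {
  stopifnot(inherits(mask, "feature_mask"))
  if (mask$n_selected >= 1L) return(mask)
  bits <- mask$bits
  bits[sample.int(length(bits), 1L)] <- 1L
  feature_mask(bits)
}
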