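#' Synthetic binary-labelled feature tables with known structure
#'
#' Generates a feature table in which a known subset of columns carries
#' class signal, so selection quality can be judged against ground truth.
#' Three column kinds are produced, in order:
#'
#' * informative: Gaussian class-conditionals with unit within-class
#'   standard deviation and class means `class_separation` apart;
#' * redundant: random affine transforms of randomly chosen informative
#'   columns plus Gaussian jitter at 10% of the source column's standard
#'   deviation (detectable redundancy, not exact copies);
#' * noise: standard Gaussian, independent of the labels.
#'
#' Labels are assigned by `class_balance` (fraction in the positive
#' class "1"), then a fraction `label_noise` of them is flipped. The
#' whole table is a deterministic function of `seed`.
#'
#' @param n_samples Number of rows.
#' @param n_informative,n_redundant,n_noise Column counts per kind;
#'   `n_informative >= 1`.
#' @param class_separation Distance between class means in the informative
#'   dimensions, in within-class standard-deviation units.
#' @param class_balance Fraction of samples labelled "1", in (0, 1).
#' @param label_noise Fraction of labels flipped after assignment, in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @return A list: `table` (a [feature_table()]), `informative` and
#'   `redundant` (ground-truth column index vectors), and the generating
#'   parameters as `spec`.
#' @examples
#' g <- generate_synth(n_samples = 100, n_informative = 3, n_noise = 5,
#'                     class_separation = 3, seed = 1)
#' g$informative
#' @export
generate_synth <- function(n_samples = 200, n_informative = 5,
                           n_redundant = 0, n_noise = 15,
                           class_separation = 3, class_balance = 0.5,
                           label_noise = 0, seed = 1) {
  if (n_informative < 1) stop_config("n_informative must be >= 1")
  if (n_redundant < 0 || n_noise < 0) stop_config("column counts must be >= 0")
  if (class_separation < 0) stop_config("class_separation must be >= 0")
  if (class_balance <= 0 || class_balance >= 1) {
    stop_config("class_balance must lie in (0, 1)")
  }
  if (label_noise < 0 || label_noise >= 1) {
    stop_config("label_noise must lie in [0, 1)")
  }
  n <- as.integer(n_samples)
  with_seed(seed, {
    n_pos <- max(1L, min(n - 1L, round(class_balance * n)))
    y <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
    d_inf <- as.integer(n_informative)
    d_red <- as.integer(n_redundant)
    d_noi <- as.integer(n_noise)
    # informative: class-0 mean 0, class-1 mean class_separation, sd 1
    inf <- matrix(stats::rnorm(n * d_inf), n, d_inf) +
      class_separation * matrix(y, n, d_inf)
    red <- if (d_red > 0) {
      src <- sample.int(d_inf, d_red, replace = TRUE)
      m <- matrix(0, n, d_red)
      for (k in seq_len(d_red)) {
        a <- stats::runif(1, 0.5, 2) * sample(c(-1, 1), 1)
        b <- stats::runif(1, -1, 1)
        s <- stats::sd(inf[, src[k]])
        m[, k] <- a * inf[, src[k]] + b + stats::rnorm(n, sd = 0.1 * s)
      }
      m
    } else matrix(0, n, 0)
    noi <- matrix(stats::rnorm(n * d_noi), n, d_noi)
    x <- cbind(inf, red, noi)
    colnames(x) <- c(sprintf("inf%02d", seq_len(d_inf)),
                     if (d_red) sprintf("red%02d", seq_len(d_red)),
                     if (d_noi) sprintf("noise%02d", seq_len(d_noi)))
    if (label_noise > 0) {
      flip <- sample.int(n, round(label_noise * n))
      y[flip] <- 1L - y[flip]
    }
    list(table = feature_table(x, y, label_name = "label", positive = "1"),
         informative = seq_len(d_inf),
         redundant = if (d_red) d_inf + seq_len(d_red) else integer(0),
         spec = list(n_samples = n, n_informative = d_inf,
                     n_redundant = d_red, n_noise = d_noi,
                     class_separation = class_separation,
                     class_balance = class_balance,
                     label_noise = label_noise, seed = seed))
  })
}

# Shapes of the public Parkinson's-disease feature tables this generator
# can emulate: features x samples.
profile_registry <- list(
  voice        = list(n_features = 23L,  n_samples = 194L),
  spiral       = list(n_features = 15L,  n_samples = 264L),
  meander      = list(n_features = 15L,  n_samples = 264L),
  speech_sakar = list(n_features = 754L, n_samples = 756L)
)

#' Emulate the shape of a public Parkinson's-disease feature table
#'
#' Produces a synthetic table whose dimensions match one of the four
#' public PD datasets these methods are usually benchmarked on: `voice`
#' (194 samples x 23 vocal features), `spiral` and `meander`
#' (264 x 15 handwriting-trace features each) and `speech_sakar`
#' (756 x 754 speech features). Only the shape and the two-class label
#' structure are emulated — 20% of columns are informative (at
#' separation 2, balanced classes), the rest pure noise — not the
#' physiology of the real measurements.
#'
#' @param name Profile name.
#' @param seed Integer seed.
#' @param class_separation,class_balance Passed to [generate_synth()].
#' @return As [generate_synth()].
#' @export
emulate_profile <- function(name = c("voice", "spiral", "meander",
                                     "speech_sakar"),
                            seed = 1, class_separation = 2,
                            class_balance = 0.5) {
  name <- match.arg(name)
  prof <- profile_registry[[name]]
  d <- prof$n_features
  d_inf <- max(1L, as.integer(round(0.2 * d)))
  generate_synth(n_samples = prof$n_samples, n_informative = d_inf,
                 n_redundant = 0, n_noise = d - d_inf,
                 class_separation = class_separation,
                 class_balance = class_balance, seed = seed)
}
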