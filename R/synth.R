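#' Configuration for the microarray-like data generator
#'
#' Describes a synthetic gene-expression dataset in the regime typical of
#' tumour-classification microarrays: few samples, thousands of features,
#' and only a small planted set of class-relevant genes among mostly
#' irrelevant noise.
#'
#' @param n Number of samples (tens to low hundreds).
#' @param m Number of features (thousands in the microarray regime).
#' @param n_classes Number of classes (>= 2), near-balanced.
#' @param n_relevant Number of class-relevant features: class-shifted
#'   unit-variance Gaussians.
#' @param n_redundant Number of redundant features: noisy copies of
#'   relevant features.
#' @param n_complementary Number of complementary features (must be even):
#'   XOR-style pairs, individually uninformative about the class but
#'   jointly predictive.
#' @param effect_size Class mean shift of relevant features, in
#'   within-class standard deviation units (> 0).
#' @param redundancy_noise Standard deviation of the noise added to
#'   redundant copies.
#' @param seed Seed making the dataset fully reproducible.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n, m, n_classes = 2, n_relevant = 0,
                         n_redundant = 0, n_complementary = 0,
                         effect_size = 1.5, redundancy_noise = 0.5,
                         seed = 1) {
  if (n < 2 || m < 1) stop("need at least 2 samples and 1 feature")
  if (n_classes < 2) stop("'n_classes' must be at least 2")
  if (effect_size <= 0) stop("'effect_size' must be positive")
  if (n_complementary %% 2 != 0)
    stop("'n_complementary' must be even (features come in pairs)")
  if (n_relevant + n_redundant + n_complementary > m)
    stop("planted role counts exceed the number of features")
  if (n_redundant > 0 && n_relevant == 0)
    stop("redundant features need at least one relevant feature to copy")
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic microarray-like dataset
#'
#' Draws near-balanced class labels, then fills the feature matrix:
#' relevant features are unit-variance Gaussians whose means are shifted
#' per class by the configured effect size; redundant features are noisy
#' copies of relevant ones; complementary features come in XOR pairs (two
#' binary latents embedded in continuous noise whose parity tracks the
#' class parity, so each is marginally independent of the class but the
#' pair is predictive); all remaining features are standard Gaussian
#' noise. Planted roles are assigned to randomly shuffled column
#' positions, and the ground truth is returned for scoring.
#'
#' @param config A [synth_config()].
#' @return An object of class `"synth_dataset"`: `x` (numeric matrix with
#'   named columns), `y` (0-based integer labels), `roles` (per-feature
#'   role: relevant / redundant / complementary / irrelevant) and the
#'   `config`. Identical configs yield bit-identical datasets.
#' @export
synth_microarray <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  restore <- local_rng(config$seed)
  on.exit(restore())
  n <- config$n; m <- config$m; ncl <- config$n_classes
  y <- sample(rep_len(0:(ncl - 1), n))
  x <- matrix(stats::rnorm(n * m), n, m)
  roles <- rep("irrelevant", m)
  n_planted <- config$n_relevant + config$n_redundant + config$n_complementary
  pos <- sample.int(m, n_planted)
  rel_pos <- pos[seq_len(config$n_relevant)]
  red_pos <- pos[config$n_relevant + seq_len(config$n_redundant)]
  com_pos <- pos[config$n_relevant + config$n_redundant +
                   seq_len(config$n_complementary)]
  # relevant: class-shifted, centred so no class is privileged
  shift <- config$effect_size * (y - (ncl - 1) / 2)
  for (p in rel_pos) x[, p] <- stats::rnorm(n) + shift
  roles[rel_pos] <- "relevant"
  # redundant: relevant source plus configured noise
  if (config$n_redundant > 0) {
    src <- rep_len(rel_pos, config$n_redundant)
    for (i in seq_along(red_pos))
      x[, red_pos[i]] <- x[, src[i]] +
        stats::rnorm(n, sd = config$redundancy_noise)
    roles[red_pos] <- "redundant"
  }
  # complementary: XOR pairs against the class parity
  if (config$n_complementary > 0) {
    parity <- y %% 2
    for (i in seq_len(config$n_complementary / 2)) {
      a <- stats::rbinom(n, 1, 0.5)
      b <- as.integer(xor(a, parity))
      x[, com_pos[2 * i - 1]] <- (2 * a - 1) + stats::rnorm(n, sd = 0.5)
      x[, com_pos[2 * i]] <- (2 * b - 1) + stats::rnorm(n, sd = 0.5)
    }
    roles[com_pos] <- "complementary"
  }
  colnames(x) <- paste0("g", seq_len(m))
  structure(list(x = x, y = y, roles = roles, config = config),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic microarray: %d samples x %d features, %d classes\n  roles: %s\n",
    nrow(x$x), ncol(x$x), x$config$n_classes,
    paste(sprintf("%s = %d", names(table(x$roles)), table(x$roles)),
          collapse = ", ")))
  invisible(x)
}

#' The canonical synthetic test dataset
#'
#' A fixed dataset used throughout the package's tests and examples:
#' 100 samples, 2000 features, 2 classes, with 20 relevant, 10 redundant
#' and 4 complementary planted features at effect size 1.5 (seed 42).
#' Calling it twice returns identical data.
#'
#' @return A `"synth_dataset"`.
#' @export
standard_fixture <- function() {
  synth_microarray(synth_config(
    n = 100, m = 2000, n_classes = 2, n_relevant = 20, n_redundant = 10,
    n_complementary = 4, effect_size = 1.5, redundancy_noise = 0.5,
    seed = 42))
}
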