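#' Equal-width discretization of a continuous feature matrix
#'
#' Splits each feature's observed range into `n_bins` equal-width intervals
#' and maps values to 0-based bin indices: `floor((v - min) / width)`, with
#' the maximum mapped into the top bin and constant features mapped entirely
#' to bin 0. Bin edges are computed from the data passed to this call; use
#' [apply_discretization()] to apply training-fold edges to held-out data
#' (out-of-range values are clipped to the extreme bins), which keeps
#' cross-validation leak-free.
#'
#' @param x Numeric matrix (samples x features) with no missing values.
#' @param n_bins Number of bins per feature (>= 2); 10 is the conventional
#'   choice for gene-expression matrices.
#' @return Integer matrix of bin indices in `0 .. n_bins - 1`, with
#'   attributes `breaks` (a `2 x m` matrix of per-feature min/max) and
#'   `n_bins`.
#' @export
equal_width_discretize <- function(x, n_bins = 10) {
  x <- as.matrix(x)
  if (nrow(x) < 1 || ncol(x) < 1) stop("empty matrix: nothing to discretize")
  if (n_bins < 2) stop("'n_bins' must be at least 2")
  if (anyNA(x)) stop("missing values are not allowed")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  out <- bin_with_edges(x, lo, hi, n_bins)
  attr(out, "breaks") <- rbind(min = lo, max = hi)
  attr(out, "n_bins") <- as.integer(n_bins)
  out
}

#' Apply previously fitted equal-width bins to new data
#'
#' @param x Numeric matrix with the same features (columns) as the matrix
#'   the bins were fitted on.
#' @param binned The output of [equal_width_discretize()] (carries the
#'   fitted edges).
#' @return Integer matrix of bin indices; values outside the fitted range
#'   are clipped to bins 0 / `n_bins - 1`.
#' @export
apply_discretization <- function(x, binned) {
  br <- attr(binned, "breaks"); nb <- attr(binned, "n_bins")
  if (is.null(br) || is.null(nb)) stop("'binned' carries no fitted bin edges")
  x <- as.matrix(x)
  if (ncol(x) != ncol(br)) stop("feature count does not match fitted edges")
  bin_with_edges(x, br["min", ], br["max", ], nb)
}

bin_with_edges <- function(x, lo, hi, n_bins) {
  width <- (hi - lo) / n_bins
  width[width == 0] <- 1  # constant feature: everything lands in bin 0
  b <- floor(sweep(sweep(x, 2, lo), 2, width, "/"))
  b[b < 0] <- 0
  b[b > n_bins - 1] <- n_bins - 1  # closes the top edge, clips out-of-range
  storage.mode(b) <- "integer"
  b
}

#' Bundle a discretized matrix with class labels
#'
#' @param x Continuous matrix or an already discretized integer matrix from
#'   [equal_width_discretize()].
#' @param y Class labels (factor or integer); stored 0-based.
#' @param n_bins Bins used if `x` still needs discretizing.
#' @return A list of class `"discrete_dataset"`: `bins` (integer matrix),
#'   `y` (0-based integer labels), `classes` (label levels), `features`
#'   (column names) and `n_bins`.
#' @export
discrete_dataset <- function(x, y, n_bins = 10) {
  if (is.double(x) || is.null(attr(x, "n_bins")))
    x <- equal_width_discretize(x, n_bins)
  y <- as.factor(y)
  if (length(y) != nrow(x)) stop("'y' length must match the sample count")
  structure(
    list(bins = x, y = as.integer(y) - 1L, classes = levels(y),
         features = colnames(x) %||% paste0("f", seq_len(ncol(x))),
         n_bins = attr(x, "n_bins")),
    class = "discrete_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.discrete_dataset <- function(x, ...) {
  cat(sprintf("Discrete dataset: %d samples x %d features, %d bins, %d classes\n",
              nrow(x$bins), ncol(x$bins), x$n_bins, length(x$classes)))
  invisible(x)
}
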