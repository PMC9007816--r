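#' Accumulate joint event counters with saturation halving
#'
#' Streams paired observations in input order into a joint counter table.
#' Under a fixed-point spec the population counter `C` may never exceed
#' `M = 2^(bi+bf) - 1`: whenever the next increment would push `C` past
#' `M`, every joint counter is halved (integer floor division) and `C`
#' recomputed as the sum of the halved counters before counting continues.
#' Marginal counters are derived from the final joint table, so marginal
#' consistency holds exactly whenever no halving occurred.
#'
#' @param xs Integer vector of 0-based bin indices.
#' @param ys Optional second variable (0-based indices); if absent, `xs` is
#'   tallied univariately.
#' @param spec A [fixed_point_spec()], or `NULL` for unbounded
#'   (full-precision) counting.
#' @return An object of class `"counter_table"` with elements `joint`
#'   (counter matrix), `marginal_x`, `marginal_y`, `C` (population count)
#'   and `saturated` (whether halving fired).
#' @export
accumulate_counts <- function(xs, ys = NULL, spec = NULL) {
  if (length(xs) == 0) stop("empty input: nothing to count")
  xs <- as.integer(xs)
  univariate <- is.null(ys)
  ys <- if (univariate) integer(length(xs)) else as.integer(ys)
  if (length(ys) != length(xs)) stop("'xs' and 'ys' must have equal length")
  if (anyNA(xs) || anyNA(ys) || any(xs < 0) || any(ys < 0))
    stop("values must be non-negative bin indices")
  M <- if (is.null(spec)) Inf else spec$M
  res <- cpp_accumulate(xs, ys, max(xs) + 1L, max(ys) + 1L, M)
  structure(
    list(joint = res$joint,
         marginal_x = rowSums(res$joint),
         marginal_y = colSums(res$joint),
         C = res$C, saturated = res$saturated,
         univariate = univariate, spec = spec),
    class = "counter_table"
  )
}

#' @export
print.counter_table <- function(x, ...) {
  cat(sprintf("Counter table: %d x %d cells, C = %.0f%s\n",
              nrow(x$joint), ncol(x$joint), x$C,
              if (x$saturated) " (saturation halving occurred)" else ""))
  invisible(x)
}

new_mi_estimate <- function(value, bits, saturated) {
  structure(list(value = value, bits = bits, saturated = saturated),
            class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  cat(sprintf("MI estimate: %.6f nats (%s%s)\n", x$value,
              if (identical(x$bits, 64)) "full precision"
              else sprintf("%d-bit fixed point", x$bits),
              if (isTRUE(x$saturated)) ", counters saturated" else ""))
  invisible(x)
}

#' Full-precision plug-in mutual information
#'
#' The maximum-likelihood (plug-in) estimator: empirical probabilities
#' `count / C` substituted into the MI sum, evaluated in double precision.
#' Cells with zero joint count contribute 0. Units are nats.
#'
#' @param counts A [accumulate_counts()] table with `C > 0`.
#' @return An `"mi_estimate"` with `bits = 64`.
#' @export
plugin_mi <- function(counts) {
  stopifnot(inherits(counts, "counter_table"))
  if (counts$C <= 0) stop("population count must be positive")
  v <- cpp_mi_from_joint(counts$joint, counts$C, FALSE, 0, 0)
  new_mi_estimate(v, 64, counts$saturated)
}

#' Low-precision mutual information via the log-ratio lookup table
#'
#' Evaluates the plug-in MI sum with every log term replaced by its
#' quantized lookup-table value: each nonzero joint cell contributes
#' `(c_xy / C) * (L(c_xy, C) - L(c_x, C) - L(c_y, C))`. Probability
#' weights stay in full precision; only the logarithms are quantized, and
#' the weighted sum is accumulated in double precision. The result may be
#' slightly negative (bounded below by `-(3q/2)` times the number of
#' nonzero joint cells).
#'
#' @param counts A [accumulate_counts()] table (counters within `0..M`).
#' @param lut A [build_lut()] object.
#' @return An `"mi_estimate"` with `bits = bi + bf`.
#' @export
lowprec_mi <- function(counts, lut) {
  stopifnot(inherits(counts, "counter_table"), inherits(lut, "log_ratio_lut"))
  if (counts$C <= 0) stop("population count must be positive")
  spec <- lut$spec
  if (counts$C > spec$M || any(counts$joint > spec$M))
    stop("counter exceeds M: counting was not performed under this spec")
  v <- cpp_mi_from_joint(counts$joint, counts$C, TRUE, spec$q, spec$vmax)
  new_mi_estimate(v, as.integer(spec$bi + spec$bf), counts$saturated)
}

#' Low-precision joint mutual information I((X1, X2); Y)
#'
#' Encodes the pair `(xs1, xs2)` as one variable over the product alphabet
#' and estimates its low-precision MI with `ys`. This is the elementary
#' term of the JMI selection criterion.
#'
#' @param xs1,xs2 Integer vectors of 0-based bin indices (equal length).
#' @param ys Class labels (0-based integers, equal length).
#' @param spec A [fixed_point_spec()].
#' @param lut Optional prebuilt [build_lut()] for `spec`.
#' @return An `"mi_estimate"`.
#' @export
lowprec_joint_mi <- function(xs1, xs2, ys, spec, lut = NULL) {
  stopifnot(inherits(spec, "fixed_point_spec"))
  if (is.null(lut)) lut <- build_lut(spec)
  xs1 <- as.integer(xs1); xs2 <- as.integer(xs2)
  if (length(xs1) != length(xs2) || length(xs1) != length(ys))
    stop("'xs1', 'xs2' and 'ys' must have equal length")
  a2 <- max(xs2) + 1L
  lowprec_mi(accumulate_counts(xs1 * a2 + xs2, ys, spec), lut)
}

#' Mutual information between two discrete vectors
#'
#' Convenience wrapper: tallies the two vectors (with saturating counters
#' when a fixed-point depth is requested) and estimates MI at that depth.
#'
#' @param x,y Integer vectors of 0-based values.
#' @param bits Total bit depth (e.g. 4, 8, 16, 32) or `"full"` for the
#'   double-precision baseline.
#' @param bi,bf Optional explicit integer/fractional bit split.
#' @return An `"mi_estimate"`.
#' @examples
#' x <- rep(0:1, each = 10)
#' mutual_information(x, x, bits = "full")$value  # ln(2)
#' @export
mutual_information <- function(x, y, bits = "full", bi = NULL, bf = NULL) {
  spec <- depth_spec(bits, bi, bf)
  counts <- accumulate_counts(x, y, spec)
  if (is.null(spec)) plugin_mi(counts)
  else lowprec_mi(counts, build_lut(spec))
}
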