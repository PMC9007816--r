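#' Fixed-point representation specification
#'
#' Describes a signed fixed-point number format with `bi` integer bits and
#' `bf` fractional bits. Values representable in this format are the integer
#' multiples of the quantization interval `q = 2^-bf`; log magnitudes
#' saturate at `2^bi - q`. The format also bounds the frequency counters
#' used by the low-precision mutual information estimator: counters and the
#' population count may not exceed `M = 2^(bi + bf) - 1`.
#'
#' @param bi Number of integer bits (>= 1).
#' @param bf Number of fractional bits (>= 1).
#' @return An object of class `"fixed_point_spec"` with elements `bi`, `bf`,
#'   `q` (quantization interval), `M` (maximum counter value) and `vmax`
#'   (largest representable log magnitude, `2^bi - q`).
#' @examples
#' fixed_point_spec(8, 8)   # a "16-bit" format
#' @export
fixed_point_spec <- function(bi, bf) {
  stopifnot(length(bi) == 1L, length(bf) == 1L, is.finite(bi), is.finite(bf))
  if (bi < 1 || bf < 1 || bi != round(bi) || bf != round(bf))
    stop("'bi' and 'bf' must be integers >= 1")
  bi <- as.numeric(bi); bf <- as.numeric(bf)
  q <- 2^(-bf)
  structure(
    list(bi = bi, bf = bf, q = q, M = 2^(bi + bf) - 1, vmax = 2^bi - q),
    class = "fixed_point_spec"
  )
}

#' @export
print.fixed_point_spec <- function(x, ...) {
  cat(sprintf(
    "Fixed-point spec: bi = %d, bf = %d (%d bits)\n  q = 2^-%d = %.10g, M = %.0f, log range = [%.6g, %.6g]\n",
    x$bi, x$bf, x$bi + x$bf, x$bf, x$q, x$M, -x$vmax, x$vmax))
  invisible(x)
}

#' Split a total bit budget into a fixed-point spec
#'
#' A "b-bit" run splits its budget evenly between integer and fractional
#' bits, `bi = bf = b/2`; the split can be overridden. `bits = "full"` (or
#' 64) denotes the double-precision baseline and returns `NULL`.
#'
#' @param bits Total bit depth (even, >= 2), or `"full"`/`64` for the
#'   double-precision baseline.
#' @param bi,bf Optional explicit split overriding the even default.
#' @return A [fixed_point_spec()] or `NULL` for the baseline.
#' @export
depth_spec <- function(bits, bi = NULL, bf = NULL) {
  if (!is.null(bi) || !is.null(bf)) {
    if (is.null(bi) || is.null(bf)) stop("supply both 'bi' and 'bf' or neither")
    return(fixed_point_spec(bi, bf))
  }
  if (is.character(bits) && identical(tolower(bits), "full")) return(NULL)
  bits <- as.numeric(bits)
  if (identical(bits, 64)) return(NULL)
  if (bits %% 2 != 0 || bits < 2)
    stop("'bits' must be an even total >= 2, or \"full\"")
  fixed_point_spec(bits / 2, bits / 2)
}

# round half away from zero; identical to C++ std::round
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Quantized log-ratio lookup table
#'
#' Precomputes (or defines, for large formats) the table
#' `L(i, j) = [ln(i/j)/q]_R * q`, i.e. the natural log of the counter ratio
#' `i/j` rounded to the nearest multiple of the quantization interval and
#' clamped to the representable range. This is the only place the
#' low-precision estimator loses precision relative to the plug-in
#' estimator: probability weights stay in full precision and only the log
#' terms are quantized.
#'
#' For small formats (`M <= 4096`) the full `(M-1) x (M-1)` table is
#' materialized; larger formats evaluate entries on demand with the exact
#' same formula, so the two storage modes are bit-identical.
#'
#' @param spec A [fixed_point_spec()].
#' @return An object of class `"log_ratio_lut"`.
#' @seealso [lut_lookup()]
#' @export
build_lut <- function(spec) {
  stopifnot(inherits(spec, "fixed_point_spec"))
  table <- NULL
  if (spec$M <= 4096) {
    idx <- seq_len(spec$M - 1)
    table <- outer(idx, idx, function(i, j)
      cpp_quant_log_ratio(i, j, spec$q, spec$vmax))
  }
  structure(list(spec = spec, table = table), class = "log_ratio_lut")
}

#' Look up quantized log-ratios
#'
#' Returns `L(i, j)`, the quantized value of `ln(i/j)`. A zero occurrence
#' count (`i = 0`) maps to the distinguished zero-count sentinel `-Inf`
#' (the event was never observed); a zero population (`j = 0`) is a domain
#' error, since no probability is defined over an empty population.
#'
#' @param lut A [build_lut()] object.
#' @param i Occurrence counters (non-negative integers).
#' @param j Population counters (positive integers).
#' @return Numeric vector of quantized log-ratios, each an integer multiple
#'   of `q`; `-Inf` where `i = 0`.
#' @export
lut_lookup <- function(lut, i, j) {
  stopifnot(inherits(lut, "log_ratio_lut"))
  n <- max(length(i), length(j))
  i <- rep_len(as.numeric(i), n); j <- rep_len(as.numeric(j), n)
  if (any(j == 0)) stop("log of probability with empty population (j = 0)")
  if (any(i < 0 | j < 0)) stop("counters must be non-negative")
  out <- numeric(n)
  zero <- i == 0
  out[zero] <- -Inf
  nz <- !zero
  if (any(nz)) {
    spec <- lut$spec
    if (!is.null(lut$table) && all(i[nz] < spec$M) && all(j[nz] < spec$M)) {
      out[nz] <- lut$table[cbind(i[nz], j[nz])]
    } else {
      out[nz] <- cpp_quant_log_ratio(i[nz], j[nz], spec$q, spec$vmax)
    }
  }
  out
}

#' @export
print.log_ratio_lut <- function(x, ...) {
  cat(sprintf("Log-ratio LUT for bi = %d, bf = %d (%s; M = %.0f)\n",
              x$spec$bi, x$spec$bf,
              if (is.null(x$table)) "computed on demand" else "materialized",
              x$spec$M))
  invisible(x)
}

#' Maximum-likelihood event probability
#'
#' The plug-in probability estimate: the frequency of occurrence of an event
#' divided by the total number of events.
#'
#' @param occurrences Number of occurrences of the event (0 <= occurrences
#'   <= total).
#' @param total Total number of events (> 0).
#' @return `occurrences / total` in double precision.
#' @examples
#' ml_probability(4, 961)
#' @export
ml_probability <- function(occurrences, total) {
  if (any(total <= 0)) stop("total number of events must be positive")
  if (any(occurrences < 0) || any(occurrences > total))
    stop("'occurrences' must lie in [0, total]")
  occurrences / total
}
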