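#' Information-theoretic feature ranking at a chosen bit depth
#'
#' The package's central fitting function. Discretizes a continuous
#' sample-by-feature matrix (equal-width bins), then greedily ranks
#' features against the class labels with one of three mutual-information
#' filters, evaluating every MI term either with the full-precision plug-in
#' estimator or with the fixed-point, lookup-table estimator at the
#' requested bit depth:
#'
#' \describe{
#'   \item{`mim`}{Mutual Information Maximization: ranks features by
#'     `I(X_f; Y)` alone (univariate relevance).}
#'   \item{`mrmr`}{minimum Redundancy Maximum Relevance: greedily maximizes
#'     `I(X_f; Y) - mean_{s in S} I(X_f; X_s)`, relevance minus mean
#'     redundancy with the already selected set `S`.}
#'   \item{`jmi`}{Joint Mutual Information: greedily maximizes
#'     `sum_{s in S} I((X_f, X_s); Y)`, which also rewards features that
#'     are complementary to those already selected.}
#' }
#'
#' The first feature of every method is the maximum-relevance feature. All
#' ties are broken by ascending feature index, so rankings are fully
#' deterministic. A total bit depth `b` is split evenly into `bi = bf =
#' b/2` integer/fractional bits unless overridden.
#'
#' @param x A numeric matrix or data frame (samples x features), a
#'   [discrete_dataset()], or a formula (see
#'   `lowmi_rank.formula`).
#' @param y Class labels (factor or integer vector), ignored when `x` is
#'   already a `discrete_dataset`.
#' @param method One of `"mim"`, `"mrmr"`, `"jmi"`.
#' @param k Number of features to select (1 <= k <= m).
#' @param bits Total bit depth of the MI arithmetic: 4, 8, 16, 32, ... or
#'   `"full"` (the default) for the double-precision baseline.
#' @param bi,bf Optional explicit integer/fractional bit split.
#' @param n_bins Equal-width bins used to discretize continuous features.
#' @param ... Passed between methods.
#' @return An object of class `"feature_ranking"`: the ordered selected
#'   feature indices (`features`, best first), their names, the criterion
#'   `scores` at the step each was selected, the `method`, `bits` label,
#'   `k` and the number of MI evaluations performed (`n_evals`).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200 * 20), 200, 20)
#' y <- as.integer(x[, 3] + x[, 7] > 0)
#' fit <- lowmi_rank(x, y, method = "mrmr", k = 5, bits = 8)
#' print(fit)
#' @export
lowmi_rank <- function(x, ...) UseMethod("lowmi_rank")

#' @rdname lowmi_rank
#' @param formula A model formula such as `class ~ .`; the response is the
#'   class label, the remaining columns are features.
#' @param data Data frame holding the formula's variables.
#' @export
lowmi_rank.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- mf[, -1, drop = FALSE]
  fit <- lowmi_rank(as.matrix(x), y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname lowmi_rank
#' @export
lowmi_rank.default <- function(x, y = NULL,
                               method = c("mim", "mrmr", "jmi"),
                               k = min(50L, ncol(dd$bins)),
                               bits = "full", bi = NULL, bf = NULL,
                               n_bins = 10, ...) {
  method <- match.arg(method)
  dd <- if (inherits(x, "discrete_dataset")) x else discrete_dataset(x, y, n_bins)
  m <- ncol(dd$bins)
  if (k < 1 || k > m) stop(sprintf("'k' must lie in [1, %d]", m))
  spec <- depth_spec(bits, bi, bf)
  eng <- rank_engine(dd, method, as.integer(k), spec)
  structure(
    list(features = eng$features,
         feature_names = dd$features[eng$features],
         scores = eng$scores,
         method = method,
         bits = if (is.null(spec)) 64L else as.integer(spec$bi + spec$bf),
         spec = spec, k = as.integer(k), n_evals = eng$n_evals,
         call = match.call()),
    class = "feature_ranking"
  )
}

# Greedy selection engines. All MI terms go through the C++ kernels; one
# bulk call evaluates the criterion's new terms for every remaining
# candidate, and n_evals counts individual MI evaluations.
rank_engine <- function(dd, method, k, spec) {
  X <- dd$bins
  y <- dd$y
  nb <- max(dd$n_bins, max(X) + 1L)
  ny <- max(length(dd$classes), max(y) + 1L)
  m <- ncol(X)
  lowprec <- !is.null(spec)
  M <- if (lowprec) spec$M else Inf
  q <- if (lowprec) spec$q else 0
  vmax <- if (lowprec) spec$vmax else 0

  rel <- cpp_mi_columns(X, seq_len(m) - 1L, y, nb, ny, M, lowprec, q, vmax)
  n_evals <- m
  if (method == "mim") {
    ord <- order(-rel, seq_len(m))[seq_len(k)]
    return(list(features = ord, scores = rel[ord], n_evals = n_evals))
  }

  selected <- integer(k)
  scores <- numeric(k)
  in_set <- logical(m)
  acc <- numeric(m)  # cumulative redundancy (mrmr) or joint-MI sum (jmi)
  selected[1] <- which.max(rel)
  scores[1] <- rel[selected[1]]
  in_set[selected[1]] <- TRUE
  if (k > 1) for (step in 2:k) {
    cand <- which(!in_set)
    s <- selected[step - 1] - 1L
    new_terms <- if (method == "mrmr") {
      cpp_mi_with_column(X, cand - 1L, s, nb, M, lowprec, q, vmax)
    } else {
      cpp_joint_mi_columns(X, cand - 1L, s, y, nb, ny, M, lowprec, q, vmax)
    }
    n_evals <- n_evals + length(cand)
    acc[cand] <- acc[cand] + new_terms
    crit <- if (method == "mrmr") rel[cand] - acc[cand] / (step - 1)
            else acc[cand]
    pick <- cand[which.max(crit)]  # candidates ascend, so ties go low-index
    selected[step] <- pick
    scores[step] <- crit[which.max(crit)]
    in_set[pick] <- TRUE
  }
  list(features = selected, scores = scores, n_evals = n_evals)
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("Feature ranking (%s, %s, k = %d)\n", toupper(x$method),
              if (x$bits == 64) "full precision" else sprintf("%d-bit", x$bits),
              x$k))
  n <- min(10L, x$k)
  df <- data.frame(rank = seq_len(n), feature = x$feature_names[seq_len(n)],
                   score = signif(x$scores[seq_len(n)], 5))
  print(df, row.names = FALSE)
  if (x$k > n) cat(sprintf("  ... %d more\n", x$k - n))
  invisible(x)
}

#' @export
summary.feature_ranking <- function(object, ...) {
  cat(sprintf(
    "%s ranking at %s precision\n  %d features selected, %d MI evaluations\n  score range: [%.5g, %.5g]\n",
    toupper(object$method),
    if (object$bits == 64) "full (64-bit float)" else sprintf("%d-bit fixed-point", object$bits),
    object$k, object$n_evals, min(object$scores), max(object$scores)))
  invisible(object)
}

#' @export
coef.feature_ranking <- function(object, ...) {
  stats::setNames(object$scores, object$feature_names)
}

#' @export
plot.feature_ranking <- function(x, ...) {
  plot(seq_len(x$k), x$scores, type = "b", pch = 19,
       xlab = "selection step", ylab = "criterion score at selection",
       main = sprintf("%s, %s", toupper(x$method),
                      if (x$bits == 64) "full precision"
                      else sprintf("%d bits", x$bits)), ...)
  invisible(x)
}

#' Restrict new data to the selected features
#'
#' @param object A [lowmi_rank()] ranking.
#' @param newdata Matrix or data frame with the same feature columns the
#'   ranking was fitted on.
#' @param k Use only the top `k` selected features (default: all selected).
#' @param ... Unused.
#' @return `newdata` restricted (and ordered) to the selected features.
#' @export
predict.feature_ranking <- function(object, newdata, k = object$k, ...) {
  stopifnot(k >= 1, k <= object$k)
  newdata[, object$features[seq_len(k)], drop = FALSE]
}

#' Rank the same data at several bit depths
#'
#' Runs one feature-selection method at each requested bit depth on a
#' shared discretization, so depth is the only thing that varies between
#' the returned rankings.
#'
#' @param x,y,method,k,n_bins As in [lowmi_rank()].
#' @param depths Vector of total bit depths; `"full"` (or 64) denotes the
#'   double-precision baseline. Default: the conventional 4/8/16/32-bit
#'   grid plus the baseline.
#' @return A named list of `"feature_ranking"` objects (class
#'   `"ranking_set"`), named by depth.
#' @export
rank_all_depths <- function(x, y = NULL, method = c("mim", "mrmr", "jmi"),
                            k = 50, depths = c(4, 8, 16, 32, "full"),
                            n_bins = 10) {
  method <- match.arg(method)
  dd <- if (inherits(x, "discrete_dataset")) x else discrete_dataset(x, y, n_bins)
  out <- lapply(depths, function(b)
    lowmi_rank(dd, method = method, k = k, bits = b))
  names(out) <- vapply(depths, as.character, "")
  structure(out, class = c("ranking_set", "list"), method = method, k = k)
}

#' @export
print.ranking_set <- function(x, ...) {
  cat(sprintf("Ranking set: %s at depths %s (k = %d)\n",
              toupper(attr(x, "method")), paste(names(x), collapse = ", "),
              attr(x, "k")))
  invisible(x)
}
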