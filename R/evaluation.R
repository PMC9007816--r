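#' Top-k true positive rate between two rankings
#'
#' The proportion of the reference ranking's top-k features that also
#' appear in the candidate ranking's top-k. The comparison is set-based:
#' order within the top-k is irrelevant, so the statistic is symmetric in
#' its two arguments and invariant to permutations below rank k.
#'
#' @param reference,candidate `"feature_ranking"` objects (or plain integer
#'   vectors of ranked feature indices), each covering at least `k`
#'   features.
#' @param k Size of the top sets to compare.
#' @return A proportion in `[0, 1]`.
#' @export
tpr_top_k <- function(reference, candidate, k) {
  ref <- ranked_features(reference)
  can <- ranked_features(candidate)
  if (k < 1 || k > length(ref) || k > length(can))
    stop("'k' exceeds the length of a ranking")
  length(intersect(ref[seq_len(k)], can[seq_len(k)])) / k
}

ranked_features <- function(r) {
  if (inherits(r, "feature_ranking")) r$features else as.integer(r)
}

#' TPR grid across methods, depths and top-k sizes
#'
#' For each method, ranks the data once per bit depth (plus the
#' full-precision reference) and tabulates the top-k true positive rate of
#' every low-precision ranking against the reference at every requested k.
#'
#' @param x,y,n_bins As in [lowmi_rank()].
#' @param methods Subset of `c("mim", "mrmr", "jmi")`.
#' @param depths Bit depths to compare against the full-precision
#'   reference.
#' @param k_values Top-k sizes; rankings are computed to `max(k_values)`.
#' @return A data frame with columns `method`, `bits`, `k`, `tpr`.
#' @export
compare_rankings <- function(x, y = NULL, methods = c("mim", "mrmr", "jmi"),
                             depths = c(4, 8, 16, 32),
                             k_values = c(5, 10, 20, 30, 40, 50),
                             n_bins = 10) {
  dd <- if (inherits(x, "discrete_dataset")) x else discrete_dataset(x, y, n_bins)
  kmax <- max(k_values)
  rows <- list()
  for (method in methods) {
    rs <- rank_all_depths(dd, method = method, k = kmax,
                          depths = c(as.list(depths), list("full")))
    ref <- rs[["full"]]
    for (b in as.character(depths)) for (k in k_values) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, bits = as.integer(b), k = k,
        tpr = tpr_top_k(ref, rs[[b]], k))
    }
  }
  do.call(rbind, rows)
}

#' Reference 3-nearest-neighbour classifier
#'
#' A deliberately simple Euclidean k-NN majority vote, so the
#' cross-validation harness has a classifier with no external dependency
#' and no tuning. Ties in the vote are broken in favour of the tied class
#' with the nearest voting neighbour, then by the smallest class label;
#' ties in distance by training-sample order.
#'
#' @param train Numeric training matrix (samples x features).
#' @param labels Training class labels.
#' @param test Numeric test matrix with the same features.
#' @param n_neighbors Number of neighbours (default 3).
#' @return Predicted labels for the rows of `test`, of the same type as
#'   `labels`.
#' @export
reference_knn <- function(train, labels, test, n_neighbors = 3) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (nrow(train) < 1) stop("at least one training sample is required")
  nn <- min(n_neighbors, nrow(train))
  f <- as.factor(labels)
  # squared Euclidean cross-distances via the expanded inner product
  d2 <- outer(rowSums(test^2), rep(1, nrow(train))) +
        outer(rep(1, nrow(test)), rowSums(train^2)) -
        2 * tcrossprod(test, train)
  pred <- vapply(seq_len(nrow(test)), function(t) {
    i <- order(d2[t, ])[seq_len(nn)]  # nearest first
    votes <- table(f[i])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      # tied vote: the class with the nearest voting neighbour wins; a
      # stable sort leaves equally-near classes in label order
      nearest <- vapply(top, function(cl)
        min(d2[t, i[as.character(f[i]) == cl]]), 0)
      top <- top[order(nearest)]
    }
    top[1]
  }, "")
  if (is.factor(labels)) factor(pred, levels = levels(f))
  else if (is.numeric(labels)) as.numeric(pred)
  else pred
}

#' Repeated stratified cross-validation with feature selection in the loop
#'
#' For each repetition and stratified fold: the training fold is
#' discretized (bin edges fitted on the training fold only), features are
#' ranked at the requested method/bit depth, the original undiscretized
#' train and test matrices are restricted to the top-k features, and the
#' classifier is fitted and scored. Performing selection inside the loop
#' avoids the optimistic bias of selecting on the full data.
#'
#' @param x Continuous feature matrix (samples x features).
#' @param y Class labels.
#' @param method,bits,k,n_bins Feature-selection configuration (see
#'   [lowmi_rank()]).
#' @param classifier Either `"knn3"` (the built-in [reference_knn()]) or a
#'   function `f(train, labels, test)` returning predicted labels.
#' @param repetitions,folds Cross-validation design (default 3 x 5-fold).
#' @param seed Master seed; each repetition reshuffles folds with a seed
#'   derived deterministically from it.
#' @return An object of class `"cv_result"`: a data frame of per-fold
#'   accuracies (`$folds`), the overall `mean_accuracy` (percent), and the
#'   configuration.
#' @export
run_cv <- function(x, y, method = "mim", bits = "full", k = 20,
                   classifier = "knn3", repetitions = 3, folds = 5,
                   seed = 1, n_bins = 10) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nrow(x) < folds) stop("need at least as many samples as folds")
  if (min(table(y)) < folds)
    stop("every class needs at least as many members as folds for stratification")
  clf <- if (is.function(classifier)) classifier
         else if (identical(classifier, "knn3")) reference_knn
         else stop("unknown classifier; pass \"knn3\" or a function")
  rows <- list()
  for (rep_i in seq_len(repetitions)) {
    fold_of <- stratified_folds(y, folds, seed = seed * 1000L + rep_i)
    for (fold_i in seq_len(folds)) {
      test_idx <- which(fold_of == fold_i)
      train_idx <- which(fold_of != fold_i)
      fit <- lowmi_rank(x[train_idx, , drop = FALSE], y[train_idx],
                        method = method, k = k, bits = bits, n_bins = n_bins)
      sel <- fit$features[seq_len(k)]
      pred <- clf(x[train_idx, sel, drop = FALSE], y[train_idx],
                  x[test_idx, sel, drop = FALSE])
      acc <- 100 * mean(as.character(pred) == as.character(y[test_idx]))
      rows[[length(rows) + 1L]] <- data.frame(
        repetition = rep_i, fold = fold_i, accuracy = acc)
    }
  }
  df <- do.call(rbind, rows)
  structure(
    list(folds = df, mean_accuracy = mean(df$accuracy),
         config = list(method = method, bits = bits, k = k,
                       classifier = if (is.function(classifier)) "custom"
                                    else classifier,
                       repetitions = repetitions, folds = folds,
                       n_bins = n_bins, seed = seed)),
    class = "cv_result"
  )
}

# Stratified fold assignment: within each class, samples are shuffled with
# the given seed and dealt round-robin across folds.
stratified_folds <- function(y, folds, seed) {
  fold_of <- integer(length(y))
  rng <- local_rng(seed)
  on.exit(rng())
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

# Seed the RNG locally; returns a restorer for on.exit.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.cv_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "%d x %d-fold CV: %s at %s, top-%d features, %s classifier\n  mean accuracy: %.2f%% (fold sd %.2f)\n",
    cfg$repetitions, cfg$folds, toupper(cfg$method),
    if (identical(cfg$bits, "full") || identical(cfg$bits, 64)) "full precision"
    else sprintf("%s bits", cfg$bits),
    cfg$k, cfg$classifier, x$mean_accuracy, stats::sd(x$folds$accuracy)))
  invisible(x)
}
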