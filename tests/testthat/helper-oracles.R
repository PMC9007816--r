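# Independent brute-force oracles. These share no code with the package
# internals: MI is evaluated with table() and a direct term-by-term sum,
# the greedy criteria are re-implemented literally, and the k-NN oracle
# computes every distance explicitly.

oracle_mi <- function(x, y) {
  tab <- table(x, y)
  C <- sum(tab)
  px <- rowSums(tab) / C
  py <- colSums(tab) / C
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    p <- tab[i, j] / C
    if (p > 0) mi <- mi + p * log(p / (px[i] * py[j]))
  }
  unname(mi)
}

oracle_joint_mi <- function(x1, x2, y) {
  oracle_mi(paste(x1, x2), y)
}

# Literal greedy evaluation of the three selection criteria in double
# precision, ties by ascending feature index.
oracle_greedy_rank <- function(X, y, method, k) {
  m <- ncol(X)
  rel <- vapply(seq_len(m), function(j) oracle_mi(X[, j], y), 0)
  if (method == "mim") return(order(-rel, seq_len(m))[seq_len(k)])
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(m), sel)
    crit <- vapply(cand, function(f) {
      if (length(sel) == 0) return(rel[f])
      if (method == "mrmr") {
        rel[f] - mean(vapply(sel, function(s) oracle_mi(X[, f], X[, s]), 0))
      } else {
        sum(vapply(sel, function(s) oracle_joint_mi(X[, f], X[, s], y), 0))
      }
    }, 0)
    sel <- c(sel, cand[which.max(crit)])
  }
  sel
}

oracle_knn <- function(train, labels, test, k = 3) {
  labels <- as.factor(labels)
  apply(as.matrix(test), 1, function(p) {
    d <- sqrt(colSums((t(as.matrix(train)) - p)^2))
    votes <- table(labels[order(d)[seq_len(k)]])
    names(votes)[which.max(votes)]
  })
}

# Quantized log-ratio reimplemented from its definition (round half away
# from zero, clamp to the representable range).
oracle_quant_log <- function(i, j, q, bi) {
  v <- sign(log(i / j) / q) * floor(abs(log(i / j) / q) + 0.5) * q
  pmin(pmax(v, -(2^bi - q)), 2^bi - q)
}

# Small random discrete dataset for oracle-equivalence sweeps.
random_discrete_data <- function(n, m, n_bins = 4, seed) {
  set.seed(seed)
  X <- matrix(sample.int(n_bins, n * m, replace = TRUE) - 1L, n, m)
  y <- sample.int(2, n, replace = TRUE) - 1L
  # a couple of weakly class-linked columns so rankings are not pure noise
  X[, 1] <- (y + stats::rbinom(n, 1, 0.3)) %% 2
  X[, 2] <- (y + stats::rbinom(n, 1, 0.4)) %% 2
  list(X = X, y = y)
}
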