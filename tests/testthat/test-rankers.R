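test_that("MIM ranks a perfect copy above noise above a constant", {
  set.seed(31)
  n <- 100
  y <- rep(0:1, n / 2)
  x <- cbind(f0 = y + rnorm(n, sd = 0.05),
             f1 = rnorm(n),
             f2 = rep(1, n))
  fit <- lowmi_rank(x, y, method = "mim", k = 3)
  expect_equal(fit$features, c(1L, 2L, 3L))
  expect_gt(fit$scores[1], fit$scores[2])
  expect_identical(fit$scores[3], 0)
})

test_that("exact ties fall back to ascending feature index", {
  x <- matrix(rep(c(0, 1, 2, 3), 5), ncol = 5)
  y <- rep(0:1, 2)
  for (method in c("mim", "mrmr", "jmi")) {
    fit <- lowmi_rank(discrete_dataset(x, y, n_bins = 4),
                      method = method, k = 5)
    expect_equal(fit$features, 1:5, info = method)
  }
})

test_that("full-precision rankings match brute-force greedy oracles", {
  for (seed in 1:20) {
    d <- random_discrete_data(n = 60, m = 10, n_bins = 4, seed = seed)
    dd <- discrete_dataset(d$X, d$y, n_bins = 4)
    for (method in c("mim", "mrmr", "jmi")) {
      fit <- lowmi_rank(dd, method = method, k = 10)
      expect_equal(fit$features,
                   oracle_greedy_rank(d$X, d$y, method, 10),
                   info = sprintf("%s seed %d", method, seed))
    }
  }
})

test_that("mRMR postpones a redundant copy that MIM ranks on top", {
  set.seed(33)
  n <- 400
  y <- rep(0:1, n / 2)
  f0 <- (y + rbinom(n, 1, 0.05)) %% 2          # strong, noisy copy of y
  x <- cbind(f0 = f0,
             f1 = f0,                           # exact duplicate of f0
             f2 = (y + rbinom(n, 1, 0.25)) %% 2,  # weaker, different noise
             f3 = rbinom(n, 1, 0.5))
  dd <- discrete_dataset(x, y, n_bins = 2)
  mim <- lowmi_rank(dd, method = "mim", k = 4)
  mrmr <- lowmi_rank(dd, method = "mrmr", k = 4)
  expect_equal(mim$features[1:2], c(1L, 2L))      # duplicate right behind
  expect_lt(which(mrmr$features == 3), which(mrmr$features == 2))
  expect_equal(mrmr$features,
               oracle_greedy_rank(x, y, "mrmr", 4))
})

test_that("JMI picks up the complementary partner of a selected feature", {
  set.seed(34)
  n <- 400
  a <- rbinom(n, 1, 0.5)
  b <- rbinom(n, 1, 0.2)       # biased, so 'a' is weakly relevant alone
  y <- (a + b) %% 2
  x <- cbind(a, b, matrix(rbinom(n * 4, 1, 0.5), n))
  dd <- discrete_dataset(x, y, n_bins = 2)
  # b alone is almost uninformative, but (a, b) determines y exactly
  rel <- vapply(1:6, function(j) oracle_mi(x[, j], y), 0)
  expect_gt(rel[1], 0.1)
  expect_lt(rel[2], 0.02)
  fit <- lowmi_rank(dd, method = "jmi", k = 3)
  expect_equal(fit$features[1:2], c(1L, 2L))
  expect_equal(fit$features, oracle_greedy_rank(x, y, "jmi", 3))
  # MIM, blind to complementarity, leaves the partner near the bottom
  mim <- lowmi_rank(dd, method = "mim", k = 6)
  expect_gt(which(mim$features == 2L), 2)
})

test_that("mRMR and JMI coincide with MIM at the first selection", {
  set.seed(35)
  d <- random_discrete_data(80, 12, seed = 99)
  dd <- discrete_dataset(d$X, d$y, n_bins = 4)
  first <- vapply(c("mim", "mrmr", "jmi"), function(m)
    lowmi_rank(dd, method = m, k = 1)$features, 0L)
  expect_true(all(first == first[1]))
})

test_that("rankings are deterministic and depth grids reuse discretization", {
  set.seed(36)
  x <- matrix(rnorm(150 * 40), 150, 40)
  y <- as.integer(x[, 5] > 0)
  a <- lowmi_rank(x, y, method = "jmi", k = 10, bits = 8)
  b <- lowmi_rank(x, y, method = "jmi", k = 10, bits = 8)
  expect_identical(a$features, b$features)
  expect_identical(a$scores, b$scores)
  rs <- rank_all_depths(x, y, method = "mim", k = 10,
                        depths = c(8, 8, "full"))
  expect_identical(rs[[1]]$features, rs[[2]]$features)
  expect_identical(rs[["full"]]$features,
                   lowmi_rank(x, y, method = "mim", k = 10)$features)
})

test_that("top-k recovery does not degrade as bit depth increases", {
  set.seed(37)
  ds <- synth_microarray(synth_config(n = 150, m = 300, n_relevant = 15,
                                      effect_size = 1.5, seed = 3))
  rs <- rank_all_depths(ds$x, ds$y, method = "mim", k = 20,
                        depths = c(8, 16, 32, "full"))
  ref <- rs[["full"]]
  tprs <- vapply(c("8", "16", "32"), function(b)
    tpr_top_k(ref, rs[[b]], 20), 0)
  expect_true(all(diff(tprs) >= -0.05))  # sampling slack on a finite grid
  expect_gte(tprs[["32"]], 0.95)
})

test_that("estimator invocations respect the k*m and k^2*m complexity bounds", {
  for (cfg in list(c(m = 100, k = 10), c(m = 200, k = 20))) {
    set.seed(38)
    m <- cfg[["m"]]; k <- cfg[["k"]]
    x <- matrix(rnorm(50 * m), 50, m)
    y <- rep(0:1, 25)
    dd <- discrete_dataset(x, y)
    mim <- lowmi_rank(dd, method = "mim", k = k)
    expect_equal(mim$n_evals, m)
    expect_lte(mim$n_evals, 2 * k * m)
    for (method in c("mrmr", "jmi")) {
      fit <- lowmi_rank(dd, method = method, k = k)
      expect_equal(fit$n_evals, m + sum(m - seq_len(k - 1)))
      expect_lte(fit$n_evals, 2 * k^2 * m)
    }
  }
})

test_that("k outside [1, m] and unknown methods are rejected", {
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(0:1, 10)
  expect_error(lowmi_rank(x, y, k = 3), "'k'")
  expect_error(lowmi_rank(x, y, k = 0), "'k'")
  expect_error(lowmi_rank(x, y, method = "cmim"), "arg")
})
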