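make_counts <- function(joint) {
  # counter table from an explicit joint count matrix (no saturation)
  xs <- integer(0); ys <- integer(0)
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    xs <- c(xs, rep(i - 1L, joint[i, j]))
    ys <- c(ys, rep(j - 1L, joint[i, j]))
  }
  accumulate_counts(xs, ys)
}

test_that("the plug-in estimator reproduces direct evaluation of the MI sum", {
  ct <- make_counts(rbind(c(2, 1), c(1, 2)))
  est <- plugin_mi(ct)
  # direct term-by-term value on this 2x2 table is 0.056633...
  expect_equal(est$value, oracle_mi(rep(0:1, c(3, 3)), c(0, 0, 1, 0, 1, 1)),
               tolerance = 1e-12)
  expect_equal(est$value, 0.05663, tolerance = 1e-4)
  expect_identical(est$bits, 64)
})

test_that("degenerate and perfectly dependent tables hit the closed forms", {
  expect_identical(plugin_mi(make_counts(cbind(c(3, 4))))$value, 0)
  expect_equal(plugin_mi(make_counts(rbind(c(3, 0), c(0, 3))))$value, log(2))
})

test_that("the low-precision estimate is an explicit sum of LUT entries", {
  spec <- fixed_point_spec(4, 2)
  lut <- build_lut(spec)
  ct <- make_counts(rbind(c(2, 1), c(1, 2)))
  got <- lowprec_mi(ct, lut)
  # the four nonzero cells, summed by hand from the independently built LUT
  hand <- 0
  for (i in 1:2) for (j in 1:2) {
    c_xy <- ct$joint[i, j]
    hand <- hand + (c_xy / 6) *
      (oracle_quant_log(c_xy, 6, spec$q, spec$bi) -
         oracle_quant_log(ct$marginal_x[i], 6, spec$q, spec$bi) -
         oracle_quant_log(ct$marginal_y[j], 6, spec$q, spec$bi))
  }
  expect_identical(got$value, hand)
  expect_identical(got$bits, 6L)
})

test_that("constant Y gives exactly zero at every precision", {
  xs <- c(0, 1, 2, 0, 1, 2)
  ct <- accumulate_counts(xs, rep(0, 6))
  expect_identical(plugin_mi(ct)$value, 0)
  for (b in c(2, 4, 8)) {
    spec <- fixed_point_spec(b, b)
    expect_identical(lowprec_mi(ct, build_lut(spec))$value, 0)
  }
})

test_that("quantization error is bounded and shrinks as bf grows", {
  set.seed(5)
  tables <- replicate(200, {
    joint <- matrix(sample(0:1, 4, replace = TRUE), 2)
    if (sum(joint) == 0) joint[1, 1] <- 1
    joint
  }, simplify = FALSE)
  max_dev <- c()
  for (bf in c(2, 4, 8, 16)) {
    spec <- fixed_point_spec(bf, bf)
    lut <- build_lut(spec)
    devs <- vapply(tables, function(joint) {
      ct <- make_counts(joint)
      stopifnot(ct$C <= spec$M / 2)  # no saturation in this sweep
      dev <- abs(lowprec_mi(ct, lut)$value - plugin_mi(ct)$value)
      bound <- 1.5 * spec$q * sum(joint > 0)
      expect_lte(dev, bound)
      dev
    }, 0)
    max_dev <- c(max_dev, max(devs))
  }
  expect_true(all(diff(max_dev) < 0))
})

test_that("both estimators are symmetric under swapping the variables", {
  set.seed(9)
  spec <- fixed_point_spec(4, 4)
  lut <- build_lut(spec)
  for (i in 1:20) {
    xs <- sample.int(3, 40, TRUE) - 1L
    ys <- sample.int(4, 40, TRUE) - 1L
    a <- accumulate_counts(xs, ys, spec)
    b <- accumulate_counts(ys, xs, spec)
    expect_equal(plugin_mi(a)$value, plugin_mi(b)$value, tolerance = 1e-12)
    expect_equal(lowprec_mi(a, lut)$value, lowprec_mi(b, lut)$value,
                 tolerance = 1e-12)
  }
})

test_that("plug-in MI is non-negative; low-precision MI bounded below", {
  set.seed(13)
  spec <- fixed_point_spec(3, 3)
  lut <- build_lut(spec)
  for (i in 1:50) {
    xs <- sample.int(4, 30, TRUE) - 1L
    ys <- sample.int(2, 30, TRUE) - 1L
    ct <- accumulate_counts(xs, ys, spec)
    expect_gte(plugin_mi(accumulate_counts(xs, ys))$value, 0)
    expect_gte(lowprec_mi(ct, lut)$value,
               -1.5 * spec$q * sum(ct$joint > 0))
  }
})

test_that("a duplicated coordinate adds no joint information", {
  set.seed(21)
  spec <- fixed_point_spec(6, 6)
  xs <- sample.int(4, 80, TRUE) - 1L
  ys <- sample.int(2, 80, TRUE) - 1L
  joint <- lowprec_joint_mi(xs, xs, ys, spec)
  single <- lowprec_mi(accumulate_counts(xs, ys, spec), build_lut(spec))
  expect_identical(joint$value, single$value)
})

test_that("joint MI of independent variables is near zero at high precision", {
  set.seed(22)
  spec <- fixed_point_spec(8, 8)
  n <- 4000
  xs1 <- sample.int(3, n, TRUE) - 1L
  xs2 <- sample.int(3, n, TRUE) - 1L
  ys <- sample.int(2, n, TRUE) - 1L
  est <- lowprec_joint_mi(xs1, xs2, ys, spec)
  expect_lt(abs(est$value), 0.05)
  expect_equal(est$value, oracle_joint_mi(xs1, xs2, ys), tolerance = 0.02)
})

test_that("adding a coordinate cannot lose information (up to quantization)", {
  set.seed(23)
  spec <- fixed_point_spec(8, 8)
  lut <- build_lut(spec)
  for (i in 1:10) {
    xs1 <- sample.int(3, 120, TRUE) - 1L
    xs2 <- sample.int(3, 120, TRUE) - 1L
    ys <- xs1 %% 2
    joint <- lowprec_joint_mi(xs1, xs2, ys, spec, lut)$value
    single <- lowprec_mi(accumulate_counts(xs2, ys, spec), lut)$value
    slack <- 3 * spec$q * 18
    expect_gte(joint, single - slack)
  }
})

test_that("the convenience wrapper routes to the right estimator", {
  x <- rep(0:1, each = 10)
  expect_equal(mutual_information(x, x)$value, log(2))
  est <- mutual_information(x, x, bits = 8)
  expect_identical(est$bits, 8L)
  expect_lt(abs(est$value - log(2)), 3 * 2^-4)
})
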