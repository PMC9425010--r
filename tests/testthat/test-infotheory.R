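# Discrete information-theory engine: oracle equivalence and identities.

test_that("shannon_entropy matches closed forms", {
  expect_equal(shannon_entropy(c(0, 1, 0, 1)), 1)
  expect_equal(shannon_entropy(rep("a", 10)), 0)
  expect_equal(shannon_entropy(1:8), 3)
  # H(p) for p = (1/2, 1/4, 1/4)
  expect_equal(shannon_entropy(c(1, 1, 2, 3)), 1.5)
  expect_error(shannon_entropy(integer(0)), "non-empty")
})

test_that("entropy/MI/CMI match the brute-force oracle on random tables", {
  set.seed(42)
  for (r in 1:200) {
    n <- sample(20:60, 1)
    x <- sample.int(sample(2:4, 1), n, replace = TRUE)
    y <- sample.int(sample(2:4, 1), n, replace = TRUE)
    z <- sample.int(sample(2:4, 1), n, replace = TRUE)
    expect_equal(shannon_entropy(x), oracle_entropy(x), tolerance = 1e-12)
    expect_equal(mutual_information(x, y), max(0, oracle_mi(x, y)),
                 tolerance = 1e-12)
    expect_equal(conditional_mutual_information(x, y, z),
                 max(0, oracle_cmi(x, y, z)), tolerance = 1e-12)
  }
})

test_that("MI is symmetric, non-negative, and bounded by marginal entropies", {
  set.seed(7)
  x <- sample(letters[1:3], 50, replace = TRUE)
  y <- sample(1:4, 50, replace = TRUE)
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  expect_gte(mutual_information(x, y), 0)
  expect_lte(mutual_information(x, y),
             min(shannon_entropy(x), shannon_entropy(y)) + 1e-12)
  expect_equal(mutual_information(x, x), shannon_entropy(x))
})

test_that("chain rule I(XY;L) = I(X;L) + I(Y;L|X) holds", {
  set.seed(11)
  for (r in 1:20) {
    x <- sample(1:3, 40, replace = TRUE)
    y <- sample(1:3, 40, replace = TRUE)
    l <- sample(0:1, 40, replace = TRUE)
    lhs <- mutual_information(list(x, y), l)
    rhs <- mutual_information(x, l) + conditional_mutual_information(y, l, x)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("XOR synergy: individually useless markers jointly carry 1 bit", {
  x <- c(0, 0, 1, 1)
  y <- c(0, 1, 0, 1)
  l <- as.integer(xor(x, y))
  expect_equal(mutual_information(x, l), 0)
  expect_equal(mutual_information(y, l), 0)
  expect_equal(mutual_information(list(x, y), l), 1)
  expect_equal(incremental_gain(x, y, l), 1)
})

test_that("joint coding accepts lists and data.frames equivalently", {
  set.seed(3)
  a <- sample(1:3, 30, replace = TRUE)
  b <- sample(1:2, 30, replace = TRUE)
  l <- sample(0:1, 30, replace = TRUE)
  expect_equal(mutual_information(list(a, b), l),
               mutual_information(data.frame(a, b), l))
  expect_error(mutual_information(1:5, 1:6), "equal length")
})

test_that("joint coding survives wide panels without integer overflow", {
  set.seed(9)
  panel <- replicate(25, sample(1:4, 60, replace = TRUE), simplify = FALSE)
  l <- sample(0:1, 60, replace = TRUE)
  # joint level space 4^25 >> .Machine$integer.max; must still work
  got <- mutual_information(panel, l)
  key <- do.call(paste, panel)
  expect_equal(got, max(0, oracle_mi(key, l)), tolerance = 1e-12)
})

test_that("percent_of_max_info normalizes against label entropy", {
  set.seed(5)
  l <- sample(0:1, 100, replace = TRUE)
  res <- percent_of_max_info(l, l)
  expect_s3_class(res, "info_result")
  expect_equal(res$percent_of_max, 100)
  x <- sample(1:3, 100, replace = TRUE)
  res2 <- percent_of_max_info(x, l, n_perm = 99, seed = 1)
  expect_equal(res2$percent_of_max,
               100 * mutual_information(x, l) / shannon_entropy(l))
  expect_true(res2$p_value > 0 && res2$p_value <= 1)
  expect_error(percent_of_max_info(x, rep(1, 100)), "H\\(label\\) = 0")
})

test_that("incremental gain of the plug-in estimator is non-negative", {
  set.seed(13)
  for (r in 1:20) {
    base <- sample(1:3, 40, replace = TRUE)
    add <- sample(1:3, 40, replace = TRUE)
    l <- sample(0:1, 40, replace = TRUE)
    expect_gte(incremental_gain(base, add, l), -1e-12)
  }
})

test_that("discretize: equal-frequency bins are balanced and cover all points", {
  x <- 1:100
  f <- discretize(x, 4)
  expect_equal(as.numeric(table(f)), rep(25, 4))
  expect_equal(length(f), 100)
  expect_false(anyNA(f))
  # equal width on a uniform grid agrees
  fw <- discretize(x, 4, strategy = "equal_width")
  expect_equal(as.numeric(table(fw)), rep(25, 4))
  # the maximum lands in the last bin, not NA
  expect_equal(as.integer(f[100]), nlevels(f))
})

test_that("discretize handles ties, constants and few distinct values", {
  expect_warning(f <- discretize(rep(2, 10), 3), "constant")
  expect_equal(nlevels(f), 1)
  expect_warning(g <- discretize(rep(c(1, 5), 10), 4), "distinct")
  expect_equal(nlevels(g), 2)
  # ties land in the same bin
  x <- c(rep(1, 50), rep(2, 50), 3, 4)
  h <- discretize(x, 4)
  expect_equal(length(unique(as.integer(h)[x == 1])), 1)
  expect_error(discretize(c(1, NA), 2), "finite")
  expect_error(discretize(1:10, 1), ">= 2")
})

test_that("permutation p-values use the add-one rule and never return 0", {
  x <- c(rep(0, 25), rep(1, 25))
  p <- permutation_significance(mutual_information, x, x, n_perm = 99,
                                seed = 1)
  expect_equal(p, 1 / 100)  # nothing can beat a perfect association
  # generic (non-MI) statistic path agrees with the fast path
  slow_mi <- function(a, b) mutual_information(a, b)
  set.seed(2)
  y <- sample(0:1, 50, replace = TRUE)
  p_fast <- permutation_significance(mutual_information, x, y, n_perm = 199,
                                     seed = 7)
  p_slow <- permutation_significance(slow_mi, x, y, n_perm = 199, seed = 7)
  expect_equal(p_fast, p_slow)
})

test_that("significance stars map thresholds correctly", {
  expect_equal(significance_stars(c(0.2, 0.05, 0.01, 0.001, 1e-4, 1e-6)),
               c("", "*", "**", "***", "****", "****"))
})
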