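test_that("U counts pairs favouring the first sample (plus half ties)", {
  res <- mannWhitneyU(c(4, 5, 6), c(1, 2, 3))
  expect_identical(statistic(res), 9)                 # complete separation
  expect_equal(pValue(mannWhitneyU(c(4, 5, 6), c(1, 2, 3), sided = "one",
                                   direction = "greater")),
               1 / choose(6, 3), tolerance = 1e-15)
  expect_identical(statistic(mannWhitneyU(c(1, 1), c(1, 1))), 2)  # all ties
})

test_that("identical samples give exact two-sided p of 1", {
  res <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_identical(res@method, "exact")
  expect_identical(pValue(res), 1)
})

test_that("small tied samples match full enumeration of labelings", {
  # x = {1,3}, y = {2,4}: U = 2 (pairs 3>2 plus 1>nothing... enumerate)
  res <- mannWhitneyU(c(1, 3), c(2, 4))
  expect_identical(statistic(res), 1)
  # all C(4,2) = 6 labelings of ranks {1,2,3,4}; U values: 0,1,1,2,3,2...
  r <- c(1, 3, 2, 4)
  Us <- apply(combn(4, 2), 2, function(ix) sum(rank(r)[ix]) - 3)
  pOracle <- min(1, 2 * min(mean(Us <= 1), mean(Us >= 1)))
  expect_equal(pValue(res), pOracle, tolerance = 1e-15)
})

test_that("exact U and p agree with wilcox.test on untied samples", {
  set.seed(20)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(9)
    mine <- mannWhitneyU(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_identical(statistic(mine), unname(ref$statistic))
    expect_equal(pValue(mine), ref$p.value, tolerance = 1e-12)
    mineL <- mannWhitneyU(x, y, sided = "one", direction = "less")
    refL <- wilcox.test(x, y, exact = TRUE, alternative = "less")
    expect_equal(pValue(mineL), refL$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation with ties matches wilcox.test's corrected z", {
  set.seed(21)
  for (rep in 1:5) {
    x <- sample(1:6, 25, replace = TRUE)
    y <- sample(1:6, 30, replace = TRUE)
    mine <- mannWhitneyU(x, y, method = "normal")
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(pValue(mine), ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact and normal-approximate p agree closely at n = 10 + 10", {
  set.seed(22)
  for (rep in 1:20) {
    x <- rnorm(10); y <- rnorm(10, mean = runif(1, -1, 1))
    pe <- pValue(mannWhitneyU(x, y, method = "exact"))
    pn <- pValue(mannWhitneyU(x, y, method = "normal"))
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(23)
  x <- rnorm(12); y <- rnorm(15)
  f <- function(v) exp(2 * v) - 1
  expect_identical(statistic(mannWhitneyU(x, y)),
                   statistic(mannWhitneyU(f(x), f(y))))
  expect_identical(pValue(mannWhitneyU(x, y)),
                   pValue(mannWhitneyU(f(x), f(y))))
  a <- rnorm(15); b <- rnorm(15)
  expect_identical(statistic(kendallTauB(a, b)),
                   statistic(kendallTauB(f(a), f(b))))
})

test_that("empty samples are rejected", {
  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("tau-b handles perfect order, hand-checked pairs and reversal", {
  expect_identical(statistic(kendallTauB(1:3, 1:3)), 1)
  expect_equal(statistic(kendallTauB(1:4, c(2, 1, 4, 3))), 1 / 3,
               tolerance = 1e-15)
  set.seed(24)
  x <- rnorm(10); y <- rnorm(10)
  expect_identical(statistic(kendallTauB(x, -y)),
                   -statistic(kendallTauB(x, y)))
})

test_that("tau-b and its p agree with cor.test, with and without ties", {
  set.seed(25)
  for (rep in 1:8) {
    x <- rnorm(20); y <- 0.4 * x + rnorm(20)
    mine <- kendallTauB(x, y)                       # n > 8 -> normal approx
    ref <- cor.test(x, y, method = "kendall", exact = FALSE)
    expect_equal(statistic(mine), unname(ref$estimate), tolerance = 1e-12)
    expect_equal(pValue(mine), ref$p.value, tolerance = 1e-9)
  }
  for (rep in 1:5) {
    x <- sample(1:5, 20, replace = TRUE)            # heavy ties
    y <- sample(1:5, 20, replace = TRUE)
    mine <- kendallTauB(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "kendall",
                                     exact = FALSE))
    expect_equal(statistic(mine), unname(ref$estimate), tolerance = 1e-12)
    expect_equal(pValue(mine), ref$p.value, tolerance = 1e-9)
  }
})

test_that("exact permutation p at small n matches cor.test's exact p", {
  set.seed(26)
  for (rep in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    mine <- kendallTauB(x, y)                       # auto -> exact for n <= 8
    expect_identical(mine@method, "exact")
    ref <- cor.test(x, y, method = "kendall", exact = TRUE)
    expect_equal(pValue(mine), ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate correlation inputs raise errors", {
  expect_error(kendallTauB(rep(1, 5), 1:5), "tied")
  expect_error(kendallTauB(1:4, 1:5), "length")
  expect_error(kendallTauB(1:2, 1:2), "at least 3")
})

test_that("Benjamini-Hochberg helper appends adjusted p-values", {
  tab <- data.frame(p = c(0.01, 0.04, 0.2))
  out <- adjustBH(tab)
  expect_equal(out$p_adj, p.adjust(tab$p, "BH"), tolerance = 1e-15)
})
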