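test_that("the dip test rejects bimodality and respects the unimodal null", {
  set.seed(71)
  bim <- c(rnorm(250, 0, 0.01), rnorm(250, 1, 0.01))
  r <- dipTest(bim, nBoot = 2000, seed = 1)
  expect_lt(r$p, 0.01)
  expect_true(r$dip >= 1 / (2 * 500) && r$dip <= 0.25)

  uni <- replicate(15, dipTest(rnorm(500), nBoot = 500)$p > 0.05)
  expect_gte(mean(uni), 0.9)

  expect_error(dipTest(c(1, 2, 3)), "at least 4")
})

test_that("the dip statistic matches hand anchors and the LP reference", {
  expect_equal(dipStatistic(c(0, 1)), 0.25, tolerance = 1e-9)
  expect_equal(dipStatistic(c(0, 1, 2)), 1 / 6, tolerance = 1e-9)

  set.seed(72)
  for (i in 1:12) {
    n <- sample(5:18, 1)
    x <- switch(sample(3, 1), runif(n), rnorm(n),
                c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 4)))
    expect_equal(dipStatistic(x), dipLpOracle(x), tolerance = 1e-10)
  }
  ## affine invariance
  x <- rnorm(40)
  expect_equal(dipStatistic(x), dipStatistic(5 * x + 3), tolerance = 1e-9)
})

test_that("two-sample KS follows the empirical-cdf sup difference", {
  set.seed(73)
  x <- rnorm(50)
  expect_equal(ksTwoSample(x, x)$D, 0)
  expect_equal(ksTwoSample(rnorm(30), rnorm(30) + 100)$D, 1)
  ## brute-force ECDF enumeration on small samples
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1))
    grid <- sort(c(a, b))
    Dref <- max(abs(vapply(grid, function(g)
      mean(a <= g) - mean(b <= g), numeric(1))))
    expect_equal(ksTwoSample(a, b)$D, Dref, tolerance = 1e-12)
  }
  expect_error(ksTwoSample(1, rnorm(5)), "n >= 2")
})

test_that("rank-sum p-values are exact for small samples, normal beyond", {
  x <- c(1, 2, 3, 4, 5); y <- c(6, 7, 8, 9, 10)
  r <- rankSumTest(x, y)
  expect_true(r$exact)
  expect_equal(r$p, 2 / choose(10, 5))
  expect_equal(r$p, ranksumEnumOracle(x, y))

  set.seed(74)
  a <- rnorm(10); b <- rnorm(10, 0.8)
  big <- rankSumTest(a, b)
  expect_false(big$exact)
  expect_lt(abs(big$p - ranksumEnumOracle(a, b)), 0.01)

  ## permutation invariance of the inputs
  expect_equal(rankSumTest(sample(a), sample(b))$p, big$p)
  same <- rankSumTest(c(1, 2, 2, 3), c(2, 1, 3, 2))
  expect_equal(same$p, 1)
  expect_error(rankSumTest(numeric(0), 1), "non-empty")
})

test_that("ET scores are hit/FA ratios with a flagged undefined case", {
  e <- etScore(0.57, 0.50)
  expect_equal(e$score, 1.14)
  expect_equal(etScore(0.4, 0.4)$score, 1)
  z <- etScore(0.5, 0)
  expect_true(z$undefined && is.na(z$score))
  expect_error(etScore(1.2, 0.5), "\\[0, 1\\]")
})

test_that("subgroup splitting is dip-gated and recovers planted labels", {
  set.seed(75)
  nBroad <- 10; nNarrow <- 13
  summaries <- data.frame(
    participant = sprintf("p%02d", 1:(nBroad + nNarrow)),
    maxVariance = c(rlnorm(nBroad, log(6e-3), 0.15),
                    rlnorm(nNarrow, log(2.4e-3), 0.15)))
  pooled <- c(rlnorm(1500, log(3e-3), 0.3), rlnorm(1500, log(5e-4), 0.3))
  s <- splitSubgroups(summaries, pooled, nBoot = 2000, seed = 2)
  expect_false(attr(s, "unimodal"))
  expect_equal(s$subgroup, rep(c("A_broad", "B_narrow"), c(nBroad, nNarrow)))

  unipooled <- rlnorm(2000, log(1e-3), 0.3)
  s2 <- splitSubgroups(summaries, unipooled, nBoot = 2000, seed = 2)
  expect_true(attr(s2, "unimodal"))
  expect_true(all(s2$subgroup == "none"))

  expect_error(splitSubgroups(summaries[1:2, ], pooled), "4 participants")
})

test_that("convergence is the first block from which subgroup bands overlap", {
  same <- data.frame(block = rep(1:4, each = 4),
                     subgroup = rep(c("A", "A", "B", "B"), 4),
                     variance = rep(c(1, 2, 1, 2), 4))
  expect_equal(convergenceSummary(same)$convergenceBlock, 1)

  ## planted convergence at block 6 of 8
  set.seed(76)
  rows <- do.call(rbind, lapply(1:8, function(b) {
    gapA <- if (b < 6) 10 else 1
    data.frame(block = b,
               subgroup = rep(c("A", "B"), each = 6),
               variance = c(runif(6, gapA, gapA + 0.5), runif(6, 1, 1.5)))
  }))
  cs <- convergenceSummary(rows)
  expect_true(abs(cs$convergenceBlock - 6) <= 1)

  never <- data.frame(block = rep(1:3, each = 2),
                      subgroup = rep(c("A", "B"), 3),
                      variance = rep(c(10, 1), 3))
  expect_true(is.na(convergenceSummary(never)$convergenceBlock))
})

test_that("the group test battery reports raw and BH-adjusted p-values", {
  set.seed(77)
  pooled <- list(mixed = c(rnorm(300, 0, .2), rnorm(300, 2, .2)),
                 correlated = rnorm(300, 1, .3),
                 random = rnorm(300, 1, .3))
  tests <- groupTests(pooled,
                      etBySubgroup = list(A_broad = rnorm(10, 0.9, 0.2),
                                          B_narrow = rnorm(13, 1.5, 0.2)),
                      nBoot = 500, seed = 3)
  expect_true(all(c("test", "statistic", "p", "pAdjusted") %in% names(tests)))
  expect_equal(nrow(tests), 3 + 3 + 1)   # 3 dips, 3 pairwise KS, 1 ranksum
  expect_true(all(tests$pAdjusted >= tests$p - 1e-12))
  expect_lt(tests$p[tests$test == "dip:mixed"], 0.01)
})
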