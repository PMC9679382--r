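randomHist <- function(n = 200, bins = 20) {
  windowHistogram(rbeta(n, runif(1, 0.5, 4), runif(1, 0.5, 4)), bins = bins)
}

test_that("window histograms are mass-normalized on fixed edges", {
  set.seed(61)
  h <- windowHistogram(runif(500))
  expect_equal(sum(h$mass), 1, tolerance = 1e-12)
  expect_length(h$mass, 20)
  expect_true(all(diff(h$edges) > 0))
  expect_error(windowHistogram(c(0.5, 1.2)), "support")
})

test_that("closed-form EMD equals transport oracles and is a metric", {
  set.seed(62)
  h <- windowHistogram(rbeta(300, 2, 5))
  expect_equal(emd(h, h), 0)

  ## unit point masses: translation distance
  mk <- function(center) {
    edges <- c(0.1, 0.3, 0.4, 0.6)
    list(mass = as.numeric(c(0.2, 0.35, 0.5) == center),
         edges = edges, centers = c(0.2, 0.35, 0.5), n = 1)
  }
  expect_equal(emd(mk(0.2), mk(0.5)), 0.3)

  for (i in 1:50) {
    h1 <- randomHist(); h2 <- randomHist()
    expect_equal(emd(h1, h2), transportEmdOracle(h1, h2), tolerance = 1e-10)
  }
  ## full transportation LP on a few coarse pairs
  for (i in 1:5) {
    h1 <- randomHist(bins = 8); h2 <- randomHist(bins = 8)
    expect_equal(emd(h1, h2), lpEmdOracle(h1, h2), tolerance = 1e-8)
  }
  ## metric axioms on random triples
  for (i in 1:30) {
    h1 <- randomHist(); h2 <- randomHist(); h3 <- randomHist()
    d12 <- emd(h1, h2); d13 <- emd(h1, h3); d23 <- emd(h2, h3)
    expect_gte(d12, 0)
    expect_equal(d12, emd(h2, h1))
    expect_lte(d13, d12 + d23 + 1e-12)
  }
  expect_error(emd(randomHist(), randomHist(bins = 10)), "edges")
})

test_that("EMD scales linearly with the support", {
  set.seed(63)
  v1 <- rbeta(300, 2, 3) * 0.5
  v2 <- rbeta(300, 4, 2) * 0.5
  h1 <- windowHistogram(v1, range = c(0, 0.5))
  h2 <- windowHistogram(v2, range = c(0, 0.5))
  H1 <- windowHistogram(2 * v1, range = c(0, 1))
  H2 <- windowHistogram(2 * v2, range = c(0, 1))
  expect_equal(emd(H1, H2), 2 * emd(h1, h2), tolerance = 1e-12)
})

test_that("EMD series labels landings and never bridges gaps", {
  set.seed(64)
  hists <- replicate(6, randomHist(), simplify = FALSE)
  same <- replicate(4, hists[[1]], simplify = FALSE)
  es0 <- emdSeries(same)
  expect_equal(es0$emd, rep(0, 3))

  withGap <- list(hists[[1]], hists[[2]], NULL, hists[[4]], hists[[5]])
  es <- emdSeries(withGap, quadrants = c("LUQ", "RLQ", NA, "RLQ", "LUQ"))
  expect_equal(nrow(es), 2)            # 1->2 and 4->5 only
  expect_equal(unique(es$segment), c(1L, 2L))
  expect_equal(es$color, c("red", "blue"))
  expect_equal(es$direction, c("LUQ->RLQ", "RLQ->LUQ"))
})

test_that("a planted regime switch yields the largest EMD step at the switch", {
  set.seed(65)
  hits <- 0
  for (rep in 1:20) {
    hists <- c(
      lapply(1:6, function(i) windowHistogram(rbeta(200, 1.2, 6))),
      lapply(1:6, function(i) windowHistogram(rbeta(200, 8, 2))))
    es <- emdSeries(hists)
    hits <- hits + (abs(which.max(es$emd) - 6) <= 1)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("a stationary regime shows no EMD trend", {
  set.seed(66)
  hists <- lapply(1:40, function(i) windowHistogram(rbeta(300, 2, 4)))
  es <- emdSeries(hists)
  trend <- summary(lm(es$emd ~ es$from))$coefficients[2, 4]
  expect_gt(trend, 0.05)
})

test_that("EMD peak statistics expose amplitudes and inter-peak intervals", {
  expect_length(emdPeaks(seq(0, 1, length.out = 50))$peakIndices, 0)

  periodic <- rep(c(0, 1, 0.5, 0.2), 25)
  ep <- emdPeaks(periodic)
  expect_true(all(ep$intervals == 4))
  expect_true(ep$lowConfidence)

  set.seed(67)
  long <- abs(rnorm(3000, 0.2, 0.05))
  ep2 <- emdPeaks(long)
  expect_false(ep2$lowConfidence)
  expect_true(!is.null(ep2$amplitudeFit))
  expect_true(!is.null(ep2$intervalFit))
})

test_that("the second-level shape process recovers planted parameters", {
  cst <- globalShapeProcess(rep(5, 100))
  expect_true(cst$degenerate)

  set.seed(68)
  v <- rgamma(4000, shape = 7, scale = 0.4)
  g <- globalShapeProcess(v)
  expect_false(g$degenerate)
  expect_true(g$fit$shapeCI[1] <= 7 && 7 <= g$fit$shapeCI[2])
  expect_true(g$fit$scaleCI[1] <= 0.4 && 0.4 <= g$fit$scaleCI[2])
  expect_equal(g$fit$nsr, g$fit$scale)
})
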