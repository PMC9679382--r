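test_that("Gamma MLE recovers parameters with sane confidence intervals", {
  set.seed(51)
  x <- rgamma(5000, shape = 4, scale = 0.05)
  f <- fitGamma(x)
  expect_true(f$shapeCI[1] <= 4 && 4 <= f$shapeCI[2])
  expect_true(f$scaleCI[1] <= 0.05 && 0.05 <= f$scaleCI[2])
  expect_lt(f$shapeCI[1], f$shape)
  expect_gt(f$shapeCI[2], f$shape)
  expect_equal(f$mean, f$shape * f$scale)
  expect_equal(f$variance, f$shape * f$scale^2)
  ## cross-check the point estimates against an independent fitter
  ref <- fitdistrplus::fitdist(x, "gamma")
  expect_equal(f$shape, unname(ref$estimate["shape"]), tolerance = 1e-4)
  expect_equal(1 / f$scale, unname(ref$estimate["rate"]), tolerance = 1e-4)
  expect_error(fitGamma(c(-1, 1, 2)), "positive")
  expect_error(fitGamma(rep(2, 10)), "degenerate")
})

test_that("candidate-family selection attributes data to its own family", {
  set.seed(52)
  gens <- list(
    gamma = function(n) rgamma(n, shape = 3, scale = 0.1),
    lognormal = function(n) rlnorm(n, -1.5, 0.6),
    normal = function(n) rnorm(n, 0.5, 0.05),
    weibull = function(n) rweibull(n, shape = 1.6, scale = 0.4))
  for (fam in names(gens)) {
    hits <- vapply(1:10, function(i)
      fitCandidates(gens[[fam]](5000))$family == fam, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})

test_that("exponential draws are reported through the Gamma fit at shape one", {
  set.seed(53)
  fc <- fitCandidates(rexp(5000, rate = 10))
  ## exponential is nested in the Gamma family: the winner by raw
  ## log-likelihood is Gamma, with shape indistinguishable from 1
  expect_equal(fc$family, "gamma")
  expect_gte(fc$logLik["gamma"], fc$logLik["exponential"])
  expect_true(fc$gamma$shapeCI[1] <= 1 && 1 <= fc$gamma$shapeCI[2])
  expect_error(fitCandidates(rexp(50)), "insufficient")
})

test_that("the Gamma density and moments follow the closed forms", {
  expect_equal(gammaPdf(1, 2, 1), exp(-1))
  expect_equal(gammaPdf(1e-12, 1, 1), 1, tolerance = 1e-9)
  for (p in list(c(0.7, 2), c(3, 0.2), c(12, 1.5))) {
    expect_equal(
      integrate(gammaPdf, 0, Inf, shape = p[1], scale = p[2])$value, 1,
      tolerance = 1e-6)
  }
  m <- gammaMoments(4, 2)
  expect_equal(m, list(mean = 8, variance = 16, skewness = 1,
                       kurtosis = 1.5))
  expect_equal(gammaMoments(1, 5)$skewness, 2)
  set.seed(54)
  x <- rgamma(2e5, shape = 6, scale = 0.3)
  mm <- gammaMoments(6, 0.3)
  expect_equal(mean(x), mm$mean, tolerance = 0.01)
  expect_equal(var(x), mm$variance, tolerance = 0.02)
  expect_error(gammaPdf(1, -1, 1), "positive")
})

test_that("NSR is the scale parameter and SNR its reciprocal, exactly", {
  expect_equal(nsr(3, 0.5), 0.5)
  expect_equal(snr(3, 0.5), 2)
  set.seed(55)
  for (i in 1:20) {
    a <- runif(1, 0.2, 50); b <- runif(1, 0.001, 5)
    expect_equal(nsr(a, b) * snr(a, b), 1, tolerance = 1e-12)
    m <- gammaMoments(a, b)
    expect_equal(nsr(a, b), m$variance / m$mean)
  }
})

test_that("quadrants split on the median log parameters with the tie rule", {
  q <- quadrantSplit(c(1, 1, 10, 10), c(0.1, 10, 0.1, 10))
  expect_setequal(as.character(q$quadrant), c("LLQ", "LUQ", "RLQ", "RUQ"))

  qq <- quadrantSplit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(as.character(qq$quadrant[2]), "LLQ")  # on both medians

  set.seed(56)
  shape <- c(rlnorm(20, 2.5, 0.1), rlnorm(20, 0, 0.1))
  scale <- c(rlnorm(20, -3, 0.1), rlnorm(20, 0, 0.1))
  q2 <- quadrantSplit(shape, scale)
  expect_true(all(q2$quadrant[1:20] == "RLQ"))
  expect_true(all(q2$quadrant[21:40] == "LUQ"))

  ## each median line splits the fits into halves differing by <= 1
  for (i in 1:10) {
    a <- rlnorm(15, 0, 1); b <- rlnorm(15, 0, 1)
    q3 <- quadrantSplit(a, b)
    right <- q3$quadrant %in% c("RUQ", "RLQ")
    upper <- q3$quadrant %in% c("RUQ", "LUQ")
    expect_lte(abs(sum(right) - sum(!right)), 1)
    expect_lte(abs(sum(upper) - sum(!upper)), 1)
  }
  expect_error(quadrantSplit(1, 1), "2 fits")
})

test_that("block summaries report shape-distribution SNR and flag gaps", {
  fits <- data.frame(block = rep(1:2, each = 4),
                     shape = c(rep(3, 4), c(2, 4, 2, 4)),
                     scale = 0.1)
  s <- suppressWarnings(blockSummary(fits))
  expect_true(is.infinite(s$snrShape[1]) && s$degenerate[1])
  expect_equal(s$meanShape[2], 3)

  twoBlocks <- data.frame(block = rep(1:2, each = 200),
                          shape = c(rnorm(200, 10, 1), rnorm(200, 10, 2)),
                          scale = 0.1)
  s2 <- blockSummary(twoBlocks)
  expect_equal(s2$snrShape[1] / s2$snrShape[2],
               var(twoBlocks$shape[201:400]) / var(twoBlocks$shape[1:200]) *
                 s2$meanShape[1] / s2$meanShape[2],
               tolerance = 1e-10)
})

test_that("windowed fitting skips sparse windows and flags them", {
  set.seed(57)
  times <- sort(sample(1:5000, 400))
  train <- new("MMSTrain", times = times,
               values = rbeta(400, 2, 2), nSamples = 5000L,
               sourceMean = 1, meanMethod = "gamma-mle")
  plan <- planWindows(5000, 256, 5, 0.5)
  wf <- windowedGammaFits(train, plan, minPeaks = 100)
  expect_true(any(wf$accepted))
  expect_true(all(is.na(wf$shape[!wf$accepted])))
  expect_true(all(wf$n[wf$accepted] >= 100))
})
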