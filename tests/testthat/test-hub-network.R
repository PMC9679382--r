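rate <- 256

test_that("bandpass keeps the passband and rejects out-of-band tones", {
  t <- seq(0, 4, by = 1 / rate)
  s5 <- sin(2 * pi * 5 * t)
  s50 <- sin(2 * pi * 50 * t)
  expect_lt(sd(bandpassRecording(s5, rate = rate)) / sd(s5), 0.05)
  expect_lt(abs(sd(bandpassRecording(s50, rate = rate)) / sd(s50) - 1), 0.05)
  expect_error(bandpassRecording(s5, 100, 13, rate = rate), "lowHz")
  expect_error(bandpassRecording(s5, 13, 130, rate = rate), "Nyquist")
})

test_that("self-coherence is one and pure delays show the analytic phase", {
  set.seed(31)
  x <- as.numeric(bandpassRecording(rnorm(rate * 6), rate = rate))
  self <- coherenceEdge(x, x, rate)
  expect_equal(self$coherence, 1, tolerance = 1e-10)

  t <- seq(0, 6, by = 1 / rate)
  tone <- sin(2 * pi * 20 * t) + 0.05 * rnorm(length(t))
  delay <- as.integer(0.0125 * rate)            # 12.5 ms = quarter period
  e <- coherenceEdge(tone[1:(length(t) - delay)],
                     tone[(1 + delay):length(t)], rate)
  expect_equal(e$freqHz, 20, tolerance = 1)
  expect_equal(abs(e$phase), pi / 2, tolerance = 0.15)
})

test_that("independent noise stays below the Monte-Carlo null quantile", {
  ## null distribution of the max band coherence for independent pairs
  set.seed(32)
  nullMax <- replicate(200, {
    a <- rnorm(rate * 5); b <- rnorm(rate * 5)
    coherenceEdge(a, b, rate)$coherence
  })
  q99 <- quantile(nullMax, 0.99)
  set.seed(33)
  hits <- replicate(20, coherenceEdge(rnorm(rate * 5), rnorm(rate * 5),
                                      rate)$coherence < q99)
  expect_gte(mean(hits), 0.9)
})

test_that("adjacency is symmetric, bounded and matches pairwise edges", {
  set.seed(34)
  X <- matrix(rnorm(rate * 5 * 4), ncol = 4)
  X[, 2] <- 0.6 * X[, 1] + 0.8 * X[, 2]
  A <- adjacencyMatrix(X, rate)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_true(all(A >= 0 & A <= 1))
  for (i in 1:3) for (j in (i + 1):4) {
    e <- coherenceEdge(X[, i], X[, j], rate)
    expect_equal(A[i, j], e$coherence, tolerance = 1e-10)
  }
  same <- matrix(rep(X[, 1], 3), ncol = 3)
  Asame <- adjacencyMatrix(same, rate)
  expect_true(all(Asame[upper.tri(Asame)] > 0.999))
  expect_error(adjacencyMatrix(X[, 1:2], rate), "3 channels")
  expect_error(adjacencyMatrix(cbind(X[, 1], 0 * X[, 2], X[, 3]), rate),
               "constant")
})

test_that("clustering coefficients match the exhaustive-triple oracle", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(clusteringCoefficients(tri)), rep(1, 3))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(unname(clusteringCoefficients(star)[1]), 0)

  set.seed(35)
  for (n in 3:8) {
    for (rep in 1:15) {
      A <- matrix(0, n, n)
      up <- upper.tri(A)
      w <- runif(sum(up))
      w[runif(length(w)) < 0.3] <- 0          # sparse graphs too
      A[up] <- w
      A <- A + t(A)
      expect_equal(unname(clusteringCoefficients(A)), clusteringOracle(A),
                   tolerance = 1e-12)
    }
  }
  expect_error(clusteringCoefficients(matrix(c(0, -1, -1, 0), 2)),
               "nonnegative")
})

test_that("hub selection recovers a planted hub and breaks ties first-wins", {
  set.seed(36)
  n <- rate * 5
  hub <- as.numeric(bandpassRecording(rnorm(n), rate = rate))
  spoke <- function() 0.55 * hub + 0.84 * rnorm(n)
  X <- cbind(hub, spoke(), spoke(), spoke(), rnorm(n))
  sel <- selectHub(X, rate, labels = c("H", "s1", "s2", "s3", "noise"))
  expect_equal(sel$hub, "H")

  Xtie <- cbind(hub, hub, 0.5 * hub + rnorm(n))
  tie <- selectHub(Xtie, rate, labels = c("first", "second", "other"))
  expect_equal(tie$hub, "first")

  expect_error(selectHub(X[, 1:2], rate), "3 channels")
  expect_error(selectHub(matrix(0, n, 3), rate), "zero")
})

test_that("hub series concatenates stride segments with a label track", {
  set.seed(37)
  spec <- participantSpec("h", "mixed", "B_narrow", blockS = 20,
                          nChannels = 4, seed = 7)
  synth <- generateParticipant(spec)
  rec <- recording(synth)
  oneBlock <- EEGRecording(samples(rec)[, 1:(20 * rate)], rate,
                           channelLabels(rec))
  plan <- planWindows(20 * rate, rate, 5, 0.5)
  hs <- hubSeries(oneBlock, plan)
  expect_equal(length(hs$series), 20 * rate)
  expect_gte(mean(hs$assignments$hub == groundTruth(synth)$hub), 0.95)
  hubRow <- groundTruth(synth)$hubIndex
  if (all(hs$assignments$hub == groundTruth(synth)$hub))
    expect_equal(hs$series, samples(oneBlock)[hubRow, ])

  empty <- hubSeries(oneBlock, planWindows(20 * rate, rate, 5, 0.5)[0, ])
  expect_length(empty$series, 0)
})

test_that("a mid-recording hub hand-off shows up in the label track", {
  set.seed(38)
  n <- rate * 20
  a <- as.numeric(bandpassRecording(rnorm(n), rate = rate))
  b <- as.numeric(bandpassRecording(rnorm(n), rate = rate))
  half <- n / 2
  ## first half: channel 1 is the hub; second half: channel 2
  ch1 <- c(a[1:half], 0.3 * b[(half + 1):n] + 0.5 * rnorm(half))
  ch2 <- c(0.3 * a[1:half] + 0.5 * rnorm(half), b[(half + 1):n])
  ch3 <- 0.55 * c(a[1:half], b[(half + 1):n]) + 0.6 * rnorm(n)
  ch4 <- 0.55 * c(a[1:half], b[(half + 1):n]) + 0.6 * rnorm(n)
  rec <- EEGRecording(rbind(ch1, ch2, ch3, ch4), rate,
                      c("early", "late", "s1", "s2"))
  plan <- planWindows(n, rate, 5, 0.5)
  hs <- hubSeries(rec, plan)
  firstHalf <- hs$assignments$hub[hs$assignments$end <= half]
  secondHalf <- hs$assignments$hub[hs$assignments$start >= half]
  expect_equal(names(which.max(table(firstHalf))), "early")
  expect_equal(names(which.max(table(secondHalf))), "late")
})
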