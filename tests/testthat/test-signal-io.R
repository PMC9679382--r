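test_that("window plans stride correctly and drop trailing partials", {
  plan <- planWindows(2560, 256, 5, 0.5)
  expect_equal(plan$start, c(0L, 640L, 1280L))
  expect_equal(plan$end, c(1280L, 1920L, 2560L))
  expect_equal(attr(plan, "stride"), 640L)

  tiling <- planWindows(1000, 100, 1, 0)
  expect_equal(tiling$start, seq(0L, 900L, by = 100L))
  expect_true(all(diff(tiling$start) == attr(tiling, "windowSamples")))

  expect_error(planWindows(100, 256, 5, 0.5), "shorter")
  expect_error(planWindows(2560, 256, 5, 1), "overlap")
  expect_error(planWindows(2560, 256, 5, -0.1), "overlap")
})

test_that("window count matches brute enumeration across random geometries", {
  set.seed(11)
  for (i in 1:40) {
    rate <- sample(c(100, 128, 256, 500), 1)
    windowS <- runif(1, 0.5, 6)
    overlap <- runif(1, 0, 0.9)
    w <- as.integer(round(windowS * rate))
    stride <- as.integer(round((1 - overlap) * w))
    if (w < 2 || stride < 1) next
    n <- sample(w:(20 * w), 1)
    plan <- planWindows(n, rate, windowS, overlap)
    expect_equal(nrow(plan), windowCountOracle(n, w, stride))
    expect_equal(nrow(plan), floor((n - w) / stride) + 1)
    expect_true(all(plan$end <= n))
    if (nrow(plan) > 1)
      expect_true(all(plan$end[-nrow(plan)] - plan$start[-1] ==
                        w - stride))
  }
})

test_that("recordings round-trip through EDF, BDF and CSV", {
  set.seed(21)
  rec <- EEGRecording(matrix(rnorm(4 * 512, sd = 30), 4), 256,
                      c("Fp1", "Fp2", "Cz", "Oz"))
  for (fmt in c("edf", "bdf", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeRecording(rec, path)
    back <- readRecording(path)
    rng <- diff(range(samples(rec)))
    quantum <- switch(fmt, edf = rng / 2^15, bdf = rng / 2^23, csv = 1e-10)
    expect_lt(max(abs(samples(back) - samples(rec))), 2 * quantum)
    expect_identical(channelLabels(back), channelLabels(rec))
    expect_equal(samplingRate(back), 256)
  }
})

test_that("BDF files preserve many channel labels in file order", {
  set.seed(22)
  labels <- sprintf("EEG%02d", 1:32)
  rec <- EEGRecording(matrix(rnorm(32 * 256), 32), 256, labels)
  path <- withr::local_tempfile(fileext = ".bdf")
  writeRecording(rec, path)
  expect_identical(channelLabels(readRecording(path)), labels)
})

test_that("malformed inputs give format errors", {
  noHeader <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), noHeader)
  expect_error(readRecording(noHeader), "rate_hz")
  expect_error(readRecording(withr::local_tempfile(fileext = ".csv")),
               "no such file")
  bad <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw(100), bad)
  expect_error(readRecording(bad))
})

test_that("recording container validates its invariants", {
  expect_error(EEGRecording(matrix(0, 2, 10), -1), "samplingRate")
  expect_error(EEGRecording(matrix(0, 2, 10), 256, c("a", "a")), "unique")
  expect_error(
    EEGRecording(matrix(0, 2, 10), 256,
                 annotations = data.frame(block = 1, start = 0, end = 20)),
    "annotation")
  rec <- EEGRecording(matrix(0, 2, 10), 256)
  expect_equal(nChannels(rec), 2)
  expect_equal(nSamples(rec), 10)
})

test_that("window plans export as 3-column BED-like TSV", {
  plan <- planWindows(2560, 256, 5, 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeWindowPlan(plan, path)
  tsv <- read.table(path, sep = "\t")
  expect_equal(nrow(tsv), 3)
  expect_equal(tsv$V2, plan$start)
  expect_equal(tsv$V3, plan$end)
})
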