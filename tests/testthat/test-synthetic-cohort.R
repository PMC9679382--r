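test_that("regime schedules honor their defining constraints", {
  ex <- regimeSchedule("exploratory")
  expect_equal(nrow(ex), 8)
  expect_lte(ex$shape[1], 1.5)
  expect_gte(ex$shape[8], 10)
  expect_true(all(ex$shape > 0 & ex$scale > 0))
  ## log-linear drift: equal ratios between consecutive blocks
  expect_equal(diff(log(ex$shape)), rep(diff(log(ex$shape))[1], 7))

  ec <- regimeSchedule("error_correction")
  expect_equal(length(unique(ec$scale)), 1)
  expect_lte(ec$scale[1], 0.05)
  expect_gte(min(ec$shape), 10)

  expect_error(regimeSchedule("exploratory", shapeStart = -1), "positive")
})

test_that("participant specs validate their invariants", {
  expect_error(participantSpec("p", "mixed", "A_broad", blockS = 0),
               "invalid spec")
  expect_error(participantSpec("p", "mixed", "A_broad", rate = 100),
               "invalid spec")
  expect_error(participantSpec("p", "correlated", "A_broad"), "mixed")
  expect_error(participantSpec("p", "mixed", "none"), "subgroup")
  s <- participantSpec("p", "random", blockS = 10, nChannels = 4)
  expect_s3_class(s$schedule, "data.frame")
  expect_equal(s$schedule$regime[1], "random_stable")
})

test_that("generation is deterministic given the seed", {
  spec <- participantSpec("d", "mixed", "B_narrow", blockS = 6,
                          nChannels = 4, seed = 99)
  a <- generateParticipant(spec)
  b <- generateParticipant(spec)
  expect_identical(samples(a), samples(b))
  expect_identical(groundTruth(a)$peakAmps, groundTruth(b)$peakAmps)
})

test_that("ground-truth amplitudes follow the planted per-block Gamma", {
  spec <- participantSpec("k", "mixed", "A_broad", blockS = 80,
                          nChannels = 4, seed = 123)
  synth <- generateParticipant(spec)
  gt <- groundTruth(synth)
  pvals <- vapply(seq_len(nrow(gt$schedule)), function(b) {
    amps <- gt$peakAmps[[b]]
    suppressWarnings(ks.test(amps, "pgamma", shape = gt$schedule$shape[b],
                             scale = gt$schedule$scale[b])$p.value)
  }, numeric(1))
  expect_true(all(vapply(gt$peakAmps, length, integer(1)) >= 500))
  expect_true(all(pvals > 0.01))
})

test_that("cohort generation writes consistent tables and is reproducible", {
  specs <- c(list(participantSpec("a1", "mixed", "A_broad", blockS = 4,
                                  nChannels = 4)),
             list(participantSpec("b1", "mixed", "B_narrow", blockS = 4,
                                  nChannels = 4)))
  dir <- withr::local_tempdir()
  g1 <- generateCohort(specs, masterSeed = 7, dir = dir, format = "csv")
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_true(file.exists(file.path(dir, "a1.csv")))
  beh <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(beh$participant, c("a1", "b1"))
  ## realized ET score equals hit/fa
  et <- beh$hit_rate / beh$fa_rate
  expect_true(all(et > 0))

  g2 <- generateCohort(specs, masterSeed = 7)
  expect_identical(samples(g1$recordings[[1]]), samples(g2$recordings[[1]]))
  expect_identical(g1$behavior$hit_rate, g2$behavior$hit_rate)

  expect_error(generateCohort(list(), 1), "empty")
  expect_error(generateCohort(c(specs, specs[1]), 1), "duplicate")
})

test_that("the default cohort matches the study composition", {
  specs <- defaultCohortSpec(blockS = 4, nChannels = 4)
  expect_length(specs, 70)
  groups <- vapply(specs, `[[`, "", "group")
  subgroups <- vapply(specs, `[[`, "", "subgroup")
  expect_equal(sum(groups == "mixed"), 23)
  expect_equal(sum(groups == "correlated"), 23)
  expect_equal(sum(groups == "random"), 24)
  expect_equal(sum(subgroups == "A_broad"), 10)
  expect_equal(sum(subgroups == "B_narrow"), 13)
})

test_that("ET scores are drawn per subgroup with positive truncation", {
  specs <- defaultCohortSpec(blockS = 4, nChannels = 4)
  g <- generateCohort(specs, masterSeed = 11, generate = FALSE)
  beh <- g$behavior
  et <- ifelse(beh$fa_rate > 0, beh$hit_rate / beh$fa_rate, NA)
  expect_true(all(is.na(et[beh$group == "random"])))
  expect_true(all(et[beh$group != "random"] > 0, na.rm = TRUE))
  ## broad learners score lower on the explicit memory test than narrow
  expect_lt(mean(et[beh$subgroup == "A_broad"]),
            mean(et[beh$subgroup == "B_narrow"]))
})
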