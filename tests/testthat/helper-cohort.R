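## Shared scaled-down synthetic cohorts for the cohort-level tests: built
## once per test run and cached.  23 mixed participants (10 broad
## exploratory + 13 narrow error-correction) and 23 correlated-regime
## participants, 8 blocks of 45 s, 6 channels - the full pipeline at desk
## scale.

.fixtures <- new.env(parent = emptyenv())

scaledCohortSpecs <- function(blockS = 45, nChannels = 6) {
  mk <- function(prefix, k, group, subgroup) {
    lapply(seq_len(k), function(i)
      participantSpec(sprintf("%s%02d", prefix, i), group = group,
                      subgroup = subgroup, blockS = blockS,
                      nChannels = nChannels))
  }
  list(mixed = c(mk("MA", 10, "mixed", "A_broad"),
                 mk("MB", 13, "mixed", "B_narrow")),
       correlated = mk("C", 23, "correlated", "none"))
}

analyzedScaledCohorts <- function() {
  if (!is.null(.fixtures$cohorts)) return(.fixtures$cohorts)
  specs <- scaledCohortSpecs()
  gm <- generateCohort(specs$mixed, masterSeed = 20221108, generate = FALSE)
  gcorr <- generateCohort(specs$correlated, masterSeed = 20221109,
                          generate = FALSE)
  mixed <- analyzeCohort(gm$specs, behavior = gm$behavior)
  correlated <- analyzeCohort(gcorr$specs, behavior = gcorr$behavior)
  .fixtures$cohorts <- list(mixed = mixed, correlated = correlated)
  .fixtures$cohorts
}

pooledVariances <- function(result) {
  acc <- result$fits[result$fits$accepted, ]
  acc$variance
}
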