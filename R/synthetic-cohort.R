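## Synthetic cohort generator.  Produces clean multichannel recordings whose
## hub-channel peak statistics follow planted per-block Gamma regimes, plus
## behavioral tables, so the whole pipeline is testable without any data
## download.
##
## Carrier model: on each block, event times follow a homogeneous renewal
## process (shifted-exponential gaps, default mean 40 ms); each event adds a
## smooth bump whose amplitude is an i.i.d. draw from the block's scheduled
## Gamma(shape, scale); a band-limited noise floor at a fixed fraction of
## the block's mean amplitude supplies the background rhythm.  Non-hub
## channels are attenuated, decorrelated copies of the hub plus independent
## band-limited noise, so hub selection has a planted answer.

.regimes <- c("exploratory", "error_correction", "random_stable",
              "correlated_stable")

#' Planted per-block Gamma regime schedule
#'
#' Builds the per-block target Gamma shape and scale for the peak-amplitude
#' process of one participant. Exploratory schedules drift log-linearly
#' from a near-exponential shape (1) to the Gaussian-range floor (10);
#' error-correction schedules keep a high shape and a constant low scale;
#' the stable regimes hold a constant mid/high shape. Scales are set so the
#' mean amplitude a*b stays at 1 (unit-scaled amplitudes), except for
#' error-correction where the constant low scale is the planted signature.
#'
#' @param regime one of \code{"exploratory"}, \code{"error_correction"},
#'   \code{"random_stable"}, \code{"correlated_stable"}.
#' @param nBlocks number of blocks (default 8).
#' @param shapeStart,shapeEnd endpoints of the shape trajectory (defaults
#'   per regime).
#' @param scale constant scale for the constant-scale regimes.
#' @return data.frame \code{block}, \code{shape}, \code{scale},
#'   \code{regime}.
#' @export
regimeSchedule <- function(regime = .regimes, nBlocks = 8,
                           shapeStart = NULL, shapeEnd = NULL, scale = NULL) {
  regime <- match.arg(regime)
  defaults <- switch(regime,
    exploratory = list(shapeStart = 1, shapeEnd = 10, scale = NA),
    error_correction = list(shapeStart = 10, shapeEnd = 10, scale = 0.01),
    random_stable = list(shapeStart = 8, shapeEnd = 8, scale = NA),
    correlated_stable = list(shapeStart = 8, shapeEnd = 8, scale = NA))
  if (is.null(shapeStart)) shapeStart <- defaults$shapeStart
  if (is.null(shapeEnd)) shapeEnd <- defaults$shapeEnd
  if (is.null(scale)) scale <- defaults$scale
  if (shapeStart <= 0 || shapeEnd <= 0) stop("shapes must be positive")
  shape <- exp(seq(log(shapeStart), log(shapeEnd), length.out = nBlocks))
  sc <- if (is.na(scale)) 1 / shape else rep(scale, nBlocks)
  if (any(sc <= 0)) stop("scales must be positive")
  data.frame(block = seq_len(nBlocks), shape = shape, scale = sc,
             regime = regime)
}

#' Participant specification
#'
#' @param id participant id (unique string).
#' @param group one of \code{"mixed"}, \code{"correlated"}, \code{"random"}.
#' @param subgroup \code{"A_broad"}, \code{"B_narrow"} or \code{"none"};
#'   only the mixed group carries subgroups.
#' @param schedule a [regimeSchedule()] (defaults per group/subgroup:
#'   A_broad = exploratory, B_narrow = error_correction, correlated/random =
#'   their stable regimes).
#' @param etMean,etSd ET-score distribution (defaults: A_broad 0.94/0.4,
#'   B_narrow 1.52/0.75, correlated 1.37/0.9, random NA).
#' @param blockS seconds per block (default 300).
#' @param nChannels number of channels (default 32).
#' @param rate sampling rate in Hz (default 256).
#' @param seed participant RNG seed.
#' @param meanInterPeakS mean event gap in seconds (default 0.1; together
#'   with the 40 Hz pinning rhythm a 5-s window holds well over 100
#'   deviation peaks).
#' @param shapeJitterSd sd of the per-participant log-normal multiplier on
#'   the scheduled shapes (default 0.08 for the mixed group, 0.25 for the
#'   stable groups).
#' @return a \code{participantSpec} list.
#' @export
participantSpec <- function(id, group = c("mixed", "correlated", "random"),
                            subgroup = c("none", "A_broad", "B_narrow"),
                            schedule = NULL, etMean = NULL, etSd = NULL,
                            blockS = 300, nChannels = 32, rate = 256,
                            seed = 1L, meanInterPeakS = 0.1,
                            shapeJitterSd = NULL) {
  group <- match.arg(group)
  subgroup <- match.arg(subgroup)
  if (subgroup != "none" && group != "mixed")
    stop("subgroups are defined only within the mixed group")
  if (group == "mixed" && subgroup == "none")
    stop("mixed-group participants need a subgroup")
  if (blockS <= 0) stop("invalid spec: block duration must be positive")
  if (nChannels < 3) stop("invalid spec: need at least 3 channels")
  if (rate < 2 * 100)
    stop("invalid spec: rate below twice the upper analysis band edge")
  if (is.null(schedule)) {
    schedule <- switch(paste(group, subgroup, sep = "."),
      mixed.A_broad = regimeSchedule("exploratory"),
      mixed.B_narrow = regimeSchedule("error_correction"),
      correlated.none = regimeSchedule("correlated_stable"),
      random.none = regimeSchedule("random_stable"))
  }
  if (any(schedule$shape <= 0) || any(schedule$scale <= 0))
    stop("invalid spec: schedule parameters must be positive")
  et <- switch(paste(group, subgroup, sep = "."),
    mixed.A_broad = c(0.94, 0.4),
    mixed.B_narrow = c(1.52, 0.75),
    correlated.none = c(1.37, 0.9),
    random.none = c(NA_real_, NA_real_))
  if (is.null(etMean)) etMean <- et[1]
  if (is.null(etSd)) etSd <- et[2]
  if (is.null(shapeJitterSd))
    shapeJitterSd <- if (group == "mixed") 0.08 else 0.25
  ## a 5-s window must hold >= 100 deviation peaks (events + pinning rhythm)
  if (5 * (1 / meanInterPeakS + 40) < 100)
    stop("invalid spec: event gap leaves a 5-s window under 100 peaks")
  structure(list(id = as.character(id), group = group, subgroup = subgroup,
                 schedule = schedule, etMean = etMean, etSd = etSd,
                 blockS = blockS, nChannels = nChannels, rate = rate,
                 seed = as.integer(seed), meanInterPeakS = meanInterPeakS,
                 shapeJitterSd = shapeJitterSd),
            class = "participantSpec")
}

## band-limited Gaussian noise via Fourier masking, unit sd
.bandNoise <- function(n, rate, low, high) {
  z <- rnorm(n)
  f <- fft(z)
  freq <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) * rate / n
  mask <- abs(freq) >= low & abs(freq) <= high
  f[!mask] <- 0
  y <- Re(fft(f, inverse = TRUE)) / n
  s <- sd(y)
  if (s == 0) y else y / s
}

## One block of the hub channel.  The carrier is a smooth positive rhythm:
## a baseline at the scheduled mean amplitude carrying a fast small "pinning"
## oscillation (keeps the empirically estimated mean amplitude anchored just
## above the baseline and supplies a dense reference population of
## deviation peaks), plus sparse renewal-time event bumps whose crest
## amplitudes are the planted i.i.d. Gamma(shape, scale) draws.  Event MMS
## values then grade with the crest-to-pedestal ratio, so the planted
## amplitude dispersion (CV = 1/sqrt(shape)) maps monotonically onto the
## windowed MMS Gamma variance - broad planted regimes come out broad.
.hubBlock <- function(nSamples, rate, shape, scale, meanInterPeakS,
                      pinFrac = 0.1, pinHz = 40, bumpS = 0.04) {
  minGap <- meanInterPeakS / 2
  nEvents <- ceiling(nSamples / rate / minGap) + 8
  gaps <- minGap + rexp(nEvents, rate = 1 / (meanInterPeakS - minGap))
  times <- cumsum(gaps)
  times <- times[times < (nSamples - 30) / rate]
  idx <- pmax(15L, as.integer(round(times * rate)))
  idx <- idx[!duplicated(idx)]
  amps <- rgamma(length(idx), shape = shape, scale = scale)
  meanAmp <- shape * scale
  half <- max(3L, as.integer(round(bumpS * rate / 2)))
  prof <- cos(seq(-half, half) * pi / (2 * half))^2   # smooth unit bump
  phase <- runif(1, 0, 2 * pi)
  tt <- seq_len(nSamples)
  pin <- pinFrac * meanAmp * sin(2 * pi * pinHz * tt / rate + phase)
  ev <- numeric(nSamples)
  for (k in seq_along(idx)) {
    span <- (idx[k] - half):(idx[k] + half)
    ok <- span >= 1 & span <= nSamples
    ev[span[ok]] <- ev[span[ok]] + amps[k] * prof[ok]
  }
  list(signal = meanAmp + pin + ev, events = ev,
       peakTimes = idx, peakAmps = amps)
}

#' Generate one synthetic participant recording
#'
#' Builds the full multichannel recording for one participant: the hub
#' channel carries the planted renewal-event/Gamma-amplitude process block
#' by block; every other channel is an attenuated copy of the hub plus
#' independent band-limited noise. Ground truth (event times, amplitudes,
#' schedule, hub label) is recorded for recovery tests.
#'
#' @param spec a [participantSpec()].
#' @param pinFrac amplitude of the fast pinning rhythm as a fraction of the
#'   block mean amplitude (default 0.1).
#' @param bumpS event bump duration in seconds (default 0.04).
#' @param hubChannel planted hub channel index (default: seeded draw).
#' @return A [SyntheticRecording-class].
#' @export
generateParticipant <- function(spec, pinFrac = 0.1, bumpS = 0.04,
                                hubChannel = NULL) {
  stopifnot(inherits(spec, "participantSpec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  rate <- spec$rate
  nb <- nrow(spec$schedule)
  nBlockSamples <- as.integer(round(spec$blockS * rate))
  if (nBlockSamples < 2) stop("invalid spec: block too short")
  n <- nb * nBlockSamples
  if (is.null(hubChannel)) hubChannel <- sample.int(spec$nChannels, 1)
  ## one per-participant multiplicative jitter on the scheduled shapes:
  ## between-subject variability (larger for the stable regimes, which lack
  ## the common error-correction attractor of the mixed group)
  jit <- exp(rnorm(1, 0, spec$shapeJitterSd))
  shapes <- spec$schedule$shape * jit
  hub <- numeric(n)
  events <- numeric(n)
  peakTimes <- vector("list", nb)
  peakAmps <- vector("list", nb)
  for (b in seq_len(nb)) {
    blk <- .hubBlock(nBlockSamples, rate, shapes[b],
                     spec$schedule$scale[b], spec$meanInterPeakS,
                     pinFrac = pinFrac, bumpS = bumpS)
    off <- (b - 1L) * nBlockSamples
    hub[(off + 1):(off + nBlockSamples)] <- blk$signal
    events[(off + 1):(off + nBlockSamples)] <- blk$events
    peakTimes[[b]] <- blk$peakTimes + off
    peakAmps[[b]] <- blk$peakAmps
  }
  ## spokes share the hub's event component only (the pinning rhythm is the
  ## hub's own), plus independent band-limited noise: hub-spoke coherence
  ## peaks in the event band, spoke-spoke stays weaker, so the planted hub
  ## carries the maximal clustering coefficient
  X <- matrix(0, nrow = spec$nChannels, ncol = n)
  sdEv <- sd(events)
  for (ch in seq_len(spec$nChannels)) {
    if (ch == hubChannel) {
      X[ch, ] <- hub
    } else {
      g <- runif(1, 0.3, 0.55)
      X[ch, ] <- g * events +
        sqrt(1 - g^2) * sdEv * .bandNoise(n, rate, 13, 100)
    }
  }
  labels <- paste0("ch", seq_len(spec$nChannels))
  ann <- data.frame(block = seq_len(nb),
                    start = (seq_len(nb) - 1L) * nBlockSamples,
                    end = seq_len(nb) * nBlockSamples)
  rec <- EEGRecording(X, samplingRate = rate, channelLabels = labels,
                      annotations = ann)
  planted <- spec$schedule
  planted$shape <- shapes           # effective, jittered planted shapes
  new("SyntheticRecording", recording = rec,
      groundTruth = list(peakTimes = peakTimes, peakAmps = peakAmps,
                         schedule = planted, shapeJitter = jit,
                         hub = labels[hubChannel], hubIndex = hubChannel,
                         spec = spec))
}

## truncated-positive normal draw
.rtruncnorm <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    v <- rnorm(n, mean, sd)
    out <- c(out, v[v > 0])
  }
  out[seq_len(n)]
}

#' Default cohort specification
#'
#' The default synthetic cohort mirrors the study composition: 23 mixed
#' (10 A_broad exploratory + 13 B_narrow error-correction), 23 correlated
#' and 24 random participants.
#'
#' @param nBroad,nNarrow,nCorrelated,nRandom subgroup/group sizes.
#' @param blockS,nChannels,rate forwarded to [participantSpec()].
#' @return list of [participantSpec()] (seeds filled by [generateCohort()]).
#' @export
defaultCohortSpec <- function(nBroad = 10, nNarrow = 13, nCorrelated = 23,
                              nRandom = 24, blockS = 300, nChannels = 32,
                              rate = 256) {
  specs <- list()
  add <- function(prefix, k, group, subgroup) {
    lapply(seq_len(k), function(i)
      participantSpec(sprintf("%s%02d", prefix, i), group = group,
                      subgroup = subgroup, blockS = blockS,
                      nChannels = nChannels, rate = rate))
  }
  c(add("M-A", nBroad, "mixed", "A_broad"),
    add("M-B", nNarrow, "mixed", "B_narrow"),
    add("C", nCorrelated, "correlated", "none"),
    add("R", nRandom, "random", "none"))
}

#' Generate a synthetic cohort
#'
#' Draws per-participant seeds and ET scores from the master seed, generates
#' every recording, and (optionally) writes the cohort to disk: one EDF/BDF
#' or CSV recording per participant, a behavioral table \code{cohort.csv}
#' (participant, group, subgroup, hit_rate, fa_rate, seed) and
#' \code{ground_truth.json}. Deterministic given \code{masterSeed}.
#'
#' ET scores are drawn from the per-subgroup truncated-positive normal and
#' back-solved into a hit/false-alarm pair preserving the ratio:
#' fa = 0.5 and hit = ET/2 when ET <= 2, else hit = 1 and fa = 1/ET.
#'
#' @param specs list of [participantSpec()] (e.g. [defaultCohortSpec()]).
#' @param masterSeed integer master seed.
#' @param dir optional output directory (created if missing).
#' @param format recording format for \code{dir} output
#'   (\code{"edf"}, \code{"bdf"} or \code{"csv"}).
#' @param generate when FALSE, only seeds and the behavioral table are
#'   produced (specs annotated with seeds are returned).
#' @return list with \code{recordings} (list of
#'   [SyntheticRecording-class] or NULL), \code{behavior} (data.frame),
#'   \code{specs}.
#' @export
generateCohort <- function(specs, masterSeed, dir = NULL,
                           format = c("edf", "bdf", "csv"),
                           generate = TRUE) {
  format <- match.arg(format)
  if (!length(specs)) stop("empty cohort specification")
  ids <- vapply(specs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate participant ids")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(masterSeed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(specs))
  et <- vapply(specs, function(s) {
    if (is.na(s$etMean)) NA_real_ else .rtruncnorm(1, s$etMean, s$etSd)
  }, numeric(1))
  hit <- ifelse(is.na(et), NA_real_, pmin(et / 2, 1))
  fa <- ifelse(is.na(et), NA_real_, ifelse(et <= 2, 0.5, 1 / et))
  behavior <- data.frame(
    participant = ids,
    group = vapply(specs, `[[`, "", "group"),
    subgroup = vapply(specs, `[[`, "", "subgroup"),
    hit_rate = hit, fa_rate = fa, seed = seeds)
  specs <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]; s$seed <- seeds[i]; s
  })
  recordings <- NULL
  if (generate)
    recordings <- lapply(specs, generateParticipant)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write.csv(behavior, file.path(dir, "cohort.csv"), row.names = FALSE)
    gt <- lapply(seq_along(specs), function(i) {
      s <- specs[[i]]
      out <- list(participant = s$id, group = s$group, subgroup = s$subgroup,
                  seed = s$seed, schedule = s$schedule)
      if (!is.null(recordings)) {
        out$hub <- recordings[[i]]@groundTruth$hub
        out$peakTimes <- recordings[[i]]@groundTruth$peakTimes
        out$peakAmps <- recordings[[i]]@groundTruth$peakAmps
      }
      out
    })
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(recordings)) {
      for (i in seq_along(recordings))
        writeRecording(recordings[[i]]@recording,
                       file.path(dir, paste0(ids[i], ".", format)),
                       format = format)
    }
  }
  list(recordings = recordings, behavior = behavior, specs = specs)
}
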