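## End-to-end pipeline: hub selection -> MMS -> windowed Gamma fits ->
## EMD trajectories, per participant and per cohort, plus the cohort-level
## report.  Windows restart at each block boundary (block statistics are
## reported per block); the empirical mean amplitude is estimated once per
## participant session by default.

#' Pipeline parameters
#'
#' Bundles the analysis parameters with their standard defaults: 5-s
#' windows with 50% overlap, 13--100 Hz band, order-20 bandpass, 20
#' histogram bins, 100-peak minimum per accepted window.
#'
#' @param windowS window length (s).
#' @param overlap window overlap fraction.
#' @param band analysis band (Hz).
#' @param order bandpass filter order.
#' @param bins histogram bins on [0, 1].
#' @param minPeaks minimum spikes per accepted window.
#' @param segS Welch segment length (s) for coherence.
#' @param meanPerBlock re-estimate the empirical mean per block instead of
#'   once per session.
#' @return a \code{pipelineParams} list.
#' @export
pipelineParams <- function(windowS = 5, overlap = 0.5, band = c(13, 100),
                           order = 20, bins = 20, minPeaks = 100,
                           segS = 0.5, meanPerBlock = FALSE) {
  structure(list(windowS = windowS, overlap = overlap, band = band,
                 order = order, bins = bins, minPeaks = minPeaks,
                 segS = segS, meanPerBlock = meanPerBlock),
            class = "pipelineParams")
}

.blockSpans <- function(rec) {
  ann <- blockAnnotations(rec)
  if (nrow(ann) == 0)
    ann <- data.frame(block = 1L, start = 0L, end = nSamples(rec))
  ann
}

#' Analyze one recording
#'
#' Runs the full single-participant pipeline: per-window hub selection on
#' the bandpassed data, hub-series assembly, MMS construction (empirical
#' mean once per session by default), windowed Gamma MLE fits, window
#' histograms and the per-block EMD trajectory with quadrant/direction
#' labels.
#'
#' @param rec an [EEGRecording-class] or [SyntheticRecording-class].
#' @param params a [pipelineParams()].
#' @param participant id used in the output tables.
#' @return list with \code{fits} (data.frame), \code{hubs} (per-block hub
#'   assignments), \code{trajectory} (EMD steps per block),
#'   \code{histograms}, \code{sourceMean}, \code{skipped} (windows under
#'   the peak minimum).
#' @export
analyzeRecording <- function(rec, params = pipelineParams(),
                             participant = "p1") {
  if (is(rec, "SyntheticRecording")) rec <- rec@recording
  stopifnot(is(rec, "EEGRecording"))
  rate <- samplingRate(rec)
  spans <- .blockSpans(rec)
  filtered <- bandpassRecording(rec, params$band[1], params$band[2],
                                params$order)
  perBlock <- vector("list", nrow(spans))
  for (b in seq_len(nrow(spans))) {
    s0 <- spans$start[b]; s1 <- spans$end[b]
    sub <- EEGRecording(rec@samples[, (s0 + 1):s1, drop = FALSE], rate,
                        rec@channelLabels)
    subF <- EEGRecording(filtered@samples[, (s0 + 1):s1, drop = FALSE], rate,
                         rec@channelLabels)
    plan <- planWindows(s1 - s0, rate, params$windowS, params$overlap)
    hs <- hubSeries(sub, plan, band = params$band, order = params$order,
                    segS = params$segS, filtered = subF)
    perBlock[[b]] <- list(block = spans$block[b], series = hs$series,
                          hubs = hs$assignments)
  }
  ## empirical mean amplitude: once per session (default) or per block.
  ## Peak magnitudes |peaks| feed the Gamma fit: a zero-mean oscillatory
  ## carrier has negative-valued local maxima, outside the Gamma support.
  sessionMean <- NULL
  if (!params$meanPerBlock) {
    allPeaks <- abs(unlist(lapply(perBlock, function(pb)
      extractPeaks(pb$series)$values)))
    allPeaks <- allPeaks[allPeaks > 0]
    sessionMean <- as.numeric(
      empiricalMeanAmplitude(allPeaks, minPeaks = params$minPeaks))
  }
  fits <- list(); traj <- list(); hists <- list()
  skipped <- 0L
  for (b in seq_along(perBlock)) {
    pb <- perBlock[[b]]
    blockMean <- sessionMean
    if (is.null(blockMean)) {
      pk <- abs(extractPeaks(pb$series)$values)
      blockMean <- as.numeric(
        empiricalMeanAmplitude(pk[pk > 0], minPeaks = params$minPeaks))
    }
    train <- buildMMS(pb$series, minPeaks = params$minPeaks,
                      mean = blockMean)
    plan <- planWindows(length(pb$series), rate, params$windowS,
                        params$overlap)
    wf <- windowedGammaFits(train, plan, minPeaks = params$minPeaks)
    ## windows spanning a hub-channel switch mix two channels' streams and
    ## carry concatenation artifacts; an isolated single-window hub flip
    ## (a label agreeing with neither neighbour) is indistinguishable from
    ## a selection error.  Fit windows touching either are excluded.
    hubs <- perBlock[[b]]$hubs
    if (nrow(hubs) > 1) {
      nh <- nrow(hubs)
      h <- hubs$hub
      switches <- hubs$start[which(h[-1] != h[-nh]) + 1L]
      flip <- vapply(seq_len(nh), function(k) {
        left <- if (k > 1) h[k] != h[k - 1] else TRUE
        right <- if (k < nh) h[k] != h[k + 1] else TRUE
        left && right && nh > 1
      }, logical(1))
      stride <- attr(plan, "stride")
      spans <- lapply(which(flip), function(k)
        c(hubs$start[k], if (k < nh) hubs$start[k] + stride else hubs$end[k]))
      bad <- vapply(seq_len(nrow(wf)), function(w) {
        inSwitch <- any(switches > wf$start[w] & switches < wf$end[w])
        inFlip <- any(vapply(spans, function(sp)
          sp[1] < wf$end[w] && sp[2] > wf$start[w], logical(1)))
        inSwitch || inFlip
      }, logical(1))
      wf$accepted[bad] <- FALSE
    }
    skipped <- skipped + sum(!wf$accepted)
    wf <- cbind(participant = participant, block = pb$block, wf)
    acc <- which(wf$accepted)
    if (length(acc) >= 2) {
      q <- quadrantSplit(wf$shape[acc], wf$scale[acc])
      wf$quadrant <- NA_character_
      wf$quadrant[acc] <- as.character(q$quadrant)
    } else {
      wf$quadrant <- NA_character_
    }
    hb <- vector("list", nrow(wf))
    for (w in acc) {
      v <- train@values[train@times > wf$start[w] & train@times <= wf$end[w]]
      hb[[w]] <- windowHistogram(v, bins = params$bins)
    }
    if (nrow(wf) >= 2) {
      es <- emdSeries(hb, quadrants = wf$quadrant)
      if (nrow(es)) {
        es <- cbind(participant = participant, block = pb$block, es)
        traj[[length(traj) + 1L]] <- es
      }
    }
    fits[[b]] <- wf
    hists[[b]] <- hb
  }
  list(fits = do.call(rbind, fits),
       hubs = do.call(rbind, lapply(perBlock, function(pb)
         cbind(block = pb$block, pb$hubs))),
       trajectory = if (length(traj)) do.call(rbind, traj) else NULL,
       histograms = hists,
       sourceMean = sessionMean,
       skipped = skipped)
}

#' Per-participant summary of windowed fits
#'
#' @param fits accepted-fit rows for one participant (columns
#'   \code{variance}, \code{block}).
#' @return list with \code{minVariance}, \code{maxVariance},
#'   \code{nAccepted}.
#' @export
participantSummary <- function(fits) {
  f <- fits[fits$accepted, , drop = FALSE]
  if (!nrow(f)) return(list(minVariance = NA_real_, maxVariance = NA_real_,
                            nAccepted = 0L))
  list(minVariance = min(f$variance), maxVariance = max(f$variance),
       nAccepted = nrow(f))
}

#' Analyze a synthetic cohort (or a list of recordings)
#'
#' Generates (when given specs) and analyzes each participant in turn,
#' keeping only the fit tables, and assembles the cohort table: one row per
#' participant with group, subgroup (planted, when known), variance range
#' and ET score from the behavioral table.
#'
#' @param specs list of [participantSpec()] with seeds assigned (e.g. the
#'   \code{specs} element of [generateCohort()]), or a named list of
#'   [EEGRecording-class]/[SyntheticRecording-class] objects.
#' @param behavior behavioral table (\code{participant}, \code{group},
#'   \code{subgroup}, \code{hit_rate}, \code{fa_rate}).
#' @param params a [pipelineParams()].
#' @param verbose print per-participant progress.
#' @return list with \code{fits} (all participants), \code{cohort}
#'   (summary data.frame), \code{behavior}, \code{trajectory} (per-block
#'   EMD steps of all participants).
#' @export
analyzeCohort <- function(specs, behavior = NULL,
                          params = pipelineParams(), verbose = FALSE) {
  n <- length(specs)
  fits <- vector("list", n)
  traj <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- specs[[i]]
    if (inherits(s, "participantSpec")) {
      id <- s$id
      rec <- generateParticipant(s)
      group <- s$group; subgroup <- s$subgroup
    } else {
      id <- if (!is.null(names(specs))) names(specs)[i] else paste0("p", i)
      rec <- s
      group <- subgroup <- NA_character_
    }
    if (verbose) message("analyzing ", id)
    res <- analyzeRecording(rec, params, participant = id)
    fits[[i]] <- res$fits
    traj[[i]] <- res$trajectory
    ps <- participantSummary(res$fits)
    rows[[i]] <- data.frame(participant = id, group = group,
                            subgroup = subgroup,
                            minVariance = ps$minVariance,
                            maxVariance = ps$maxVariance,
                            nAccepted = ps$nAccepted)
    rm(rec, res)
  }
  cohort <- do.call(rbind, rows)
  if (!is.null(behavior)) {
    et <- etScore(behavior$hit_rate[match(cohort$participant,
                                          behavior$participant)],
                  behavior$fa_rate[match(cohort$participant,
                                         behavior$participant)])
    cohort$etScore <- et$score
    bi <- match(cohort$participant, behavior$participant)
    cohort$group <- behavior$group[bi]
    cohort$subgroup <- behavior$subgroup[bi]
  }
  traj <- traj[!vapply(traj, is.null, logical(1))]
  list(fits = do.call(rbind, fits), cohort = cohort, behavior = behavior,
       trajectory = if (length(traj)) do.call(rbind, traj) else NULL)
}

#' Cohort-level report
#'
#' Runs the cohort statistics on an [analyzeCohort()] result: pooled
#' variance distributions per group, dip-gated subgroup split of the mixed
#' group, group test battery, block summaries per group, the second-level
#' shape-fluctuation process per group, and the subgroup convergence block.
#'
#' @param result an [analyzeCohort()] result.
#' @param nBoot dip bootstrap replicates.
#' @param seed seed for the dip bootstrap.
#' @return list with \code{pooled}, \code{split}, \code{tests},
#'   \code{blockSummaries}, \code{globalShape}, \code{convergence}.
#' @export
reportCohort <- function(result, nBoot = 5000, seed = NULL) {
  fits <- result$fits
  cohort <- result$cohort
  acc <- fits[fits$accepted, , drop = FALSE]
  grp <- cohort$group[match(acc$participant, cohort$participant)]
  pooled <- split(acc$variance, grp)
  split <- NULL
  etBySub <- NULL
  mixedIds <- cohort$participant[cohort$group %in% "mixed"]
  if (length(mixedIds) >= 4) {
    mixedSummaries <- cohort[cohort$participant %in% mixedIds, ]
    split <- splitSubgroups(
      data.frame(participant = mixedSummaries$participant,
                 maxVariance = mixedSummaries$maxVariance),
      pooledVariances = pooled[["mixed"]], nBoot = nBoot, seed = seed)
    if (!attr(split, "unimodal") && "etScore" %in% names(mixedSummaries)) {
      lab <- split$subgroup[match(mixedSummaries$participant,
                                  split$participant)]
      etBySub <- list(
        A_broad = mixedSummaries$etScore[lab == "A_broad"],
        B_narrow = mixedSummaries$etScore[lab == "B_narrow"])
    }
  }
  tests <- groupTests(pooled, etBySubgroup = etBySub, nBoot = nBoot,
                      seed = seed)
  blockSummaries <- lapply(base::split(acc, grp), blockSummary)
  globalShape <- lapply(base::split(acc, grp), function(f)
    globalShapeProcess(f$shape[order(f$participant, f$block, f$window)]))
  convergence <- NULL
  if (!is.null(split) && !attr(split, "unimodal")) {
    lab <- split$subgroup[match(acc$participant, split$participant)]
    mixedAcc <- acc[!is.na(lab) & lab != "none", ]
    lab <- lab[!is.na(lab) & lab != "none"]
    ## one variance trajectory per participant: per-block median windowed
    ## variance, so the subgroup bands compare participants, not windows
    med <- aggregate(variance ~ participant + block,
                     data = cbind(mixedAcc, subgroup = lab),
                     FUN = median)
    med$subgroup <- lab[match(med$participant, mixedAcc$participant)]
    convergence <- convergenceSummary(
      data.frame(block = med$block, subgroup = med$subgroup,
                 variance = med$variance))
  }
  list(pooled = pooled, split = split, tests = tests,
       blockSummaries = blockSummaries, globalShape = globalShape,
       convergence = convergence)
}
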