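## Cohort-level statistics: bimodality of pooled windowed Gamma variances,
## distribution-difference tests, dip-gated subgroup splitting, explicit-
## memory (ET) scores, and block-by-block convergence summaries.

#' Hartigan dip test of unimodality
#'
#' Computes the Hartigan & Hartigan dip statistic (the smallest sup-norm
#' distance between the empirical cdf and any unimodal cdf) and calibrates
#' its p-value by bootstrap against the uniform null.
#'
#' @param values numeric sample, n >= 4.
#' @param nBoot bootstrap replicates (default 5000).
#' @param seed optional integer seed for the bootstrap (uses the session RNG
#'   stream when NULL).
#' @return list with \code{dip} (in [1/(2n), 0.25]), \code{p},
#'   \code{nBoot}, \code{n}.
#' @export
dipTest <- function(values, nBoot = 5000, seed = NULL) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("dip test requires at least 4 values")
  d <- dipStatistic(values)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  count <- .dipBootCount(length(values), d, as.integer(nBoot))
  list(dip = d, p = (1 + count) / (nBoot + 1), nBoot = nBoot,
       n = length(values))
}

#' Dip statistic
#'
#' The dip statistic alone (no p-value); see [dipTest()].
#'
#' @param values numeric sample, n >= 2.
#' @return the dip statistic.
#' @export
dipStatistic <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("dip requires at least 2 values")
  .dipStat(values)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided sup-difference of the empirical cdfs with asymptotic p-value
#' (via [stats::ks.test()]).
#'
#' @param x,y numeric samples with n >= 2 each.
#' @return list with \code{D} and \code{p}.
#' @export
ksTwoSample <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) stop("both samples need n >= 2")
  kt <- suppressWarnings(ks.test(x, y, alternative = "two.sided",
                                 exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie correction
#' (both via [stats::wilcox.test()]).
#'
#' @param x,y numeric samples (n >= 1 each).
#' @return list with \code{p}, \code{W}, \code{exact}.
#' @export
rankSumTest <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(p = unname(wt$p.value), W = unname(wt$statistic), exact = exact)
}

#' Explicit-memory test score
#'
#' ET score = hit rate / false-alarm rate; higher scores reflect better
#' explicit knowledge of the embedded regularity. A zero false-alarm rate
#' leaves the score undefined (flagged NA, not infinity).
#'
#' @param hitRate,faRate rates in [0, 1].
#' @return list with \code{score} (NA when undefined) and \code{undefined}.
#' @export
etScore <- function(hitRate, faRate) {
  if (any(hitRate < 0 | hitRate > 1, na.rm = TRUE) ||
      any(faRate < 0 | faRate > 1, na.rm = TRUE))
    stop("rates must lie in [0, 1]")
  undefined <- !is.na(faRate) & faRate == 0
  score <- ifelse(is.na(hitRate) | is.na(faRate) | undefined,
                  NA_real_, hitRate / faRate)
  list(score = score, undefined = undefined)
}

#' Split one group into variance subgroups
#'
#' Reconstructs the self-emerging broad/narrow-variance subgroups: the
#' pooled windowed Gamma variances must first fail unimodality (Hartigan
#' dip, alpha = 0.01 gate); participants are then split by 1-D 2-means on
#' the log of their maximum windowed variance. The cluster with the larger
#' centroid is labelled \code{A_broad}, the other \code{B_narrow}. When the
#' dip gate does not reject, all labels are \code{none} and the result is
#' flagged unimodal.
#'
#' @param summaries data.frame with one row per participant: columns
#'   \code{participant} and \code{maxVariance} (max windowed Gamma variance
#'   over the session).
#' @param pooledVariances numeric vector of all accepted windows' fitted
#'   Gamma variances pooled over the group (the dip-gate input).
#' @param alpha gate level (default 0.01).
#' @param nBoot dip bootstrap replicates.
#' @param seed seed for the dip bootstrap.
#' @return data.frame \code{participant}, \code{subgroup} with attributes
#'   \code{dip} (the [dipTest()] result) and \code{unimodal}.
#' @export
splitSubgroups <- function(summaries, pooledVariances, alpha = 0.01,
                           nBoot = 5000, seed = NULL) {
  if (nrow(summaries) < 4) stop("need at least 4 participants to split")
  if (!all(c("participant", "maxVariance") %in% names(summaries)))
    stop("summaries need columns participant, maxVariance")
  dip <- dipTest(pooledVariances, nBoot = nBoot, seed = seed)
  if (dip$p >= alpha) {
    out <- data.frame(participant = summaries$participant,
                      subgroup = "none")
    attr(out, "dip") <- dip
    attr(out, "unimodal") <- TRUE
    return(out)
  }
  lv <- log(summaries$maxVariance)
  km <- kmeans(lv, centers = 2, nstart = 25)
  broad <- which.max(km$centers)
  out <- data.frame(participant = summaries$participant,
                    subgroup = ifelse(km$cluster == broad,
                                      "A_broad", "B_narrow"))
  attr(out, "dip") <- dip
  attr(out, "unimodal") <- FALSE
  out
}

#' Block-by-block convergence of subgroup variance ranges
#'
#' Computes each subgroup's per-block variance range (bandwidth) and
#' reports the convergence block: the first block from which the subgroup
#' ranges overlap and keep overlapping through the last block.
#'
#' @param trajectories data.frame with columns \code{block},
#'   \code{subgroup}, \code{variance} (per-participant per-block windowed
#'   Gamma variance values).
#' @return list with \code{bands} (per block and subgroup: min, max) and
#'   \code{convergenceBlock} (integer, or NA when the ranges never stay
#'   overlapping).
#' @export
convergenceSummary <- function(trajectories) {
  need <- c("block", "subgroup", "variance")
  if (!all(need %in% names(trajectories)))
    stop("trajectories need columns block, subgroup, variance")
  blocks <- sort(unique(trajectories$block))
  if (length(blocks) < 2) stop("need at least 2 blocks")
  groups <- sort(unique(as.character(trajectories$subgroup)))
  if (length(groups) != 2)
    stop("convergence is defined for exactly 2 subgroups")
  bands <- do.call(rbind, lapply(blocks, function(b) {
    do.call(rbind, lapply(groups, function(g) {
      v <- trajectories$variance[trajectories$block == b &
                                   trajectories$subgroup == g]
      data.frame(block = b, subgroup = g,
                 min = if (length(v)) min(v) else NA_real_,
                 max = if (length(v)) max(v) else NA_real_)
    }))
  }))
  overlap <- vapply(blocks, function(b) {
    a <- bands[bands$block == b & bands$subgroup == groups[1], ]
    c2 <- bands[bands$block == b & bands$subgroup == groups[2], ]
    if (anyNA(c(a$min, a$max, c2$min, c2$max))) return(NA)
    a$min <= c2$max && c2$min <= a$max
  }, logical(1))
  conv <- NA_integer_
  for (i in seq_along(blocks)) {
    if (all(overlap[i:length(blocks)] %in% TRUE)) { conv <- blocks[i]; break }
  }
  list(bands = bands, convergenceBlock = conv)
}

#' Group-level test battery with FDR column
#'
#' Runs the group-level tests (dip per group, pairwise KS between groups,
#' rank-sum on ET scores between subgroups when present) and reports raw
#' p-values alongside Benjamini-Hochberg adjusted ones.
#'
#' @param pooledByGroup named list of pooled windowed Gamma variance
#'   vectors, one per group.
#' @param etBySubgroup optional named list of two ET-score vectors
#'   (e.g. \code{A_broad}, \code{B_narrow}).
#' @param nBoot,seed dip bootstrap settings.
#' @return data.frame: \code{test}, \code{statistic}, \code{p},
#'   \code{pAdjusted}.
#' @export
groupTests <- function(pooledByGroup, etBySubgroup = NULL, nBoot = 5000,
                       seed = NULL) {
  rows <- list()
  for (g in names(pooledByGroup)) {
    dt <- dipTest(pooledByGroup[[g]], nBoot = nBoot, seed = seed)
    rows[[length(rows) + 1L]] <-
      data.frame(test = paste0("dip:", g), statistic = dt$dip, p = dt$p)
  }
  gs <- names(pooledByGroup)
  if (length(gs) > 1) {
    for (i in seq_len(length(gs) - 1)) {
      for (j in (i + 1):length(gs)) {
        kt <- ksTwoSample(pooledByGroup[[gs[i]]], pooledByGroup[[gs[j]]])
        rows[[length(rows) + 1L]] <-
          data.frame(test = paste0("ks:", gs[i], "-vs-", gs[j]),
                     statistic = kt$D, p = kt$p)
      }
    }
  }
  if (!is.null(etBySubgroup) && length(etBySubgroup) == 2) {
    rs <- rankSumTest(etBySubgroup[[1]], etBySubgroup[[2]])
    rows[[length(rows) + 1L]] <-
      data.frame(test = paste0("ranksum:", paste(names(etBySubgroup),
                                                 collapse = "-vs-")),
                 statistic = rs$W, p = rs$p)
  }
  out <- do.call(rbind, rows)
  out$pAdjusted <- p.adjust(out$p, method = "BH")
  out
}
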