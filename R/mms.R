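## Micro-movement spikes (MMS): unitless spike trains built from the peaks
## of the absolute deviations of a biorhythmic series from its empirically
## estimated mean amplitude.  Each peak is normalized as
##   mms = peak / (peak + avg_min_to_min)
## where avg_min_to_min averages the samples strictly between the two local
## minima flanking the peak, excluding the peak sample itself.  The
## normalization removes allometric amplitude effects (MMS(c*x) = MMS(x)
## for c > 0) while preserving the original peak timing.

#' Extract peaks of a series
#'
#' Strict interior local maxima; a flat plateau contributes a single peak at
#' its first sample. Each peak's flanking local minima are returned as well
#' (the series boundary stands in when a side has no interior minimum).
#'
#' @param x numeric series of length >= 3.
#' @return list with \code{peaks} (1-based indices), \code{values},
#'   \code{leftMin}, \code{rightMin} (indices of the flanking minima).
#' @examples
#' extractPeaks(c(0, 1, 0, 2, 0))$peaks   # 2 and 4
#' @export
extractPeaks <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("series must have at least 3 samples")
  d <- diff(x)
  ## collapse flat runs: direction of change, carrying the last nonzero sign
  s <- sign(d)
  nz <- s != 0
  if (!any(nz))
    return(list(peaks = integer(), values = numeric(),
                leftMin = integer(), rightMin = integer()))
  carried <- s
  last <- 0
  for (i in seq_len(n - 1L)) {              # forward-fill zero slopes
    if (carried[i] == 0) carried[i] <- last else last <- carried[i]
  }
  ## a peak starts where slope turns from +1 to -1; plateau rule: the turn
  ## is detected at the first sample of the flat top because zeros carry the
  ## preceding +1 until the drop, and we take the first index of the run
  turn <- which(s[-1] == -1 & carried[-(n - 1L)] == 1) + 1L
  ## map each turn to the first sample of its plateau (walk back over zeros)
  peaks <- vapply(turn, function(i) {
    while (i > 1L && x[i - 1L] == x[i]) i <- i - 1L
    i
  }, integer(1))
  peaks <- unique(peaks)
  peaks <- peaks[peaks > 1L & peaks < n]
  if (!length(peaks))
    return(list(peaks = integer(), values = numeric(),
                leftMin = integer(), rightMin = integer()))
  ## local minima (with plateau rule, first sample), plus boundaries
  mins <- which(s[-1] == 1 & carried[-(n - 1L)] == -1) + 1L
  mins <- vapply(mins, function(i) {
    while (i > 1L && x[i - 1L] == x[i]) i <- i - 1L
    i
  }, integer(1))
  mins <- sort(unique(c(1L, mins, n)))
  li <- findInterval(peaks - 1L, mins)
  leftMin <- mins[pmax(li, 1L)]
  ri <- findInterval(peaks, mins) + 1L
  rightMin <- mins[pmin(ri, length(mins))]
  list(peaks = peaks, values = x[peaks], leftMin = leftMin,
       rightMin = rightMin)
}

#' Empirically estimated mean peak amplitude
#'
#' Fits the two-parameter Gamma family by maximum likelihood to the peak
#' amplitudes and returns the fitted mean \code{shape * scale}. Requires at
#' least \code{minPeaks} peaks for a stable estimate. A degenerate
#' (zero-variance) peak set cannot support the MLE and falls back to the
#' arithmetic mean, flagged via the \code{"method"} attribute.
#'
#' @param peakValues positive peak amplitudes.
#' @param minPeaks minimum number of peaks (default 100).
#' @return the estimated mean amplitude, with attribute \code{method}
#'   (\code{"gamma-mle"} or \code{"arithmetic"}).
#' @export
empiricalMeanAmplitude <- function(peakValues, minPeaks = 100) {
  v <- as.numeric(peakValues)
  if (length(v) < minPeaks)
    stop(sprintf("insufficient peaks: %d < %d required", length(v), minPeaks))
  if (any(v <= 0))
    stop("non-positive peak amplitudes violate the Gamma support")
  if (stats::var(v) < .Machine$double.eps * mean(v)^2) {
    warning("degenerate (zero-variance) peak set: arithmetic-mean fallback")
    return(structure(mean(v), method = "arithmetic"))
  }
  fit <- fitGamma(v)
  structure(fit$shape * fit$scale, method = "gamma-mle")
}

#' Absolute deviation from a mean level
#'
#' @param x numeric series.
#' @param mean finite reference level.
#' @return \code{abs(x - mean)}.
#' @export
deviationSeries <- function(x, mean) {
  if (!is.finite(mean)) stop("mean must be finite")
  abs(as.numeric(x) - mean)
}

#' Normalize a single peak to an MMS value
#'
#' \code{peak / (peak + avg)}, where \code{avg} is the average of the
#' samples strictly between the two flanking local minima (excluding the
#' peak itself). The result lies in (0, 1]; an isolated impulse (avg 0)
#' maps to 1.
#'
#' @param peakValue positive peak amplitude.
#' @param avgMinToMin nonnegative average between the flanking minima.
#' @return MMS value in (0, 1].
#' @export
normalizeSpike <- function(peakValue, avgMinToMin) {
  if (any(peakValue <= 0)) stop("peak value must be positive")
  if (any(avgMinToMin < 0)) stop("avg between minima must be nonnegative")
  peakValue / (peakValue + avgMinToMin)
}

## avg of samples strictly between flanking minima, excluding the peak;
## cumulative sums make this O(1) per peak
.avgMinToMin <- function(x, peaks) {
  cs <- cumsum(x)
  lo <- peaks$leftMin
  hi <- peaks$rightMin
  count <- hi - lo - 2L                      # interior samples minus the peak
  total <- cs[hi - 1L] - cs[lo] - x[peaks$peaks]
  ifelse(count <= 0L, 0, total / pmax(count, 1L))
}

#' Build a micro-movement spike train
#'
#' Composes the MMS pipeline for one series: raw peaks -> Gamma-MLE mean
#' amplitude -> absolute-deviation series -> peaks of the deviation series,
#' each normalized by [normalizeSpike()]. Spike times are the deviation-peak
#' sample indices of the original series.
#'
#' @param x numeric series (hub channel samples).
#' @param minPeaks minimum number of raw peaks required to estimate the mean
#'   (default 100).
#' @param mean optional precomputed mean amplitude (e.g. estimated once per
#'   session and reused per block); when given, \code{minPeaks} applies only
#'   to the caller's estimation.
#' @return An [MMSTrain-class].
#' @export
buildMMS <- function(x, minPeaks = 100, mean = NULL) {
  x <- as.numeric(x)
  meanMethod <- "gamma-mle"
  if (is.null(mean)) {
    pk <- extractPeaks(x)
    if (!length(pk$peaks)) {
      return(new("MMSTrain", times = integer(), values = numeric(),
                 nSamples = length(x), sourceMean = NA_real_,
                 meanMethod = "none"))
    }
    mean <- empiricalMeanAmplitude(pk$values, minPeaks = minPeaks)
    meanMethod <- attr(mean, "method")
    mean <- as.numeric(mean)
  }
  dev <- deviationSeries(x, mean)
  dpk <- extractPeaks(dev)
  keep <- dpk$values > 0
  dpk <- lapply(dpk, `[`, keep)
  if (!length(dpk$peaks))
    return(new("MMSTrain", times = integer(), values = numeric(),
               nSamples = length(x), sourceMean = mean,
               meanMethod = meanMethod))
  avg <- .avgMinToMin(dev, dpk)
  vals <- normalizeSpike(dpk$values, avg)
  new("MMSTrain", times = as.integer(dpk$peaks), values = vals,
      nSamples = length(x), sourceMean = mean, meanMethod = meanMethod)
}

#' Export an MMS train as 2-column TSV
#'
#' @param train an [MMSTrain-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMMSTrain <- function(train, path) {
  write.table(data.frame(sample_index = train@times, value = train@values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
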