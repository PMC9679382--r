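#' @import methods
#' @importFrom stats median var sd quantile rnorm runif rgamma rexp rlnorm
#'   rweibull dgamma dlnorm dnorm dexp dweibull ks.test wilcox.test kmeans
#'   fft approx p.adjust qnorm complete.cases setNames aggregate
#' @importFrom utils read.table write.table read.csv write.csv head tail
#' @useDynLib mmsgamma, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Multichannel sampled recording
#'
#' Container for a continuous multichannel biorhythmic recording: a channels
#' x time sample matrix, its sampling rate, channel labels, and optional
#' block annotations as half-open sample intervals.
#'
#' @slot samples numeric matrix, channels x time, amplitude in microvolts or
#'   unit-scaled.
#' @slot samplingRate sampling rate in Hz (positive scalar).
#' @slot channelLabels character vector, one label per channel (row).
#' @slot annotations data.frame with columns \code{block}, \code{start},
#'   \code{end}: half-open, 0-based sample intervals \code{[start, end)}.
#'
#' @seealso [EEGRecording()] for the constructor, [readRecording()] for file
#'   input.
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    samples = "matrix",
    samplingRate = "numeric",
    channelLabels = "character",
    annotations = "data.frame"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (nrow(object@samples) != length(object@channelLabels))
    msg <- c(msg, "one channel label per sample-matrix row is required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  ann <- object@annotations
  if (nrow(ann) > 0) {
    need <- c("block", "start", "end")
    if (!all(need %in% names(ann))) {
      msg <- c(msg, "annotations need columns block, start, end")
    } else if (any(ann$start < 0) || any(ann$end > ncol(object@samples)) ||
               any(ann$end <= ann$start)) {
      msg <- c(msg, "annotation intervals must be within [0, n_samples) and non-empty")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param samples channels x time numeric matrix.
#' @param samplingRate sampling rate (Hz).
#' @param channelLabels channel labels; defaults to \code{ch1, ch2, ...}.
#' @param annotations optional data.frame of half-open block intervals
#'   (columns \code{block}, \code{start}, \code{end}, 0-based samples).
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(512), nrow = 2), samplingRate = 256)
#' nSamples(rec)
#' @export
EEGRecording <- function(samples, samplingRate,
                         channelLabels = NULL, annotations = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(nrow(samples)))
  if (is.null(annotations))
    annotations <- data.frame(block = integer(), start = integer(),
                              end = integer())
  new("EEGRecording", samples = samples, samplingRate = as.numeric(samplingRate),
      channelLabels = as.character(channelLabels), annotations = annotations)
}

#' Micro-movement spike train
#'
#' Unitless spike train derived from a biorhythmic series: spike times are
#' the sample indices of the peaks of the absolute-deviation series, spike
#' values lie in (0, 1], and the train is zero between spikes (quiet periods
#' of mean-level activity).
#'
#' @slot times integer vector of 1-based sample indices, strictly increasing.
#' @slot values numeric vector in (0, 1], same length as \code{times}.
#' @slot nSamples length of the source series.
#' @slot sourceMean empirically estimated mean amplitude of the source peaks
#'   (original amplitude units).
#' @slot meanMethod \code{"gamma-mle"} or \code{"arithmetic"} (degenerate
#'   fallback).
#' @exportClass MMSTrain
setClass("MMSTrain",
  representation(
    times = "integer",
    values = "numeric",
    nSamples = "integer",
    sourceMean = "numeric",
    meanMethod = "character"
  )
)

setValidity("MMSTrain", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (is.unsorted(object@times, strictly = TRUE) && length(object@times) > 1)
    msg <- c(msg, "spike times must be strictly increasing")
  if (length(object@values) && (any(object@values <= 0) || any(object@values > 1)))
    msg <- c(msg, "spike values must lie in (0, 1]")
  if (length(object@times) && (min(object@times) < 1 ||
      max(object@times) > object@nSamples))
    msg <- c(msg, "spike times must index into the source series")
  if (length(msg)) msg else TRUE
})

#' Synthetic recording with planted ground truth
#'
#' An [EEGRecording-class] produced by the synthetic cohort generator,
#' bundled with its ground truth: the planted peak times and amplitudes on
#' the hub channel, the per-block regime schedule, and the planted hub label.
#'
#' @slot recording the generated [EEGRecording-class].
#' @slot groundTruth list with elements \code{peakTimes}, \code{peakAmps}
#'   (per block), \code{schedule} (data.frame), \code{hub} (label),
#'   \code{spec} (the generating [participantSpec()]).
#' @exportClass SyntheticRecording
setClass("SyntheticRecording",
  representation(recording = "EEGRecording", groundTruth = "list")
)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz\n",
              nrow(object@samples), ncol(object@samples), object@samplingRate))
  cat("  channels:", paste(head(object@channelLabels, 6), collapse = ", "),
      if (length(object@channelLabels) > 6) "..." else "", "\n")
  if (nrow(object@annotations))
    cat(sprintf("  %d block annotation(s)\n", nrow(object@annotations)))
})

setMethod("show", "MMSTrain", function(object) {
  cat(sprintf("MMSTrain: %d spikes over %d samples (mean %s, source mean %.4g)\n",
              length(object@times), object@nSamples, object@meanMethod,
              object@sourceMean))
})

setMethod("show", "SyntheticRecording", function(object) {
  cat("SyntheticRecording (planted hub:", object@groundTruth$hub, ")\n")
  show(object@recording)
})
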