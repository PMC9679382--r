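#' Accessor generics
#'
#' Accessors for the sample matrix, sampling rate, channel labels and block
#' annotations of an [EEGRecording-class], and for the spike times/values of
#' an [MMSTrain-class].
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("blockAnnotations", function(x) standardGeneric("blockAnnotations"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("spikeValues", function(x) standardGeneric("spikeValues"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("recording", function(x) standardGeneric("recording"))

#' @rdname accessors
#' @export
setMethod("samples", "EEGRecording", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("blockAnnotations", "EEGRecording", function(x) x@annotations)
#' @rdname accessors
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@samples))
#' @rdname accessors
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@samples))

#' @rdname accessors
#' @export
setMethod("spikeTimes", "MMSTrain", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("spikeValues", "MMSTrain", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("nSamples", "MMSTrain", function(x) x@nSamples)

#' @rdname accessors
#' @export
setMethod("recording", "SyntheticRecording", function(x) x@recording)
#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticRecording", function(x) x@groundTruth)
#' @rdname accessors
#' @export
setMethod("samples", "SyntheticRecording", function(x) x@recording@samples)
#' @rdname accessors
#' @export
setMethod("samplingRate", "SyntheticRecording", function(x) x@recording@samplingRate)
#' @rdname accessors
#' @export
setMethod("channelLabels", "SyntheticRecording", function(x) x@recording@channelLabels)
#' @rdname accessors
#' @export
setMethod("blockAnnotations", "SyntheticRecording", function(x) x@recording@annotations)

#' Dense spike-train vector
#'
#' Expand an [MMSTrain-class] to a dense numeric vector over the source
#' sample grid: spike values at spike times, zero in the quiet periods.
#'
#' @param x an [MMSTrain-class].
#' @return numeric vector of length \code{nSamples(x)}.
#' @export
trainVector <- function(x) {
  stopifnot(is(x, "MMSTrain"))
  v <- numeric(x@nSamples)
  v[x@times] <- x@values
  v
}
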