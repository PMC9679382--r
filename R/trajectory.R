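## Earth Mover's Distance trajectories: histogram-to-histogram distances
## between consecutive windows, EMD peak/inter-peak-interval statistics, and
## the second-level "Gamma process of Gamma-shape fluctuations".
##
## On a 1-D support the Wasserstein-1 distance has the closed form
##   EMD(p, q) = sum_k |cumsum(p - q)_k| * (c_{k+1} - c_k)
## over bin centers c; the linear-program transport formulation is kept as a
## test oracle.

#' Build a normalized window histogram
#'
#' Mass-normalized histogram on fixed equal-width bins; the default 20 bins
#' on [0, 1] match the MMS value range and keep about 5 expected counts per
#' occupied bin at the 100-spike window minimum.
#'
#' @param values numeric values inside \code{range}.
#' @param bins number of equal-width bins (default 20).
#' @param range support interval (default \code{c(0, 1)}).
#' @return list with \code{mass} (sums to 1), \code{edges}, \code{centers},
#'   \code{n}.
#' @export
windowHistogram <- function(values, bins = 20, range = c(0, 1)) {
  values <- as.numeric(values)
  if (!length(values)) stop("no values to bin")
  if (any(values < range[1] | values > range[2]))
    stop("values outside the histogram support")
  edges <- seq(range[1], range[2], length.out = bins + 1)
  idx <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
              bins)
  mass <- tabulate(idx, nbins = bins) / length(values)
  list(mass = mass, edges = edges,
       centers = (edges[-1] + edges[-(bins + 1)]) / 2, n = length(values))
}

#' Earth Mover's Distance between two histograms
#'
#' 1-D Wasserstein-1 distance between two mass-normalized histograms on
#' identical bins, via the cumulative-difference closed form. Units:
#' probability mass times the support units (MMS units for spike
#' histograms).
#'
#' @param h1,h2 histograms from [windowHistogram()] (identical edges).
#' @return nonnegative scalar; 0 iff the histograms are identical.
#' @export
emd <- function(h1, h2) {
  if (length(h1$edges) != length(h2$edges) ||
      max(abs(h1$edges - h2$edges)) > 1e-12)
    stop("histograms must share identical bin edges")
  cdiff <- cumsum(h1$mass - h2$mass)
  k <- length(h1$centers)
  sum(abs(cdiff[-k]) * diff(h1$centers))
}

#' EMD series over consecutive windows
#'
#' For an ordered sequence of window histograms, computes the EMD between
#' each histogram and the next, labelling each step with the landing
#' window's Gamma-plane quadrant and a shift-direction color: red for steps
#' landing in the RLQ (from the LUQ into the RLQ, or RLQ to itself), blue
#' for steps landing in the LUQ; steps landing in the off-diagonal quadrants
#' keep the quadrant pair but no color. Windows skipped upstream (NULL
#' histograms) break the series into segments rather than being bridged.
#'
#' @param histograms list of histograms ([windowHistogram()]), NULL for
#'   skipped windows.
#' @param quadrants optional factor/character of quadrant labels per window
#'   (from [quadrantSplit()]).
#' @return data.frame with \code{from}, \code{to} (window indices),
#'   \code{emd}, \code{segment} (contiguous-run id), \code{landingQuadrant},
#'   \code{direction} (e.g. \code{"LUQ->RLQ"}), \code{color}
#'   (\code{"red"}/\code{"blue"}/NA).
#' @export
emdSeries <- function(histograms, quadrants = NULL) {
  nw <- length(histograms)
  if (nw < 2) stop("need at least 2 windows")
  ok <- !vapply(histograms, is.null, logical(1))
  steps <- which(ok[-nw] & ok[-1])
  if (!length(steps))
    return(data.frame(from = integer(), to = integer(), emd = numeric(),
                      segment = integer(), landingQuadrant = character(),
                      direction = character(), color = character()))
  e <- vapply(steps, function(i) emd(histograms[[i]], histograms[[i + 1]]),
              numeric(1))
  segment <- cumsum(c(1L, diff(steps) != 1L))
  landing <- direction <- color <- rep(NA_character_, length(steps))
  if (!is.null(quadrants)) {
    quadrants <- as.character(quadrants)
    landing <- quadrants[steps + 1L]
    src <- quadrants[steps]
    direction <- paste0(src, "->", landing)
    color[landing == "RLQ"] <- "red"
    color[landing == "LUQ"] <- "blue"
  }
  data.frame(from = steps, to = steps + 1L, emd = e, segment = segment,
             landingQuadrant = landing, direction = direction, color = color)
}

#' EMD peak amplitudes and inter-peak intervals
#'
#' Extracts the peaks of an EMD series (via [extractPeaks()]), their
#' amplitudes and the inter-peak intervals (in window-index units;
#' multiply by the window stride and divide by the sampling rate for
#' seconds), and fits candidate distributions to each by MLE. With fewer
#' than \code{minPeaks} peaks the fits are still computed but flagged
#' low-confidence rather than dropped.
#'
#' @param emdValues numeric EMD series (one segment).
#' @param minPeaks the peak count below which fits are flagged (default
#'   100).
#' @return list with \code{peakIndices}, \code{amplitudes},
#'   \code{intervals}, \code{amplitudeFit}, \code{intervalFit} (each a
#'   [fitCandidates()] result or NULL when fewer than 2 positive values),
#'   \code{lowConfidence}.
#' @export
emdPeaks <- function(emdValues, minPeaks = 100) {
  emdValues <- as.numeric(emdValues)
  if (length(emdValues) < 3) stop("EMD series must have length >= 3")
  pk <- extractPeaks(emdValues)
  amps <- pk$values
  ints <- diff(pk$peaks)
  fitOrNull <- function(v) {
    v <- v[v > 0]
    if (length(v) < 2) return(NULL)
    tryCatch(fitCandidates(v, minN = 2), error = function(e) NULL)
  }
  list(peakIndices = pk$peaks, amplitudes = amps, intervals = ints,
       amplitudeFit = fitOrNull(amps),
       intervalFit = fitOrNull(as.numeric(ints)),
       lowConfidence = length(pk$peaks) < minPeaks)
}

#' Second-level Gamma process of Gamma-shape fluctuations
#'
#' Treats the pooled sequence of window-level Gamma shape values as a signal
#' in its own right: fits the second-level Gamma to the shape values (the
#' distribution of shape fluctuations), extracts the sequence's peaks, and
#' summarizes the EMD dynamics of its windowed histograms. A constant shape
#' sequence is degenerate and returns a flag instead of a fit.
#'
#' @param shapeValues ordered window-level Gamma shape values (pooled across
#'   the participants of one group/subgroup/target stratum).
#' @param minPeaks flag threshold passed to [emdPeaks()].
#' @return list with \code{degenerate}, \code{fit} (second-level
#'   [fitGamma()] with NSR/SNR), \code{peaks} (of the shape sequence),
#'   \code{n}.
#' @export
globalShapeProcess <- function(shapeValues, minPeaks = 100) {
  v <- as.numeric(shapeValues)
  v <- v[is.finite(v)]
  if (length(v) < 3) stop("need at least 3 shape values")
  if (stats::sd(v) < .Machine$double.eps * max(abs(v)))
    return(list(degenerate = TRUE, fit = NULL, peaks = NULL, n = length(v)))
  f <- fitGamma(v)
  f$nsr <- nsr(f$shape, f$scale)
  f$snr <- 1 / f$nsr
  pk <- extractPeaks(v)
  list(degenerate = FALSE, fit = f,
       peaks = list(indices = pk$peaks, values = pk$values,
                    intervals = diff(pk$peaks),
                    lowConfidence = length(pk$peaks) < minPeaks),
       n = length(v))
}
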