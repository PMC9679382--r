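## Cross-coherence hub network: Welch magnitude-squared coherence between
## all channel pairs inside each sliding window, the resulting adjacency
## matrix, Onnela-style weighted clustering coefficients, and per-window hub
## selection.

## Welch cross-spectral density matrix.
## X: samples x channels. Returns list(freq, S) with S an array
## [nfreq, nch, nch] of averaged cross spectra (Hann window, demeaned,
## 50%-overlapping segments).
.welchCsd <- function(X, rate, segS = 1, segOverlap = 0.5) {
  X <- as.matrix(X)
  n <- nrow(X)
  nseg <- as.integer(round(segS * rate))
  if (n < nseg) stop("signal shorter than one Welch segment")
  stride <- max(1L, as.integer(round((1 - segOverlap) * nseg)))
  starts <- seq.int(1L, n - nseg + 1L, by = stride)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  nf <- nseg %/% 2L + 1L
  nch <- ncol(X)
  nsg <- length(starts)
  ## all segments of all channels in one matrix (segments nested within
  ## channels, column-major), one FFT call for the window
  rows <- as.vector(outer(seq_len(nseg) - 1L, starts, `+`))
  segMat <- X[rows, , drop = FALSE]
  dim(segMat) <- c(nseg, nsg * nch)
  segMat <- segMat - matrix(colMeans(segMat), nseg, nsg * nch, byrow = TRUE)
  segMat <- segMat * win
  F <- stats::mvfft(segMat)[seq_len(nf), , drop = FALSE]
  S <- array(0+0i, dim = c(nf, nch, nch))
  for (f in seq_len(nf)) {
    Ff <- matrix(F[f, ], nsg, nch)
    S[f, , ] <- t(Conj(Ff)) %*% Ff
  }
  S <- S / nsg
  list(freq = (seq_len(nf) - 1L) * rate / nseg, S = S, nSegments = nsg)
}

## Full coherence adjacency (max over band) from a CSD array, vectorized
## over pairs.
.cohAdjacency <- function(csd, band) {
  f <- csd$freq
  keep <- which(f >= band[1] & f <= band[2])
  if (!length(keep)) stop("no Welch frequencies inside the analysis band")
  S <- csd$S[keep, , , drop = FALSE]
  nch <- dim(S)[2]
  nf <- length(keep)
  auto <- matrix(0, nf, nch)
  for (i in seq_len(nch)) auto[, i] <- Re(S[, i, i])
  bad <- which(apply(auto, 2, function(v) any(v <= .Machine$double.eps)))
  if (length(bad))
    stop("undefined coherence: (near-)constant signal in channel(s) ",
         paste(bad, collapse = ", "))
  A <- matrix(0, nch, nch)
  for (i in seq_len(nch - 1)) {
    num <- Mod(S[, i, (i + 1):nch, drop = FALSE])^2   # nf x 1 x (nch-i)
    dim(num) <- c(nf, nch - i)
    coh <- num / (auto[, i] * auto[, (i + 1):nch, drop = FALSE])
    mx <- apply(coh, 2, max)
    A[i, (i + 1):nch] <- A[(i + 1):nch, i] <- pmin(mx, 1)
  }
  A
}

## Coherence and cross-phase from a CSD array for one channel pair.
.cohFromCsd <- function(csd, i, j, band) {
  f <- csd$freq
  keep <- f >= band[1] & f <= band[2]
  Sxy <- csd$S[keep, i, j]
  Sxx <- Re(csd$S[keep, i, i])
  Syy <- Re(csd$S[keep, j, j])
  denom <- Sxx * Syy
  if (any(denom <= .Machine$double.eps))
    stop("undefined coherence: (near-)constant signal in pair")
  coh <- Mod(Sxy)^2 / denom
  k <- which.max(coh)
  list(coherence = min(coh[k], 1), freqHz = f[keep][k],
       phase = Arg(Sxy[k]))
}

#' Maximal cross-coherence between two signals
#'
#' Welch-averaged magnitude-squared coherence between two equal-length
#' signals (Hann segments, 50% segment overlap), maximized over the analysis
#' band. Returns the maximum together with the frequency at which it is
#' attained and the cross-spectral phase there. Phase follows the
#' \code{Arg(conj(X) * Y)} convention: a pure delay of \code{dt} seconds in
#' \code{y} gives phase \code{-2*pi*f*dt}.
#'
#' @param x,y equal-length numeric signals.
#' @param rate sampling rate (Hz).
#' @param band analysis band in Hz (default \code{c(13, 100)}).
#' @param segS Welch segment length in seconds (default 1).
#' @return list with \code{coherence} (in [0,1]), \code{freqHz},
#'   \code{phase} (radians), \code{nSegments}.
#' @export
coherenceEdge <- function(x, y, rate, band = c(13, 100), segS = 1) {
  if (length(x) != length(y)) stop("signals must have equal length")
  csd <- .welchCsd(cbind(x, y), rate, segS = segS)
  out <- .cohFromCsd(csd, 1L, 2L, band)
  out$nSegments <- csd$nSegments
  out
}

#' Cross-coherence adjacency matrix of one window
#'
#' Builds the symmetric matrix of maximal pairwise magnitude-squared
#' coherences over the analysis band for one window of a multichannel
#' recording; used as the weighted adjacency matrix of the channel network.
#'
#' @param X samples x channels matrix (one window, already bandpassed), or an
#'   [EEGRecording-class] whose full span is used.
#' @param rate sampling rate (Hz); taken from the recording if one is given.
#' @param band analysis band in Hz.
#' @param segS Welch segment length in seconds.
#' @return symmetric matrix with zero diagonal, entries in [0, 1],
#'   dimnames = channel labels when available.
#' @export
adjacencyMatrix <- function(X, rate = NULL, band = c(13, 100), segS = 1) {
  labels <- NULL
  if (is(X, "EEGRecording")) {
    rate <- X@samplingRate
    labels <- X@channelLabels
    X <- t(X@samples)
  }
  X <- as.matrix(X)
  nch <- ncol(X)
  if (nch < 3) stop("adjacency requires at least 3 channels")
  if (is.null(rate)) stop("rate is required")
  csd <- .welchCsd(X, rate, segS = segS)
  A <- .cohAdjacency(csd, band)
  if (!is.null(labels)) dimnames(A) <- list(labels, labels)
  A
}

#' Weighted clustering coefficients
#'
#' Onnela-style weighted clustering coefficient per node: the mean geometric
#' triangle intensity over all pairs of neighbours, with weights normalized
#' by the maximum weight in the graph, so coefficients lie in [0, 1].
#'
#' @param A symmetric nonnegative weight matrix (zero diagonal).
#' @return numeric vector of per-node coefficients; all zero for graphs with
#'   fewer than 3 nodes or nodes with degree < 2.
#' @export
clusteringCoefficients <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (any(A < 0)) stop("weights must be nonnegative")
  if (max(abs(A - t(A))) > 1e-12) stop("adjacency must be symmetric")
  n <- nrow(A)
  cc <- numeric(n)
  names(cc) <- rownames(A)
  if (n < 3) return(cc)
  diag(A) <- 0
  mx <- max(A)
  if (mx == 0) return(cc)
  W <- (A / mx)^(1 / 3)
  k <- rowSums(A > 0)
  num <- diag(W %*% W %*% W)          # 2 * sum of triangle intensities at node
  ok <- k >= 2
  cc[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  cc
}

#' Select the hub channel of one window
#'
#' The hub is the channel with the maximal weighted clustering coefficient
#' in the window's cross-coherence network; exact ties are broken by channel
#' order (first label wins).
#'
#' @inheritParams adjacencyMatrix
#' @param labels channel labels (defaulted from the recording or matrix).
#' @return list with \code{hub} (label), \code{hubIndex},
#'   \code{coefficients} (named per-channel vector).
#' @export
selectHub <- function(X, rate = NULL, band = c(13, 100), segS = 1,
                      labels = NULL) {
  if (is(X, "EEGRecording")) {
    if (is.null(labels)) labels <- X@channelLabels
    rate <- X@samplingRate
    X <- t(X@samples)
  }
  X <- as.matrix(X)
  if (ncol(X) < 3)
    stop("hub selection requires at least 3 channels")
  if (all(abs(X) < .Machine$double.eps)) stop("all-zero window")
  A <- adjacencyMatrix(X, rate, band = band, segS = segS)
  cc <- clusteringCoefficients(A)
  if (is.null(labels)) labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(X)))
  names(cc) <- labels
  idx <- which.max(cc)                 # which.max takes the first maximum
  list(hub = labels[idx], hubIndex = unname(idx), coefficients = cc)
}

#' Hub series over a window plan
#'
#' For each window of the plan, selects the hub channel on the bandpassed
#' data and takes the hub channel's raw samples over the window's stride
#' segment (its non-overlapping advance), concatenating them into one
#' continuous single-channel series with a per-window hub label track.  Only
#' the stride segment of each window contributes, so no sample is used
#' twice; the final window contributes its full remainder.
#'
#' @param rec an [EEGRecording-class] (raw, unfiltered).
#' @param plan a window plan from [planWindows()] (sample coordinates of
#'   \code{rec}).
#' @param band analysis band (Hz) used for hub selection.
#' @param order bandpass order for hub selection.
#' @param segS Welch segment length (s).
#' @param filtered optional pre-bandpassed copy of \code{rec} (to avoid
#'   refiltering when the caller already has one).
#' @return list with \code{series} (numeric), \code{assignments}
#'   (data.frame: window, start, end, hub, coefficient), \code{stride}.
#' @export
hubSeries <- function(rec, plan, band = c(13, 100), order = 20, segS = 1,
                      filtered = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  if (nrow(plan) == 0)
    return(list(series = numeric(0),
                assignments = data.frame(window = integer(), start = integer(),
                                         end = integer(), hub = character(),
                                         coefficient = numeric()),
                stride = NA_integer_))
  if (is.null(filtered))
    filtered <- bandpassRecording(rec, band[1], band[2], order)
  stride <- attr(plan, "stride")
  labels <- rec@channelLabels
  pieces <- vector("list", nrow(plan))
  hubs <- character(nrow(plan))
  coefs <- numeric(nrow(plan))
  for (w in seq_len(nrow(plan))) {
    s0 <- plan$start[w]; s1 <- plan$end[w]
    Xw <- t(filtered@samples[, (s0 + 1):s1, drop = FALSE])
    sel <- selectHub(Xw, rec@samplingRate, band = band, segS = segS,
                     labels = labels)
    hubs[w] <- sel$hub
    coefs[w] <- sel$coefficients[sel$hubIndex]
    segEnd <- if (w < nrow(plan)) min(s0 + stride, s1) else s1
    pieces[[w]] <- rec@samples[sel$hubIndex, (s0 + 1):segEnd]
  }
  list(series = unlist(pieces, use.names = FALSE),
       assignments = data.frame(window = plan$window, start = plan$start,
                                end = plan$end, hub = hubs,
                                coefficient = coefs),
       stride = stride)
}

#' Export hub assignments as TSV
#'
#' @param assignments the \code{assignments} element of [hubSeries()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeHubAssignments <- function(assignments, path) {
  write.table(assignments[, c("start", "end", "hub", "coefficient")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
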