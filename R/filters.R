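## Butterworth bandpass in cascaded second-order sections (biquads),
## applied forward-backward for zero phase.  A direct-form transfer function
## of order 20 is numerically unusable at EEG rates; the SOS cascade keeps
## each section well conditioned.  Each biquad is run through
## signal::filtfilt, so the effective magnitude response is |H|^2 of the
## designed cascade.

## Analog Butterworth lowpass prototype poles (order n, cutoff 1 rad/s),
## bandpass-transformed and discretized by the bilinear transform.
.butterBandpassSos <- function(order, lowHz, highHz, rate) {
  if (order %% 2L != 0L) stop("bandpass order must be even")
  n <- order %/% 2L                      # prototype order; bandpass doubles it
  fs2 <- 2 * rate
  w1 <- fs2 * tan(pi * lowHz / rate)     # pre-warped edge frequencies (rad/s)
  w2 <- fs2 * tan(pi * highHz / rate)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # left-half-plane poles
  ## s_lp -> (s^2 + w0^2)/(bw*s): each prototype pole yields two bandpass poles
  bp <- bw * proto
  polesA <- (bp + sqrt(bp^2 - 4 * w0^2)) / 2
  polesB <- (bp - sqrt(bp^2 - 4 * w0^2)) / 2
  zpoles <- (fs2 + c(polesA, polesB)) / (fs2 - c(polesA, polesB))
  ## zeros: n at z = 1 (s = 0) and n at z = -1 (s = Inf)
  ## group poles into conjugate pairs; pair each with one zero at +1, one at -1
  up <- zpoles[Im(zpoles) >= 0]
  up <- up[order(Mod(up))]
  sos <- lapply(up, function(p) {
    a <- c(1, -2 * Re(p), Mod(p)^2)
    b <- c(1, 0, -1)                     # zeros at +1 and -1
    list(b = b, a = a)
  })
  ## normalize overall gain to 1 at the band center frequency
  wc <- 2 * pi * sqrt(lowHz * highHz) / rate
  z1 <- exp(-1i * wc)
  h <- vapply(sos, function(s)
    (s$b[1] + s$b[2] * z1 + s$b[3] * z1^2) /
      (s$a[1] + s$a[2] * z1 + s$a[3] * z1^2), complex(1))
  g <- Mod(prod(h))
  gsec <- g^(-1 / length(sos))
  lapply(sos, function(s) list(b = s$b * gsec, a = s$a))
}

## forward-backward filtering with odd-reflection end padding, so the
## filter transient settles outside the data span
.sosFiltfilt <- function(sos, x) {
  n <- length(x)
  p <- min(n - 1L, 512L)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  bm <- do.call(rbind, lapply(sos, `[[`, "b"))
  am <- do.call(rbind, lapply(sos, `[[`, "a"))
  .sosFiltFiltC(xp, bm, am)[(p + 1):(p + n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Filters every channel of a recording with a Butterworth bandpass designed
#' as cascaded second-order sections and applied forward-backward
#' (zero-phase). The default 13--100 Hz band at order 20 targets the
#' beta-through-gamma range used for hub selection.
#'
#' @param rec an [EEGRecording-class] (or a numeric vector with \code{rate}
#'   given).
#' @param lowHz,highHz band edges in Hz; must satisfy
#'   \code{0 < lowHz < highHz < rate/2}.
#' @param order total filter order (even; default 20, i.e. ten biquads).
#' @param rate sampling rate, only needed when \code{rec} is a plain vector.
#' @return the filtered recording (same class as the input).
#' @export
bandpassRecording <- function(rec, lowHz = 13, highHz = 100, order = 20,
                              rate = NULL) {
  if (is(rec, "EEGRecording")) {
    rate <- rec@samplingRate
  } else if (is.null(rate)) {
    stop("rate must be given for plain numeric input")
  }
  if (!(lowHz > 0 && lowHz < highHz)) stop("need 0 < lowHz < highHz")
  if (highHz >= rate / 2)
    stop(sprintf("upper band edge %g Hz violates the Nyquist limit %g Hz",
                 highHz, rate / 2))
  sos <- .butterBandpassSos(order, lowHz, highHz, rate)
  if (is(rec, "EEGRecording")) {
    y <- t(apply(rec@samples, 1, function(ch) .sosFiltfilt(sos, ch)))
    initialize(rec, samples = y)
  } else {
    .sosFiltfilt(sos, as.numeric(rec))
  }
}
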