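## Windowed maximum-likelihood Gamma signatures: the local stochastic
## analyses.  Shape a and scale b parameterize the density
##   f(x) = 1 / (gamma(a) * b^a) * x^(a-1) * exp(-x / b),
## whose moments are mean a*b, variance a*b^2, skewness 2/sqrt(a) and excess
## kurtosis 6/a.  The noise-to-signal ratio of the fitted process is
## variance/mean = b, so the scale axis of the Gamma parameter plane is an
## NSR axis and SNR = 1/b.

#' Gamma MLE with asymptotic confidence intervals
#'
#' Newton iteration on the profile likelihood of the shape (the standard
#' \code{log(a) - digamma(a) = log(mean) - mean(log)} score equation), with
#' 95% confidence intervals from the observed information, computed on
#' \code{(log a, log b)} and mapped back, so the intervals respect
#' positivity.
#'
#' @param x positive values.
#' @param conf confidence level (default 0.95).
#' @return list with \code{shape}, \code{scale}, \code{shapeCI},
#'   \code{scaleCI}, \code{logLik}, \code{n}, \code{mean}, \code{variance}
#'   (fitted moments a*b and a*b^2).
#' @export
fitGamma <- function(x, conf = 0.95) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 values")
  if (any(x <= 0)) stop("Gamma support requires positive values")
  m <- mean(x)
  s <- log(m) - mean(log(x))
  if (s < .Machine$double.eps)
    stop("degenerate sample: zero variance")
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)   # Minka initialization
  for (i in 1:50) {
    step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
    aNew <- a - step
    if (aNew <= 0) aNew <- a / 2
    if (abs(aNew - a) < 1e-12 * a) { a <- aNew; break }
    a <- aNew
  }
  b <- m / a
  ll <- sum(dgamma(x, shape = a, scale = b, log = TRUE))
  ## observed information on (log a, log b):
  ##   I = n * [[a^2 * trigamma(a), a], [a, a]]
  I <- n * matrix(c(a^2 * trigamma(a), a, a, a), 2, 2)
  V <- solve(I)
  z <- qnorm(1 - (1 - conf) / 2)
  seLogA <- sqrt(V[1, 1])
  seLogB <- sqrt(V[2, 2])
  list(shape = a, scale = b,
       shapeCI = a * exp(c(-1, 1) * z * seLogA),
       scaleCI = b * exp(c(-1, 1) * z * seLogB),
       logLik = ll, n = n, mean = a * b, variance = a * b^2)
}

#' Gamma density
#'
#' Density of the two-parameter Gamma family in shape/scale form. Thin
#' domain-checked wrapper around [stats::dgamma()].
#'
#' @param x nonnegative quantiles.
#' @param shape,scale positive parameters.
#' @return density values.
#' @export
gammaPdf <- function(x, shape, scale) {
  if (any(shape <= 0) || any(scale <= 0))
    stop("shape and scale must be positive")
  if (any(x < 0)) stop("x must be nonnegative")
  dgamma(x, shape = shape, scale = scale)
}

#' Gamma moments
#'
#' Mean, variance, skewness and excess kurtosis of a Gamma(shape, scale):
#' \code{a*b}, \code{a*b^2}, \code{2/sqrt(a)}, \code{6/a}. (The kurtosis is
#' the excess-kurtosis Gamma identity 6/a.)
#'
#' @param shape,scale positive parameters.
#' @return list with \code{mean}, \code{variance}, \code{skewness},
#'   \code{kurtosis}.
#' @export
gammaMoments <- function(shape, scale) {
  if (any(shape <= 0) || any(scale <= 0))
    stop("shape and scale must be positive")
  list(mean = shape * scale, variance = shape * scale^2,
       skewness = 2 / sqrt(shape), kurtosis = 6 / shape)
}

#' Noise-to-signal and signal-to-noise ratios
#'
#' In the Gamma family the NSR (fitted variance over fitted mean) equals the
#' scale parameter: \code{a*b^2 / (a*b) = b}; the SNR is its reciprocal.
#'
#' @param shape,scale positive Gamma parameters (\code{shape} is accepted
#'   for symmetry of the signature interface; the ratio depends only on the
#'   scale).
#' @return scalar NSR (= scale) or SNR (= 1/scale).
#' @export
nsr <- function(shape, scale) {
  if (any(shape <= 0) || any(scale <= 0))
    stop("shape and scale must be positive")
  (shape * scale^2) / (shape * scale)
}

#' @rdname nsr
#' @export
snr <- function(shape, scale) 1 / nsr(shape, scale)

.candidateFamilies <- c("gamma", "exponential", "lognormal", "normal",
                        "weibull")

#' Candidate-family MLE fits and selection
#'
#' Fits the Lognormal, Normal, Exponential, Gamma and Weibull families by
#' maximum likelihood and selects the best family by raw maximized
#' log-likelihood. Because the exponential is the shape-1 special case
#' nested in the Gamma family, exponential-like data is reported through the
#' Gamma fit with shape near 1 (the Gamma log-likelihood is never below the
#' exponential's); the per-family log-likelihoods are all returned. The
#' Gamma parameters and their 95% CIs are always reported.
#'
#' @param x positive values (MMS spike values or derived positive
#'   quantities).
#' @param minN minimum sample size for an accepted fit (default 100).
#' @return list with \code{family} (selected), \code{logLik} (named vector),
#'   \code{gamma} (the [fitGamma()] result), \code{params} (per-family
#'   parameter lists), \code{n}.
#' @export
fitCandidates <- function(x, minN = 100) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < minN)
    stop(sprintf("insufficient peaks: %d < %d required", n, minN))
  if (any(x <= 0)) stop("values must be positive")
  params <- list()
  ll <- setNames(rep(NA_real_, length(.candidateFamilies)),
                 .candidateFamilies)
  g <- fitGamma(x)
  params$gamma <- g[c("shape", "scale")]
  ll["gamma"] <- g$logLik
  rate <- 1 / mean(x)
  params$exponential <- list(rate = rate)
  ll["exponential"] <- sum(dexp(x, rate, log = TRUE))
  ml <- mean(log(x)); sl <- sqrt(mean((log(x) - ml)^2))
  params$lognormal <- list(meanlog = ml, sdlog = sl)
  ll["lognormal"] <- sum(dlnorm(x, ml, sl, log = TRUE))
  mu <- mean(x); sdv <- sqrt(mean((x - mu)^2))
  params$normal <- list(mean = mu, sd = sdv)
  ll["normal"] <- sum(dnorm(x, mu, sdv, log = TRUE))
  w <- tryCatch(
    fitdistrplus::fitdist(x, "weibull"),
    error = function(e) NULL)
  if (!is.null(w)) {
    params$weibull <- as.list(w$estimate)
    ll["weibull"] <- w$loglik
  }
  best <- names(which.max(ll))
  list(family = best, logLik = ll, gamma = g, params = params, n = n)
}

#' Windowed Gamma fits of an MMS train
#'
#' Slides a window plan over an [MMSTrain-class] and fits the Gamma family
#' by MLE to the spike values inside each window. Windows with fewer than
#' \code{minPeaks} spikes are skipped and flagged.
#'
#' @param train an [MMSTrain-class].
#' @param plan window plan from [planWindows()] in the train's sample
#'   coordinates.
#' @param minPeaks minimum spikes per accepted window (default 100).
#' @return data.frame with one row per window: \code{window}, \code{start},
#'   \code{end}, \code{n}, \code{accepted}, \code{shape}, \code{shapeLo},
#'   \code{shapeHi}, \code{scale}, \code{scaleLo}, \code{scaleHi},
#'   \code{mean}, \code{variance}, \code{logLik}.
#' @export
windowedGammaFits <- function(train, plan, minPeaks = 100) {
  stopifnot(is(train, "MMSTrain"))
  out <- data.frame(window = plan$window, start = plan$start, end = plan$end,
                    n = NA_integer_, accepted = FALSE, shape = NA_real_,
                    shapeLo = NA_real_, shapeHi = NA_real_, scale = NA_real_,
                    scaleLo = NA_real_, scaleHi = NA_real_, mean = NA_real_,
                    variance = NA_real_, logLik = NA_real_)
  for (w in seq_len(nrow(plan))) {
    inWin <- train@times > plan$start[w] & train@times <= plan$end[w]
    v <- train@values[inWin]
    out$n[w] <- length(v)
    if (length(v) < minPeaks) next
    f <- tryCatch(fitGamma(v), error = function(e) NULL)
    if (is.null(f)) next
    out$accepted[w] <- TRUE
    out$shape[w] <- f$shape; out$shapeLo[w] <- f$shapeCI[1]
    out$shapeHi[w] <- f$shapeCI[2]
    out$scale[w] <- f$scale; out$scaleLo[w] <- f$scaleCI[1]
    out$scaleHi[w] <- f$scaleCI[2]
    out$mean[w] <- f$mean; out$variance[w] <- f$variance
    out$logLik[w] <- f$logLik
  }
  out
}

#' Quadrant labels on the log-log Gamma parameter plane
#'
#' Splits fits into the four quadrants spanned by the median log-shape and
#' median log-scale. Strictly greater than the median assigns right (shape)
#' or upper (scale); points exactly on a median line fall left/lower. RLQ
#' (high shape, low scale) marks Gaussian-like low-NSR windows, LUQ (low
#' shape, high scale) exponential-like high-NSR windows.
#'
#' @param shape,scale positive parameter vectors (equal length >= 2), e.g.
#'   the accepted rows of [windowedGammaFits()].
#' @return data.frame with \code{quadrant} (factor LUQ/RUQ/LLQ/RLQ) plus the
#'   \code{medianLogShape} and \code{medianLogScale} used, as attributes.
#' @export
quadrantSplit <- function(shape, scale) {
  if (length(shape) != length(scale)) stop("shape and scale lengths differ")
  if (length(shape) < 2) stop("need at least 2 fits to span quadrants")
  if (any(shape <= 0) || any(scale <= 0)) stop("parameters must be positive")
  mLogA <- median(log(shape))
  mLogB <- median(log(scale))
  right <- log(shape) > mLogA
  upper <- log(scale) > mLogB
  q <- ifelse(right & upper, "RUQ",
              ifelse(right & !upper, "RLQ",
                     ifelse(!right & upper, "LUQ", "LLQ")))
  structure(
    data.frame(quadrant = factor(q, levels = c("LUQ", "RUQ", "LLQ", "RLQ"))),
    medianLogShape = mLogA, medianLogScale = mLogB)
}

#' Per-block summary of windowed Gamma fits
#'
#' For each block: median shape and scale, mean and variance of the shape
#' values, and the SNR of the block's shape distribution (mean/variance; a
#' zero-variance block is flagged with infinite SNR).
#'
#' @param fits data.frame with columns \code{block}, \code{shape},
#'   \code{scale} and logical \code{accepted} (as produced by the pipeline);
#'   only accepted rows are used.
#' @return data.frame with one row per block: \code{block}, \code{nWindows},
#'   \code{medianShape}, \code{medianScale}, \code{meanShape},
#'   \code{varShape}, \code{snrShape}, \code{degenerate}.
#' @export
blockSummary <- function(fits) {
  need <- c("block", "shape", "scale")
  if (!all(need %in% names(fits))) stop("fits need columns block, shape, scale")
  if ("accepted" %in% names(fits)) fits <- fits[fits$accepted, , drop = FALSE]
  blocks <- sort(unique(fits$block))
  rows <- lapply(blocks, function(b) {
    f <- fits[fits$block == b, , drop = FALSE]
    if (nrow(f) < 2) {
      warning(sprintf("block %s has < 2 accepted fits: flagged gap", b))
      return(data.frame(block = b, nWindows = nrow(f), medianShape = NA_real_,
                        medianScale = NA_real_, meanShape = NA_real_,
                        varShape = NA_real_, snrShape = NA_real_,
                        degenerate = TRUE))
    }
    ms <- mean(f$shape); vs <- var(f$shape)
    data.frame(block = b, nWindows = nrow(f),
               medianShape = median(f$shape), medianScale = median(f$scale),
               meanShape = ms, varShape = vs,
               snrShape = if (vs > 0) ms / vs else Inf,
               degenerate = vs <= 0)
  })
  do.call(rbind, rows)
}
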