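## Recording I/O and the canonical sliding-window machinery.
##
## Window conventions: half-open, 0-based sample intervals [start, end).
## Trailing samples that do not fill a whole window are dropped, because the
## downstream distribution fits require full windows of spikes.

#' Plan sliding windows over a sampled signal
#'
#' Computes the half-open, 0-based sample intervals of a sliding window of
#' \code{windowS} seconds with the given overlap fraction. Consecutive
#' windows share exactly \code{overlap * window} samples; a trailing partial
#' window is dropped.
#'
#' @param nSamples total number of samples.
#' @param rate sampling rate (Hz).
#' @param windowS window length in seconds (default 5).
#' @param overlap overlap fraction in [0, 1) (default 0.5).
#' @return data.frame with columns \code{window} (1-based index),
#'   \code{start}, \code{end} (0-based, half-open), and attributes
#'   \code{windowSamples} and \code{stride}.
#' @examples
#' planWindows(2560, 256, 5, 0.5)  # three windows of 1280 samples, stride 640
#' @export
planWindows <- function(nSamples, rate, windowS = 5, overlap = 0.5) {
  stopifnot(length(nSamples) == 1, length(rate) == 1, rate > 0)
  if (overlap < 0 || overlap >= 1)
    stop("overlap must lie in [0, 1)")
  w <- as.integer(round(windowS * rate))
  if (w < 2) stop("window must span at least 2 samples")
  if (nSamples < w)
    stop(sprintf("signal of %d samples is shorter than one %d-sample window",
                 nSamples, w))
  stride <- as.integer(round((1 - overlap) * w))
  if (stride < 1) stop("overlap too large: stride below one sample")
  starts <- seq.int(0L, nSamples - w, by = stride)
  plan <- data.frame(window = seq_along(starts), start = starts,
                     end = starts + w)
  attr(plan, "windowSamples") <- w
  attr(plan, "stride") <- stride
  plan
}

#' Write a window plan as a BED-like 3-column TSV
#'
#' @param plan a window plan from [planWindows()].
#' @param path output path.
#' @param name interval name stem (default "window").
#' @return invisibly, the path.
#' @export
writeWindowPlan <- function(plan, path, name = "window") {
  df <- data.frame(paste0(name, plan$window), plan$start, plan$end)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a recording from EDF, BDF or CSV
#'
#' EDF (16-bit) and BDF (24-bit) continuous recordings are parsed from their
#' standard fixed-layout headers; CSV matrices must start with a
#' \code{# rate_hz=<rate>} comment line, followed by a header row of channel
#' labels and one row per sample.
#'
#' @param path file path.
#' @param format one of \code{"auto"}, \code{"edf"}, \code{"bdf"},
#'   \code{"csv"}; \code{"auto"} dispatches on the file extension.
#' @return An [EEGRecording-class].
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, format = c("auto", "edf", "bdf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", bdf = "bdf", csv = "csv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  switch(format,
         csv = .readRecordingCsv(path),
         edf = .readRecordingEdf(path, bits = 16L),
         bdf = .readRecordingEdf(path, bits = 24L))
}

#' Write a recording to EDF, BDF or CSV
#'
#' @param rec an [EEGRecording-class].
#' @param path output path.
#' @param format as in [readRecording()].
#' @param recordS data-record duration in seconds for EDF/BDF (default 1).
#' @return invisibly, the path.
#' @export
writeRecording <- function(rec, path, format = c("auto", "edf", "bdf", "csv"),
                           recordS = 1) {
  stopifnot(is(rec, "EEGRecording"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", bdf = "bdf", csv = "csv",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  switch(format,
         csv = .writeRecordingCsv(rec, path),
         edf = .writeRecordingEdf(rec, path, bits = 16L, recordS = recordS),
         bdf = .writeRecordingEdf(rec, path, bits = 24L, recordS = recordS))
  invisible(path)
}

.readRecordingCsv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*rate_hz\\s*=\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2)
    stop("CSV recording must start with a '# rate_hz=<rate>' header line: ",
         path)
  rate <- as.numeric(m[2])
  df <- read.table(path, sep = ",", header = TRUE, skip = 1L,
                   check.names = FALSE)
  EEGRecording(t(as.matrix(df)), samplingRate = rate,
               channelLabels = colnames(df))
}

.writeRecordingCsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.10g", rec@samplingRate), con)
  df <- as.data.frame(t(rec@samples))
  names(df) <- rec@channelLabels
  write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
}

## EDF/BDF fixed-layout header: 256 bytes global + 256 per channel.
## EDF stores 16-bit little-endian two's-complement integers; BDF 24-bit.

.padField <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

.writeRecordingEdf <- function(rec, path, bits, recordS) {
  x <- rec@samples
  nc <- nrow(x)
  rate <- rec@samplingRate
  spr <- as.integer(round(rate * recordS))
  if (abs(spr - rate * recordS) > 1e-9)
    stop("recordS * rate must be an integer number of samples")
  nrec <- ncol(x) %/% spr
  if (nrec < 1) stop("recording shorter than one data record")
  used <- nrec * spr
  if (used < ncol(x))
    warning(sprintf("dropping %d trailing samples not filling a data record",
                    ncol(x) - used))
  x <- x[, seq_len(used), drop = FALSE]
  digMax <- if (bits == 16L) 32767 else 8388607
  digMin <- -digMax - 1
  ## physical bounds must survive the 8-character header fields exactly, so
  ## quantization uses the parsed-back header values
  fmt8 <- function(v) {
    vapply(v, function(vi) {
      for (d in 6:1) {
        s <- formatC(vi, format = "g", digits = d)
        if (nchar(s) <= 8) return(s)
      }
      stop("physical bound does not fit the 8-character header field")
    }, "")
  }
  physMin <- apply(x, 1, min)
  physMax <- apply(x, 1, max)
  flat <- physMax - physMin < .Machine$double.eps
  physMax[flat] <- physMin[flat] + 1
  margin <- 0.002 * (abs(physMin) + abs(physMax) + (physMax - physMin))
  physMinS <- fmt8(physMin - margin)
  physMaxS <- fmt8(physMax + margin)
  physMin <- as.numeric(physMinS)
  physMax <- as.numeric(physMaxS)
  stopifnot(all(physMin <= apply(x, 1, min)),
            all(physMax >= apply(x, 1, max)))
  con <- file(path, "wb")
  on.exit(close(con))
  wch <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  if (bits == 16L) {
    wch(.padField("0", 8L))
  } else {
    writeBin(as.raw(255L), con)            # BDF magic: 0xFF "BIOSEMI"
    wch(.padField("BIOSEMI", 7L))
  }
  wch(.padField("", 80L))                       # patient id
  wch(.padField("", 80L))                       # recording id
  wch(.padField("01.01.00", 8L))                # start date
  wch(.padField("00.00.00", 8L))                # start time
  wch(.padField(256L * (nc + 1L), 8L))          # header bytes
  wch(.padField(if (bits == 16L) "" else "24BIT", 44L))
  wch(.padField(nrec, 8L))
  wch(.padField(format(recordS, digits = 8), 8L))
  wch(.padField(nc, 4L))
  for (lab in rec@channelLabels) wch(.padField(lab, 16L))
  for (i in seq_len(nc)) wch(.padField("", 80L))          # transducer
  for (i in seq_len(nc)) wch(.padField("uV", 8L))         # physical dim
  for (i in seq_len(nc)) wch(.padField(physMinS[i], 8L))
  for (i in seq_len(nc)) wch(.padField(physMaxS[i], 8L))
  for (i in seq_len(nc)) wch(.padField(digMin, 8L))
  for (i in seq_len(nc)) wch(.padField(digMax, 8L))
  for (i in seq_len(nc)) wch(.padField("", 80L))          # prefiltering
  for (i in seq_len(nc)) wch(.padField(spr, 8L))
  for (i in seq_len(nc)) wch(.padField("", 32L))          # reserved
  gain <- (digMax - digMin) / (physMax - physMin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(nc)) {
      d <- round((x[i, idx] - physMin[i]) * gain[i]) + digMin
      d <- pmin(pmax(d, digMin), digMax)
      if (bits == 16L) {
        writeBin(as.integer(d), con, size = 2L, endian = "little")
      } else {
        d <- as.integer(d)
        neg <- d < 0
        u <- ifelse(neg, d + 16777216, d)      # 24-bit two's complement
        b0 <- u %% 256L; u <- u %/% 256L
        b1 <- u %% 256L; b2 <- u %/% 256L
        writeBin(as.raw(rbind(b0, b1, b2)), con)
      }
    }
  }
  invisible(path)
}

.readRecordingEdf <- function(path, bits) {
  con <- file(path, "rb")
  on.exit(close(con))
  rawHdr <- readBin(con, "raw", 256L)
  hdr <- rawToChar(rawHdr[9:256])               # skip version (may be 0xFF)
  fld <- function(txt, off, w) trimws(substr(txt, off, off + w - 1L))
  nHeaderBytes <- as.integer(fld(hdr, 177L, 8L))
  nrec <- as.integer(fld(hdr, 229L, 8L))
  recordS <- as.numeric(fld(hdr, 237L, 8L))
  nc <- as.integer(fld(hdr, 245L, 4L))
  if (is.na(nc) || nc < 1)
    stop("malformed EDF/BDF header (channel count field): ", path)
  chHdr <- rawToChar(readBin(con, "raw", 256L * nc))
  block <- function(off, w) {
    vapply(seq_len(nc), function(i)
      trimws(substr(chHdr, off + (i - 1L) * w, off + i * w - 1L)), "")
  }
  pos <- 1L
  labels <- block(pos, 16L); pos <- pos + 16L * nc
  pos <- pos + 80L * nc                          # transducer
  pos <- pos + 8L * nc                           # physical dim
  physMin <- as.numeric(block(pos, 8L)); pos <- pos + 8L * nc
  physMax <- as.numeric(block(pos, 8L)); pos <- pos + 8L * nc
  digMin <- as.numeric(block(pos, 8L)); pos <- pos + 8L * nc
  digMax <- as.numeric(block(pos, 8L)); pos <- pos + 8L * nc
  pos <- pos + 80L * nc                          # prefiltering
  spr <- as.integer(block(pos, 8L))
  if (anyNA(c(physMin, physMax, digMin, digMax, spr)))
    stop("malformed EDF/BDF channel header: ", path)
  if (length(unique(spr)) != 1L)
    stop("channels with differing samples-per-record are not supported: ", path)
  spr <- spr[1]
  seek(con, nHeaderBytes)
  x <- matrix(0, nrow = nc, ncol = nrec * spr)
  gain <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    for (i in seq_len(nc)) {
      if (bits == 16L) {
        d <- readBin(con, "integer", spr, size = 2L, signed = TRUE,
                     endian = "little")
      } else {
        b <- as.integer(readBin(con, "raw", 3L * spr))
        u <- b[c(TRUE, FALSE, FALSE)] + 256L * b[c(FALSE, TRUE, FALSE)] +
          65536L * b[c(FALSE, FALSE, TRUE)]
        d <- ifelse(u >= 8388608, u - 16777216, u)
      }
      if (length(d) != spr)
        stop(sprintf("truncated data record %d, channel %d in %s", r, i, path))
      x[i, ((r - 1L) * spr + 1L):(r * spr)] <-
        physMin[i] + (d - digMin[i]) * gain[i]
    }
  }
  EEGRecording(x, samplingRate = spr / recordS, channelLabels = labels)
}
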