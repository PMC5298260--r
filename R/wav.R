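#' @include AllClasses.R
NULL

# RIFF/WAVE reader-writer for the two dialects the pipeline accepts:
# 16-bit integer PCM (format tag 1) and 32-bit IEEE float (format tag 3).
# Samples are normalised to [-1, 1] doubles internally; PCM16 values are
# scaled by 1/32767 so that a write/read cycle is an exact fixed-point
# round trip.

.wav_read_header <- function(con, path) {
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF file: ", path, " (byte offset 0)")
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a WAVE file: ", path, " (byte offset 8)")
  fmt <- NULL
  repeat {
    at <- seek(con)
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L)
      stop("truncated WAV file: ", path, " (byte offset ", at, ")")
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        tag      = readBin(con, "integer", 1L, size = 2L, endian = "little"),
        channels = readBin(con, "integer", 1L, size = 2L, endian = "little"),
        rate     = readBin(con, "integer", 1L, size = 4L, endian = "little"))
      readBin(con, "integer", 1L, size = 4L, endian = "little") # byte rate
      readBin(con, "integer", 1L, size = 2L, endian = "little") # block align
      fmt$bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (sz > 16L) readBin(con, "raw", sz - 16L)
    } else if (identical(id, "data")) {
      if (is.null(fmt))
        stop("malformed WAV (data before fmt): ", path,
             " (byte offset ", at, ")")
      fmt$dataOffset <- seek(con)
      fmt$dataSize <- sz
      return(fmt)
    } else {
      if (sz %% 2L == 1L) sz <- sz + 1L # chunks are word-aligned
      seek(con, where = sz, origin = "current")
    }
  }
}

#' Read a WAV recording
#'
#' Reads a 16-bit PCM or 32-bit float WAV file into a
#' \linkS4class{Recording}, normalising samples to [-1, 1] doubles. The
#' absolute start time is parsed from the file name with
#' \code{filenameTimeFormat} (a \code{\link{strptime}} format applied to the
#' base name without extension); when the name does not parse, the start
#' epoch is 0.
#'
#' @param path WAV file path.
#' @param channels channel selection: indices or names drawn from
#'   \code{channelNames}; NULL keeps all channels.
#' @param from,to 1-based sample range to read (bounded-memory partial
#'   reads); NULL reads everything.
#' @param channelNames labels to attach; defaults to "ch1", "ch2", ...
#' @param filenameTimeFormat strptime format for the start time encoded in
#'   the file name (config key \code{filename_time_format}).
#' @param tz local timezone carried on the Recording.
#' @return a \linkS4class{Recording}.
#' @export
readRecording <- function(path, channels = NULL, from = 1L, to = NULL,
                          channelNames = NULL,
                          filenameTimeFormat = "%Y-%m-%d_%H-%M-%S",
                          tz = "UTC") {
  con <- file(path, "rb")
  on.exit(close(con))
  fmt <- .wav_read_header(con, path)
  if (!fmt$tag %in% c(1L, 3L))
    stop("unsupported WAV format tag ", fmt$tag, " (only PCM16 and float32)")
  bytes <- fmt$bits %/% 8L
  nTotal <- fmt$dataSize %/% (bytes * fmt$channels)
  avail <- file.size(path) - fmt$dataOffset
  if (fmt$dataSize > avail)
    stop("truncated WAV file: ", path, " (data chunk claims ", fmt$dataSize,
         " bytes, only ", avail, " present after byte offset ",
         fmt$dataOffset, ")")
  if (is.null(to)) to <- nTotal
  to <- min(to, nTotal)
  if (from > 1L)
    seek(con, where = (from - 1L) * bytes * fmt$channels, origin = "current")
  n <- to - from + 1L
  if (n <= 0L) stop("empty sample range requested")
  if (fmt$tag == 1L) {
    if (fmt$bits != 16L) stop("PCM WAV must be 16-bit (got ", fmt$bits, ")")
    raw <- readBin(con, "integer", n * fmt$channels, size = 2L,
                   signed = TRUE, endian = "little")
    x <- raw / 32767
  } else {
    if (fmt$bits != 32L) stop("float WAV must be 32-bit (got ", fmt$bits, ")")
    x <- readBin(con, "double", n * fmt$channels, size = 4L,
                 endian = "little")
  }
  if (length(x) < n * fmt$channels)
    stop("truncated WAV file: ", path, " (byte offset ",
         fmt$dataOffset + length(x) * bytes, ")")
  m <- matrix(x, ncol = fmt$channels, byrow = TRUE)
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(fmt$channels))
  if (!is.null(channels)) {
    idx <- if (is.character(channels)) match(channels, channelNames)
           else as.integer(channels)
    if (anyNA(idx) || any(idx < 1L | idx > fmt$channels))
      stop("requested channel absent: ",
           paste(channels[is.na(idx) | idx < 1 | idx > fmt$channels],
                 collapse = ", "))
    m <- m[, idx, drop = FALSE]
    channelNames <- channelNames[idx]
  }
  base <- sub("\\.[^.]*$", "", basename(path))
  t0 <- as.POSIXct(base, format = filenameTimeFormat, tz = tz)
  epoch <- if (!is.na(t0)) as.numeric(t0) else 0
  epoch <- epoch + (from - 1L) / fmt$rate
  Recording(m, fmt$rate, channelNames, startEpoch = epoch, tz = tz)
}

#' Write a Recording as WAV
#'
#' @param rec a \linkS4class{Recording}.
#' @param path output file.
#' @param format "float32" (lossless for single-precision values) or
#'   "pcm16" (samples quantised to 1/32767 steps).
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  x <- t(rec@samples) # interleave channels
  nch <- ncol(rec@samples)
  n <- length(x)
  bytes <- if (format == "pcm16") 2L else 4L
  dataSize <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(if (format == "pcm16") 1L else 3L, con, size = 2L,
           endian = "little")
  writeBin(nch, con, size = 2L, endian = "little")
  writeBin(as.integer(rec@rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rec@rate) * nch * bytes, con, size = 4L,
           endian = "little")
  writeBin(nch * bytes, con, size = 2L, endian = "little")
  writeBin(8L * bytes, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4L, endian = "little")
  if (format == "pcm16") {
    v <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(v, con, size = 2L, endian = "little")
  } else {
    writeBin(as.vector(x), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Split a recording into overlapping chunks
#'
#' Yields consecutive segments of \code{chunkS} seconds whose starts advance
#' by \code{chunkS - overlapS}, so consecutive segments overlap by exactly
#' \code{overlapS}; every sample belongs to at least one segment. A chunk
#' longer than the recording yields a single segment. This is the package's
#' bounded-memory contract for hour-long files: pass a path and chunks are
#' read one at a time.
#'
#' @param x a \linkS4class{Recording} or a WAV path.
#' @param chunkS chunk length, seconds (default 300).
#' @param overlapS overlap between consecutive chunks, seconds (default 2).
#' @param FUN optional function applied to each chunk in order; when given,
#'   a list of its results is returned instead of the chunks themselves
#'   (keeps only one chunk in memory at a time for path input).
#' @param ... passed to \code{\link{readRecording}} for path input.
#' @return list of \linkS4class{Recording} segments (or of FUN results),
#'   with strictly increasing start epochs.
#' @export
streamChunks <- function(x, chunkS = 300, overlapS = 2, FUN = NULL, ...) {
  stopifnot(chunkS > overlapS, overlapS >= 0)
  if (is.character(x)) {
    probe <- readRecording(x, from = 1L, to = 1L, ...)
    rate <- probe@rate
    con <- file(x, "rb")
    hdr <- .wav_read_header(con, x)
    close(con)
    nTotal <- hdr$dataSize %/% ((hdr$bits %/% 8L) * hdr$channels)
    getter <- function(a, b) readRecording(x, from = a, to = b, ...)
    epoch0 <- probe@startEpoch
    tz <- probe@tz
  } else {
    rate <- x@rate
    nTotal <- nrow(x@samples)
    getter <- function(a, b)
      Recording(x@samples[a:b, , drop = FALSE], rate, x@channelNames,
                startEpoch = x@startEpoch + (a - 1L) / rate, tz = x@tz)
    epoch0 <- x@startEpoch
    tz <- x@tz
  }
  step <- round((chunkS - overlapS) * rate)
  len <- round(chunkS * rate)
  starts <- seq(1L, max(nTotal - round(overlapS * rate), 0L) + 1L, by = step)
  starts <- starts[starts <= nTotal]
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    a <- starts[i]
    b <- min(a + len - 1L, nTotal)
    seg <- getter(a, b)
    out[[i]] <- if (is.null(FUN)) seg else FUN(seg)
  }
  out
}
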