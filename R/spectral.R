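#' @include AllClasses.R
NULL

# Hann-windowed frames, processed in blocks of <= blockFrames columns so a
# one-hour channel never materialises the full frame matrix.
.stft_mag <- function(x, n, hop, blockFrames = 4096L) {
  starts <- seq(1L, length(x) - n + 1L, by = hop)
  w <- signal::hanning(n)
  nb <- n %/% 2L + 1L
  mag <- matrix(0, nb, length(starts))
  scale <- 2 / sum(w)
  for (b in seq(1L, length(starts), by = blockFrames)) {
    idx <- b:min(b + blockFrames - 1L, length(starts))
    fr <- matrix(x[outer(0:(n - 1L), starts[idx], `+`)], nrow = n) * w
    mag[, idx] <- abs(stats::mvfft(fr)[1:nb, , drop = FALSE]) * scale
  }
  list(mag = mag, starts = starts)
}

#' Log-magnitude spectrogram of one channel
#'
#' Short-time Fourier transform with a Hann window; magnitudes are floored
#' at \code{epsilon} (relative to full scale) before taking 20*log10, and
#' the frequency axis is cropped to \code{band}. Frame times are window
#' centres relative to the recording start.
#'
#' Defaults (window 512 samples ~ 23 ms at 22050 Hz, hop 128 samples
#' ~ 5.8 ms) resolve ~43 Hz bins and ~6 ms frames: adequate for 50-200 ms
#' pulses with a 200-500 Hz fundamental and two upper harmonics.
#'
#' @param rec a \linkS4class{Recording}.
#' @param channel channel index or name.
#' @param windowS,hopS STFT window and hop in seconds; NULL uses 512 and 128
#'   samples at the recording's rate.
#' @param band analysis band (f_lo, f_hi) in Hz, default c(100, 1500).
#' @param epsilon magnitude floor relative to full scale (default 1e-10,
#'   i.e. a -200 dB floor).
#' @return a \linkS4class{Spectrogram}.
#' @export
stftLogSpectrogram <- function(rec, channel = 1L, windowS = NULL,
                               hopS = NULL, band = c(100, 1500),
                               epsilon = 1e-10) {
  rate <- rec@rate
  if (is.character(channel)) channel <- match(channel, rec@channelNames)
  x <- rec@samples[, channel]
  n <- if (is.null(windowS)) 512L else round(windowS * rate)
  hop <- if (is.null(hopS)) 128L else round(hopS * rate)
  stopifnot(hop >= 1L, hop <= n)
  if (length(x) < n)
    stop("recording shorter than one STFT window (", length(x), " < ", n,
         " samples)")
  if (!(band[1] >= 0 && band[1] < band[2] && band[2] <= rate / 2))
    stop("band must satisfy 0 <= f_lo < f_hi <= rate/2")
  st <- .stft_mag(x, n, hop)
  freqs <- (0:(n %/% 2L)) * rate / n
  keep <- freqs >= band[1] & freqs <= band[2]
  vals <- 20 * log10(pmax(st$mag[keep, , drop = FALSE], epsilon))
  new("Spectrogram", values = vals, freqs = freqs[keep],
      times = (st$starts - 1 + (n - 1) / 2) / rate,
      windowS = n / rate, hopS = hop / rate)
}

#' Remove the stationary colony-hum background
#'
#' Subtracts, per frequency bin, a rolling median over time in the log
#' domain and clips the result below at 0 dB. The rolling median is robust
#' to sparse transient pulses, so stationary narrowband components -- in
#' particular the ~125 Hz colony hum that would otherwise dominate averaged
#' spectra -- are suppressed while brief pulses pass through.
#'
#' @param spec a \linkS4class{Spectrogram}.
#' @param rollingWindowS rolling-median window in seconds (default 60; must
#'   be much longer than the longest pulse, and at least 10 frames).
#' @return background-subtracted \linkS4class{Spectrogram}.
#' @export
subtractBackground <- function(spec, rollingWindowS = 60) {
  nf <- ncol(spec@values)
  k <- round(rollingWindowS / spec@hopS)
  if (k < 10L)
    stop("background window spans ", k, " frames; at least 10 required")
  if (k > nf) k <- nf
  if (k %% 2L == 0L) k <- k - 1L
  v <- spec@values
  if (k >= 3L) {
    # endrule "constant": frames closer than half a window to the file edge
    # reuse the nearest full-window median (cheap, and robust there too)
    bg <- t(apply(v, 1L, stats::runmed, k = k, endrule = "constant"))
  } else {
    bg <- v
  }
  new("Spectrogram", values = pmax(v - bg, 0), freqs = spec@freqs,
      times = spec@times, windowS = spec@windowS, hopS = spec@hopS)
}
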