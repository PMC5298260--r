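#' @include AllClasses.R
NULL

# analytic-signal envelope via FFT (positive-frequency doubling)
.envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

.bandpass <- function(x, rate, band, order = 4L) {
  ny <- rate / 2
  bf <- signal::butter(order, c(max(band[1], 1) / ny, min(band[2], ny * 0.99) / ny),
                       type = "pass")
  signal::filtfilt(bf, x)
}

.moving_avg <- function(x, k) {
  if (k <= 1L) return(x)
  kern <- rep(1 / k, k)
  y <- stats::filter(x, kern, sides = 2)
  y <- as.numeric(y)
  # extend edge values over the half-window the centred filter cannot reach
  first <- which(!is.na(y))[1]
  last <- max(which(!is.na(y)))
  y[seq_len(first - 1)] <- y[first]
  y[seq(last + 1, length.out = length(y) - last)] <- y[last]
  y
}

#' Estimate the fundamental frequency of a pulse
#'
#' Magnitude-spectrum peak within the search band, refined by parabolic
#' interpolation over three bins of the zero-padded, Hann-windowed
#' spectrum. The band default (150-600 Hz) brackets the 300-450 Hz range
#' where most whooping fundamentals fall, with margin, and keeps the search
#' off the stronger harmonics.
#'
#' @param x waveform segment (>= 30 ms).
#' @param rate samples/s.
#' @param searchBand c(f_lo, f_hi) Hz, default c(150, 600).
#' @param minPeakDb required peak prominence over the in-band median
#'   (default 12 dB); below it the estimate is flagged and f0 is NA. The
#'   default is set against the noise-only null: the maximum of a few
#'   hundred effectively independent Rayleigh-distributed magnitude bins
#'   sits about 9 dB above their median, so a tonal peak must clear that
#'   by a margin before a frequency is reported.
#' @return list(f0 = Hz or NA, flagged = logical).
#' @export
estimateFundamental <- function(x, rate, searchBand = c(150, 600),
                                minPeakDb = 12) {
  if (length(x) < 0.03 * rate)
    stop("segment shorter than 30 ms")
  w <- signal::hanning(length(x))
  nfft <- 2^ceiling(log2(length(x) * 4))
  mag <- Mod(stats::fft(c(x * w, numeric(nfft - length(x)))))[1:(nfft / 2 + 1)]
  freqs <- (0:(nfft / 2)) * rate / nfft
  inband <- which(freqs >= searchBand[1] & freqs <= searchBand[2])
  pk <- inband[which.max(mag[inband])]
  peakDb <- 20 * log10(mag[pk] + 1e-300)
  floorDb <- 20 * log10(stats::median(mag[inband]) + 1e-300)
  if (peakDb - floorDb < minPeakDb)
    return(list(f0 = NA_real_, flagged = TRUE))
  # parabolic refinement on log magnitude
  if (pk > 1 && pk < length(mag)) {
    lm <- log(mag[(pk - 1):(pk + 1)] + 1e-300)
    den <- lm[1] - 2 * lm[2] + lm[3]
    delta <- if (den != 0) 0.5 * (lm[1] - lm[3]) / den else 0
    delta <- max(min(delta, 0.5), -0.5)
  } else delta <- 0
  list(f0 = (pk - 1 + delta) * rate / nfft, flagged = FALSE)
}

#' Measure pulse duration
#'
#' Envelope of the band-passed analytic signal, smoothed over 20 ms; the
#' duration is the span over which the envelope stays within 10 dB of its
#' peak, walking outward from the envelope maximum nearest the segment
#' centre (so a flanking second burst in the segment is not included).
#'
#' @param x waveform segment with the pulse centred by the detector.
#' @param rate samples/s.
#' @param band band-pass edges, Hz (default c(150, 1500)).
#' @param dropDb envelope drop defining the pulse edges (default 10 dB).
#' @param smoothS envelope smoothing window (default 0.02 s).
#' @return list(duration = s or NA, flagged = logical).
#' @export
measureDuration <- function(x, rate, band = c(150, 1500), dropDb = 10,
                            smoothS = 0.02) {
  xf <- .bandpass(x, rate, band)
  env <- .moving_avg(.envelope(xf), round(smoothS * rate))
  n <- length(env)
  mid <- seq(max(1, floor(n / 3)), ceiling(2 * n / 3))
  pk <- mid[which.max(env[mid])]
  if (env[pk] < 2 * stats::median(env))
    return(list(duration = NA_real_, flagged = TRUE))
  thr <- env[pk] * 10^(-dropDb / 20)
  lo <- pk
  while (lo > 1 && env[lo - 1] >= thr) lo <- lo - 1
  hi <- pk
  while (hi < n && env[hi + 1] >= thr) hi <- hi + 1
  list(duration = (hi - lo) / rate, flagged = FALSE)
}

#' Harmonic amplitude profile at f0, 2 f0, 3 f0
#'
#' Hann-windowed magnitude spectrum integrated over +/- 1 bin around each
#' harmonic, reported in arbitrary amplitude units (linear in the input
#' gain).
#'
#' @param x waveform segment.
#' @param rate samples/s.
#' @param f0 fundamental frequency, Hz; requires 3 f0 < rate / 2.
#' @return numeric length-3 vector (h1, h2, h3), a.u.
#' @export
harmonicProfile <- function(x, rate, f0) {
  stopifnot(is.finite(f0), f0 > 0)
  if (3 * f0 >= rate / 2)
    stop("3*f0 must lie below the Nyquist frequency")
  w <- signal::hanning(length(x))
  # normalise so the +/- 1 bin sum of an exact-bin sine of amplitude A
  # reads A: the Hann response puts sum(w)/2 in the peak bin and
  # sum(w)/4 in each neighbour, totalling sum(w)
  mag <- Mod(stats::fft(x * w))[1:(floor(length(x) / 2) + 1)] / sum(w)
  df <- rate / length(x)
  vapply(1:3, function(k) {
    b <- round(k * f0 / df) + 1
    sum(mag[max(b - 1, 1):min(b + 1, length(mag))])
  }, numeric(1))
}

#' Characterise detected pulses
#'
#' For each event, slices a segment around the event time from the
#' recording and measures fundamental frequency, duration, peak amplitude
#' (peak absolute value of the band-passed segment, a.u.; multiplied by
#' \code{gain} when an absolute calibration in mm/s^2 per count is known)
#' and the harmonic profile.
#'
#' @param rec the \linkS4class{Recording} the events came from.
#' @param events data.frame with \code{time} (absolute s) and \code{channel}
#'   columns, or a \linkS4class{CandidateSet}.
#' @param segmentS segment length around each event (default 0.3 s).
#' @param searchBand f0 search band, Hz.
#' @param band band-pass for duration/amplitude, Hz.
#' @param gain amplitude calibration factor (default 1, arbitrary units).
#' @return data.frame: time, channel, f0_hz, duration_s, amplitude,
#'   h1, h2, h3, flagged.
#' @export
characterizePulses <- function(rec, events, segmentS = 0.3,
                               searchBand = c(150, 600),
                               band = c(150, 1500), gain = 1) {
  if (is(events, "CandidateSet")) events <- events@events
  n <- nrow(events)
  out <- data.frame(time = events$time, channel = events$channel,
                    f0_hz = rep(NA_real_, n), duration_s = rep(NA_real_, n),
                    amplitude = rep(NA_real_, n), h1 = rep(NA_real_, n),
                    h2 = rep(NA_real_, n), h3 = rep(NA_real_, n),
                    flagged = rep(FALSE, n), stringsAsFactors = FALSE)
  if (!n) return(out)
  half <- round(segmentS / 2 * rec@rate)
  for (i in seq_len(n)) {
    ci <- match(events$channel[i], rec@channelNames)
    c0 <- round((events$time[i] - rec@startEpoch) * rec@rate) + 1L
    a <- max(1L, c0 - half)
    b <- min(nrow(rec@samples), c0 + half)
    seg <- rec@samples[a:b, ci]
    f0r <- estimateFundamental(seg, rec@rate, searchBand)
    dur <- measureDuration(seg, rec@rate, band)
    out$f0_hz[i] <- f0r$f0
    out$duration_s[i] <- dur$duration
    out$amplitude[i] <- max(abs(.bandpass(seg, rec@rate, band))) * gain
    if (!f0r$flagged && 3 * f0r$f0 < rec@rate / 2) {
      h <- harmonicProfile(seg, rec@rate, f0r$f0)
      out$h1[i] <- h[1]; out$h2[i] <- h[2]; out$h3[i] <- h[3]
    }
    out$flagged[i] <- f0r$flagged || dur$flagged
  }
  out
}
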