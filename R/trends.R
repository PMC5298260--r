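#' @include AllClasses.R
NULL

.local_time <- function(timestamp, timezone) {
  as.POSIXlt(as.POSIXct(timestamp, origin = "1970-01-01", tz = "UTC"),
             tz = timezone)
}

#' Days x hour-of-day occurrence matrix
#'
#' Assigns each event to its local calendar day and wall-clock hour
#' (floor); the matrix cell is the event count. Events outside the date
#' range are excluded (a message reports how many).
#'
#' @param log event-log data.frame (needs a \code{timestamp} column, UTC
#'   seconds).
#' @param dateRange optional c(first, last) "YYYY-MM-DD" local days; NULL
#'   spans the data.
#' @param timezone local timezone for day/hour bucketing.
#' @return integer matrix days x 24 with dimnames (dates, hours 0-23).
#' @export
occurrenceMatrix <- function(log, dateRange = NULL, timezone = "UTC") {
  lt <- .local_time(log$timestamp, timezone)
  day <- format(lt, "%Y-%m-%d")
  hour <- lt$hour
  if (is.null(dateRange)) {
    days <- if (length(day)) seq(as.Date(min(day)), as.Date(max(day)), by = 1)
            else as.Date(character(0))
  } else {
    days <- seq(as.Date(dateRange[1]), as.Date(dateRange[2]), by = 1)
  }
  keep <- day %in% format(days, "%Y-%m-%d")
  if (any(!keep))
    message(sum(!keep), " event(s) outside the date range excluded")
  m <- matrix(0L, length(days), 24L,
              dimnames = list(format(days, "%Y-%m-%d"), 0:23))
  if (any(keep)) {
    tab <- table(factor(day[keep], levels = rownames(m)),
                 factor(hour[keep], levels = 0:23))
    m[] <- as.integer(tab)
  }
  m
}

#' Averaged daily profile of hourly occurrences
#'
#' Mean and standard error (sd / sqrt(days)) of the hourly counts across
#' days, per hour of the day.
#'
#' @param occ occurrence matrix from \code{\link{occurrenceMatrix}}.
#' @return data.frame: hour (0-23), mean, se (NA when fewer than 2 days),
#'   n_days.
#' @export
hourlyProfile <- function(occ) {
  nd <- nrow(occ)
  se <- if (nd >= 2L) apply(occ, 2L, stats::sd) / sqrt(nd)
        else rep(NA_real_, 24L)
  data.frame(hour = 0:23, mean = colMeans(occ), se = se, n_days = nd,
             row.names = NULL)
}

#' Daily averaged pulse spectrum
#'
#' Per local calendar day, the element-wise mean of per-pulse spectra
#' (typically frame-averaged background-subtracted spectrogram patches).
#' Days with no pulses are absent.
#'
#' @param spectra numeric matrix, one row per pulse, columns = frequency
#'   bins.
#' @param timestamps per-pulse absolute times (UTC s).
#' @param timezone local timezone for day bucketing.
#' @return matrix days x bins with date rownames.
#' @export
dailyMeanSpectrum <- function(spectra, timestamps, timezone = "UTC") {
  stopifnot(nrow(spectra) == length(timestamps))
  day <- format(.local_time(timestamps, timezone), "%Y-%m-%d")
  days <- sort(unique(day))
  out <- t(vapply(days,
                  function(d) colMeans(spectra[day == d, , drop = FALSE]),
                  numeric(ncol(spectra))))
  rownames(out) <- days
  out
}

#' Frequency and amplitude distribution panels
#'
#' The four standard panels for a pulse population: the f0 histogram
#' (10 Hz bins over 150-600 Hz), amplitude-conditioned mean spectra,
#' hour-of-day x amplitude histogram, and day x f0 histogram.
#'
#' @param records data.frame with timestamp, f0_hz, amplitude (and
#'   optionally per-pulse spectra passed as \code{spectra}).
#' @param spectra optional matrix of per-pulse spectra for the
#'   amplitude-conditioned panel.
#' @param nAmpBins number of logarithmic amplitude bins (default 20).
#' @param timezone local timezone.
#' @return list: f0_hist (counts per 10 Hz bin), f0_breaks,
#'   amp_breaks, hour_amp (24 x amplitude bins), day_f0 (days x f0 bins),
#'   amp_spectra (amplitude bins x frequency, or NULL).
#' @export
freqAmpHistograms <- function(records, spectra = NULL, nAmpBins = 20L,
                              timezone = "UTC") {
  f0b <- seq(150, 600, by = 10)
  f0 <- pmin(pmax(records$f0_hz, 150), 600)
  f0bin <- cut(f0, breaks = f0b, include.lowest = TRUE)
  amp <- records$amplitude
  ar <- range(amp)
  if (ar[1] <= 0 || ar[1] == ar[2]) {
    ab <- seq(min(ar[1], 0) - 1e-9, ar[2] + 1e-9, length.out = nAmpBins + 1)
  } else {
    ab <- exp(seq(log(ar[1]) - 1e-9, log(ar[2]) + 1e-9,
                  length.out = nAmpBins + 1))
  }
  abin <- cut(amp, breaks = ab, include.lowest = TRUE)
  lt <- .local_time(records$timestamp, timezone)
  hour <- factor(lt$hour, levels = 0:23)
  day <- factor(format(lt, "%Y-%m-%d"))
  ampSpec <- NULL
  if (!is.null(spectra)) {
    ampSpec <- t(vapply(levels(abin), function(l) {
      rows <- which(abin == l)
      if (length(rows)) colMeans(spectra[rows, , drop = FALSE])
      else rep(NA_real_, ncol(spectra))
    }, numeric(ncol(spectra))))
  }
  list(f0_hist = table(f0bin), f0_breaks = f0b, amp_breaks = ab,
       hour_amp = table(hour, abin), day_f0 = table(day, f0bin),
       amp_spectra = ampSpec)
}

#' Per-day modal signal amplitude
#'
#' For each local calendar day, the centre (geometric mean of the edges) of
#' the modal bin of a 100-bin log-spaced histogram of absolute sample
#' values. Tracks the slow amplitude modulation of the comb (e.g. the brood
#' cycle's mass-density effect) without being dragged by sparse transients.
#'
#' @param rec a \linkS4class{Recording} (one channel used).
#' @param channel channel index or name.
#' @param nBins histogram bins (default 100, log-spaced over the observed
#'   nonzero range).
#' @param timezone local timezone.
#' @return data.frame: day, mode (a.u.).
#' @export
modalAmplitudeDaily <- function(rec, channel = 1L, nBins = 100L,
                                timezone = "UTC") {
  if (is.character(channel)) channel <- match(channel, rec@channelNames)
  a <- abs(rec@samples[, channel])
  t <- rec@startEpoch + (seq_along(a) - 1) / rec@rate
  day <- format(.local_time(t, timezone), "%Y-%m-%d")
  pos <- a[a > 0]
  if (!length(pos)) return(data.frame(day = character(0), mode = numeric(0)))
  br <- exp(seq(log(min(pos)) - 1e-9, log(max(pos)) + 1e-9,
                length.out = nBins + 1))
  centers <- sqrt(br[-1] * br[-length(br)])
  days <- sort(unique(day))
  mode <- vapply(days, function(d) {
    v <- a[day == d & a > 0]
    if (!length(v)) return(NA_real_)
    centers[which.max(tabulate(findInterval(v, br, all.inside = TRUE),
                               nbins = nBins))]
  }, numeric(1))
  data.frame(day = days, mode = mode, row.names = NULL)[!is.na(mode), ]
}

#' Spearman rank correlation between frequency and amplitude
#'
#' Spearman's rho with average ranks for ties; a constant input makes rho
#' undefined and is flagged.
#'
#' @param f0s,amplitudes paired per-pulse values (>= 3 pairs).
#' @return list(rho, flagged).
#' @export
rankCorrelation <- function(f0s, amplitudes) {
  stopifnot(length(f0s) == length(amplitudes), length(f0s) >= 3L)
  if (stats::sd(f0s) == 0 || stats::sd(amplitudes) == 0) {
    warning("constant input: rank correlation undefined")
    return(list(rho = NA_real_, flagged = TRUE))
  }
  list(rho = stats::cor(f0s, amplitudes, method = "spearman"),
       flagged = FALSE)
}
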