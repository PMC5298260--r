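#' @include AllClasses.R
NULL

#' Match duplicated detections across two channels
#'
#' A pulse radiating through the comb can be picked up by both
#' accelerometers. For every event on channel A the nearest event in time
#' on channel B is considered, and a pair is recorded when the absolute
#' time difference is below \code{dtThreshold} (10 ms by default).
#' Conflicts -- two A-events claiming the same B-event -- are resolved
#' greedily by smallest absolute difference, with each event used at most
#' once; ties break on earlier A then B time, so the result is
#' deterministic and symmetric in the two channels (up to transposition of
#' the pair columns).
#'
#' @param timesA,timesB sorted ascending absolute event times (s).
#' @param dtThreshold coincidence window, seconds (default 0.010).
#' @return list with \code{pairs} (data.frame time_a, time_b, dt),
#'   \code{dtThreshold}, and \code{totals} (nA, nB, nPairs, union).
#' @export
matchDuplicates <- function(timesA, timesB, dtThreshold = 0.010) {
  if (is.unsorted(timesA) || is.unsorted(timesB))
    stop("event times must be sorted ascending")
  cand <- NULL
  if (length(timesA) && length(timesB)) {
    # candidate pairs: each A against its two bracketing B neighbours
    j <- findInterval(timesA, timesB)
    lo <- pmax(j, 1L)
    hi <- pmin(j + 1L, length(timesB))
    cand <- unique(rbind(
      data.frame(i = seq_along(timesA), j = lo),
      data.frame(i = seq_along(timesA), j = hi)))
    cand$dt <- timesA[cand$i] - timesB[cand$j]
    cand <- cand[abs(cand$dt) < dtThreshold, , drop = FALSE]
  }
  pairs <- data.frame(time_a = numeric(0), time_b = numeric(0),
                      dt = numeric(0))
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(abs(cand$dt), timesA[cand$i], timesB[cand$j]), ,
                 drop = FALSE]
    usedA <- logical(length(timesA))
    usedB <- logical(length(timesB))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (!usedA[cand$i[r]] && !usedB[cand$j[r]]) {
        keep[r] <- TRUE
        usedA[cand$i[r]] <- TRUE
        usedB[cand$j[r]] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    o <- order(timesA[cand$i])
    pairs <- data.frame(time_a = timesA[cand$i][o],
                        time_b = timesB[cand$j][o],
                        dt = cand$dt[o])
  }
  list(pairs = pairs, dtThreshold = dtThreshold,
       totals = c(nA = length(timesA), nB = length(timesB),
                  nPairs = nrow(pairs),
                  union = length(timesA) + length(timesB) - nrow(pairs)))
}

#' Duplication percentage per time bucket
#'
#' Per bucket, 100 x (number of matched pairs) / (number of distinct
#' events), where a matched pair counts as one distinct event -- so 100%
#' means every pulse was seen on both channels. Buckets with no events are
#' absent from the result, not zero.
#'
#' @param dup result of \code{\link{matchDuplicates}}.
#' @param timesA,timesB the event-time vectors the matching was run on.
#' @param bucketS bucket width in seconds (default 3600: hourly).
#' @return data.frame: bucket (start time, s), n_union, n_pairs, pct.
#' @export
duplicationPercentage <- function(dup, timesA, timesB, bucketS = 3600) {
  bucketOf <- function(t) floor(t / bucketS) * bucketS
  paired_b <- timesB %in% dup$pairs$time_b
  # distinct events: all of A, plus unpaired B; pairs bucketed by A time
  ev <- c(timesA, timesB[!paired_b])
  bu <- bucketOf(ev)
  pu <- bucketOf(dup$pairs$time_a)
  tab <- table(bu)
  out <- data.frame(bucket = as.numeric(names(tab)),
                    n_union = as.integer(tab))
  out$n_pairs <- vapply(out$bucket, function(b) sum(pu == b), integer(1))
  out$pct <- 100 * out$n_pairs / out$n_union
  out[order(out$bucket), , drop = FALSE]
}

#' Comb area monitored by the accelerometers
#'
#' Each accelerometer hears pulses within its sensitivity radius r on both
#' sides of the comb, so n sensors monitor about n x 2 x pi r^2 of comb
#' surface. The reported value is truncated to whole cm^2, matching the
#' convention used when quoting the coverage.
#'
#' @param radiusCm sensitivity radius r, cm.
#' @param nSensors number of accelerometers (default 2).
#' @param combSides comb faces heard by each sensor (default 2).
#' @return monitored area, integer cm^2.
#' @export
monitoredArea <- function(radiusCm, nSensors = 2, combSides = 2) {
  stopifnot(radiusCm >= 0)
  floor(nSensors * combSides * pi * radiusCm^2)
}

#' Fraction of the hive's comb surface monitored
#'
#' @param monitoredCm2 monitored area, cm^2 (see \code{\link{monitoredArea}}).
#' @param totalCm2 total comb surface, cm^2; the default is 2 faces x 10
#'   frames x 35 x 21 cm frames = 14700 cm^2.
#' @return percentage, truncated to integer.
#' @export
monitoredFraction <- function(monitoredCm2, totalCm2 = 2 * 10 * 35 * 21) {
  stopifnot(monitoredCm2 > 0, totalCm2 >= monitoredCm2)
  floor(100 * monitoredCm2 / totalCm2)
}

#' Extrapolate the observed pulse rate to the whole colony
#'
#' Scales the rate observed over the monitored comb area up to the full
#' comb surface, truncating to a whole number of pulses per minute.
#'
#' @param observedRatePerMin pulses/min seen over the monitored area.
#' @param monitoredCm2 monitored area, cm^2.
#' @param totalCm2 total comb surface, cm^2 (default 14700).
#' @return extrapolated pulses/min, integer.
#' @export
extrapolateColonyRate <- function(observedRatePerMin, monitoredCm2,
                                  totalCm2 = 2 * 10 * 35 * 21) {
  if (monitoredCm2 > totalCm2)
    stop("monitored area cannot exceed the total comb surface")
  stopifnot(monitoredCm2 > 0, observedRatePerMin >= 0)
  floor(observedRatePerMin * totalCm2 / monitoredCm2)
}
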