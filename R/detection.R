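#' @include AllClasses.R spectral.R
NULL

#' Build a pulse template from exemplar spectrogram patches
#'
#' Element-wise mean of time-aligned exemplar log-magnitude patches,
#' zero-meaned so that matching is invariant to a global gain on the
#' recording (a multiplicative gain becomes an additive offset in the log
#' domain, removed here and per-excerpt during matching).
#'
#' @param exemplarPatches list of log-magnitude matrices (bins x frames),
#'   all the same shape, time-aligned on pulse onset.
#' @param freqs bin centre frequencies of the patch rows (Hz).
#' @param windowS,hopS STFT parameters the patches were computed with.
#' @return a \linkS4class{PulseTemplate}.
#' @export
buildTemplate <- function(exemplarPatches, freqs, windowS, hopS) {
  stopifnot(length(exemplarPatches) >= 1L)
  d <- dim(exemplarPatches[[1]])
  for (i in seq_along(exemplarPatches)) {
    if (!identical(dim(exemplarPatches[[i]]), d))
      stop("exemplar ", i, " has shape ",
           paste(dim(exemplarPatches[[i]]), collapse = "x"),
           ", expected ", paste(d, collapse = "x"))
  }
  m <- Reduce(`+`, exemplarPatches) / length(exemplarPatches)
  m <- m - mean(m)
  new("PulseTemplate", patch = m, freqs = freqs,
      band = range(freqs), windowS = windowS, hopS = hopS)
}

# rows of a spectrogram matching the template's frequency axis
.template_rows <- function(spec, tpl) {
  idx <- match(round(tpl@freqs, 6), round(spec@freqs, 6))
  if (anyNA(idx))
    stop("spectrogram does not cover the template band with matching bins; ",
         "use the same STFT parameters and an enclosing band")
  idx
}

#' Template-matching criterion series
#'
#' Slides the template along the spectrogram and, for each frame lag t,
#' computes the cross-correlation product XC(t) = sum(template * excerpt)
#' and the Euclidean distance ED(t) = sqrt(sum((template - excerpt)^2))
#' over the patch (excerpts zero-meaned like the template). Both series are
#' normalised so their noise floors -- the median absolute value of the
#' series, i.e. the typical off-peak level -- equal 1, and the criterion is
#' C(t) = XC_n(t) / (ED_n(t) + eps). High XC rewards matching spectral
#' peaks; low ED penalises mismatch; their ratio outperforms either alone.
#'
#' The fast path uses BLAS cross-products and running sums and is
#' algebraically identical to the direct per-lag summation.
#'
#' @param spec a \linkS4class{Spectrogram} (typically background-subtracted).
#' @param tpl a \linkS4class{PulseTemplate}.
#' @param eps regulariser added to the normalised Euclidean distance
#'   (default 1e-3 of the ED noise floor) so a perfect self-match does not
#'   divide by zero.
#' @return list with \code{criterion} (length frames - template frames + 1),
#'   \code{times} (matched-window centre, s), \code{xc}, \code{ed} (raw
#'   series), and \code{nFrames}.
#' @export
matchingCriterion <- function(spec, tpl, eps = 1e-3) {
  raw <- .matching_raw(spec@values[.template_rows(spec, tpl), , drop = FALSE],
                       tpl@patch)
  nF <- ncol(tpl@patch)
  times <- (spec@times[seq_along(raw$xc)] +
            spec@times[seq_along(raw$xc) + nF - 1L]) / 2
  nfXC <- stats::median(abs(raw$xc))
  nfED <- stats::median(raw$ed)
  # a constant spectrogram gives xc = c * sum(template) which is zero only
  # to floating-point accuracy; compare against the scale of the products
  tolXC <- 1e-10 * sum(abs(tpl@patch)) * max(1, max(abs(spec@values)))
  if (nfXC <= tolXC || nfED == 0) {
    warning("constant spectrogram: criterion undefined, returning zeros")
    return(list(criterion = numeric(length(raw$xc)), times = times,
                xc = raw$xc, ed = raw$ed, nFrames = nF))
  }
  C <- (raw$xc / nfXC) / (raw$ed / nfED + eps)
  list(criterion = C, times = times, xc = raw$xc, ed = raw$ed, nFrames = nF)
}

# raw XC/ED series for a band-matched spectrogram matrix S and zero-mean
# template patch T; S frames >= template frames
.matching_raw <- function(S, T) {
  nF <- ncol(T)
  L <- ncol(S) - nF + 1L
  if (L < 1L) stop("spectrogram shorter than the template")
  U <- crossprod(T, S) # nF x frames; U[f, tau] = sum_b T[b,f] S[b,tau]
  xc <- numeric(L)
  for (f in seq_len(nF)) xc <- xc + U[f, f:(f + L - 1L)]
  cs1 <- colSums(S)
  cs2 <- colSums(S^2)
  win <- function(v) { # windowed sums of length-nF runs
    cv <- cumsum(v)
    cv[nF:length(v)] - c(0, cv)[nF:length(v) - nF + 1L]
  }
  nEl <- nrow(T) * nF
  e1 <- win(cs1)
  e2 <- win(cs2)
  ed2 <- sum(T^2) - 2 * xc + (e2 - e1^2 / nEl)
  list(xc = xc, ed = sqrt(pmax(ed2, 0)))
}

#' Pick candidate events from a criterion series
#'
#' Local maxima with criterion at or above the threshold, kept greedily in
#' descending criterion order with no two kept peaks closer than
#' \code{minSeparationS}. The event time is the centre of the matched
#' window; the background-subtracted spectrogram excerpt at the peak lag is
#' retained for the second pass.
#'
#' @param mc result of \code{\link{matchingCriterion}}.
#' @param spec the \linkS4class{Spectrogram} the criterion was computed on.
#' @param tpl the \linkS4class{PulseTemplate}.
#' @param channel channel label stored on the events.
#' @param threshold absolute criterion threshold; NULL uses
#'   \code{thresholdMult} times the median absolute criterion.
#' @param minSeparationS minimum time between kept peaks (default 0.1 s).
#' @param thresholdMult multiplier for the adaptive threshold (default 8: comfortably above the noise tail of the criterion, well below the response to a 10 dB pulse).
#' @param timeOffset added to event times (absolute-time bookkeeping).
#' @return a \linkS4class{CandidateSet}.
#' @export
pickCandidates <- function(mc, spec, tpl, channel = "ch1", threshold = NULL,
                           minSeparationS = 0.1, thresholdMult = 8,
                           timeOffset = 0) {
  C <- mc$criterion
  if (is.null(threshold)) threshold <- thresholdMult * stats::median(abs(C))
  n <- length(C)
  rows <- .template_rows(spec, tpl)
  nF <- mc$nFrames
  empty <- CandidateSet(
    data.frame(time = numeric(0), channel = character(0),
               criterion = numeric(0), stringsAsFactors = FALSE),
    array(0, c(length(rows), nF, 0L)))
  if (n < 1L || threshold <= 0) return(empty)
  isMax <- C >= threshold
  if (n > 1L) {
    isMax <- isMax & C >= c(-Inf, C[-n]) & C > c(C[-1], -Inf)
  }
  idx <- which(isMax)
  if (!length(idx)) return(empty)
  idx <- idx[order(C[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in idx) {
    if (!length(kept) ||
        all(abs(mc$times[i] - mc$times[kept]) >= minSeparationS))
      kept <- c(kept, i)
  }
  kept <- kept[order(mc$times[kept])]
  patches <- array(0, c(length(rows), nF, length(kept)))
  for (j in seq_along(kept))
    patches[, , j] <- spec@values[rows, kept[j]:(kept[j] + nF - 1L)]
  CandidateSet(
    data.frame(time = mc$times[kept] + timeOffset,
               channel = rep(channel, length(kept)),
               criterion = C[kept], stringsAsFactors = FALSE),
    patches)
}

.combine_candidates <- function(sets) {
  sets <- Filter(function(s) nrow(s@events) > 0, sets)
  if (!length(sets))
    return(CandidateSet(
      data.frame(time = numeric(0), channel = character(0),
                 criterion = numeric(0), stringsAsFactors = FALSE),
      array(0, c(0L, 0L, 0L))))
  ev <- do.call(rbind, lapply(sets, function(s) s@events))
  d <- dim(sets[[1]]@patches)
  patches <- array(unlist(lapply(sets, function(s) s@patches)),
                   c(d[1], d[2], nrow(ev)))
  o <- order(ev$channel, ev$time)
  CandidateSet(ev[o, , drop = FALSE], patches[, , o, drop = FALSE])
}

#' First-pass detection on a whole recording
#'
#' Per channel: log spectrogram, rolling-median background subtraction,
#' template-matching criterion, thresholded peak picking.
#'
#' @param rec a \linkS4class{Recording}.
#' @param tpl a \linkS4class{PulseTemplate}.
#' @param config pipeline configuration, see
#'   \code{\link{defaultPipelineConfig}}.
#' @return a \linkS4class{CandidateSet} covering all channels.
#' @export
detect <- function(rec, tpl, config = defaultPipelineConfig()) {
  sets <- lapply(seq_along(rec@channelNames), function(ci) {
    spec <- stftLogSpectrogram(rec, ci, config$stft$window_s,
                               config$stft$hop_s, config$stft$band_hz,
                               config$stft$epsilon)
    if (isTRUE(config$background$enabled))
      spec <- subtractBackground(spec, config$background$window_s)
    mc <- matchingCriterion(spec, tpl, config$detect$eps)
    pickCandidates(mc, spec, tpl, channel = rec@channelNames[ci],
                   threshold = config$detect$threshold,
                   minSeparationS = config$detect$min_separation_s,
                   thresholdMult = config$detect$threshold_mult,
                   timeOffset = rec@startEpoch)
  })
  .combine_candidates(sets)
}

#' Chunked first-pass detection with bounded waveform memory
#'
#' Processes the recording in blocks of STFT frames so the waveform is
#' never fully in memory. Each frame depends only on its own samples, so
#' the blocks assemble into exactly the monolithic spectrogram (a few
#' dozen floats per frame, negligible memory); background subtraction,
#' criterion normalisation and peak picking then run once over the
#' assembled series, so chunked and whole-file detection yield identical
#' candidate sets.
#'
#' @param x a \linkS4class{Recording} or a WAV path.
#' @param tpl a \linkS4class{PulseTemplate}.
#' @param config pipeline configuration.
#' @param chunkS nominal block length in seconds (default
#'   \code{config$detect$chunk_s}).
#' @param ... passed to \code{\link{readRecording}} for path input.
#' @return a \linkS4class{CandidateSet}.
#' @export
detectChunked <- function(x, tpl, config = defaultPipelineConfig(),
                          chunkS = NULL, ...) {
  if (is.character(x)) {
    meta <- readRecording(x, from = 1L, to = 2L, ...)
    rate <- meta@rate
    con <- file(x, "rb"); hdr <- .wav_read_header(con, x); close(con)
    nTotal <- hdr$dataSize %/% ((hdr$bits %/% 8L) * hdr$channels)
    nch <- length(meta@channelNames)
    slice <- function(a, b) readRecording(x, from = a, to = b, ...)
    chNames <- meta@channelNames
    epoch0 <- meta@startEpoch
    tz <- meta@tz
  } else {
    rate <- x@rate
    nTotal <- nrow(x@samples)
    nch <- ncol(x@samples)
    slice <- function(a, b)
      Recording(x@samples[a:b, , drop = FALSE], rate, x@channelNames,
                x@startEpoch + (a - 1) / rate, x@tz)
    chNames <- x@channelNames
    epoch0 <- x@startEpoch
    tz <- x@tz
  }
  if (is.null(chunkS)) chunkS <- config$detect$chunk_s
  n <- if (is.null(config$stft$window_s)) 512L
       else round(config$stft$window_s * rate)
  hop <- if (is.null(config$stft$hop_s)) 128L
         else round(config$stft$hop_s * rate)
  J <- (nTotal - n) %/% hop + 1L # total frames
  B <- max(ncol(tpl@patch) + 1L, round(chunkS * rate / hop))
  blocks <- split(seq_len(J), (seq_len(J) - 1L) %/% B)
  sets <- vector("list", nch)
  for (ci in seq_len(nch)) {
    cols <- vector("list", length(blocks))
    for (bi in seq_along(blocks)) {
      j0 <- blocks[[bi]][1]; j1 <- blocks[[bi]][length(blocks[[bi]])]
      a <- (j0 - 1L) * hop + 1L
      b <- (j1 - 1L) * hop + n
      seg <- slice(a, min(b, nTotal))
      spec <- stftLogSpectrogram(seg, ci, config$stft$window_s,
                                 config$stft$hop_s, config$stft$band_hz,
                                 config$stft$epsilon)
      cols[[bi]] <- spec@values
      freqs <- spec@freqs
    }
    full <- new("Spectrogram", values = do.call(cbind, cols), freqs = freqs,
                times = ((seq_len(J) - 1L) * hop + (n - 1) / 2) / rate,
                windowS = n / rate, hopS = hop / rate)
    if (isTRUE(config$background$enabled))
      full <- subtractBackground(full, config$background$window_s)
    mc <- matchingCriterion(full, tpl, config$detect$eps)
    sets[[ci]] <- pickCandidates(mc, full, tpl, channel = chNames[ci],
                                 threshold = config$detect$threshold,
                                 minSeparationS = config$detect$min_separation_s,
                                 thresholdMult = config$detect$threshold_mult,
                                 timeOffset = epoch0)
  }
  .combine_candidates(sets)
}
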