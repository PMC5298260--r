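#' @import methods
NULL

#' Recognised event classes
#'
#' The fixed vocabulary of pulse classes used throughout the package: the
#' whooping signal itself plus the confounder classes that the second
#' detection pass must reject.
#'
#' @export
EVENT_CLASSES <- c("whoop", "droplet", "worker_pipe", "queen_toot",
                   "spike", "unknown")

#' Recording: a multi-channel vibration recording
#'
#' Holds per-channel acceleration series (arbitrary units, proportional to
#' mm/s^2), the sampling rate, ordered channel labels, and the absolute time
#' of sample 1 (seconds since the Unix epoch) together with the hive's local
#' timezone used for hour-of-day bucketing.
#'
#' @slot samples numeric matrix, samples x channels, normalised to [-1, 1]
#'   floats internally.
#' @slot rate sampling rate in samples/s.
#' @slot channelNames unique ordered channel labels (e.g. "central",
#'   "peripheral").
#' @slot startEpoch absolute time of sample 1, UTC seconds.
#' @slot tz named local timezone (e.g. "Europe/Paris").
#' @export
setClass("Recording",
  representation(samples = "matrix", rate = "numeric",
                 channelNames = "character", startEpoch = "numeric",
                 tz = "character"))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (ncol(object@samples) != length(object@channelNames))
    msg <- c(msg, "one channel name per sample column required")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (length(object@startEpoch) != 1L || !is.finite(object@startEpoch))
    msg <- c(msg, "startEpoch must be a single finite number")
  if (length(object@tz) != 1L)
    msg <- c(msg, "tz must be a single timezone name")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param samples numeric matrix (samples x channels) or vector (one channel).
#' @param rate sampling rate, samples/s.
#' @param channelNames channel labels; defaults to "ch1", "ch2", ...
#' @param startEpoch absolute time of the first sample, UTC seconds.
#' @param tz local timezone name for hour-of-day bucketing.
#' @return a \linkS4class{Recording}.
#' @export
Recording <- function(samples, rate, channelNames = NULL, startEpoch = 0,
                      tz = "UTC") {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(ncol(samples)))
  new("Recording", samples = samples, rate = as.numeric(rate),
      channelNames = as.character(channelNames),
      startEpoch = as.numeric(startEpoch), tz = tz)
}

#' Spectrogram: log-magnitude time-frequency matrix
#'
#' @slot values log-magnitude matrix (frequency bins x time frames, dB re
#'   1 a.u.).
#' @slot freqs bin centre frequencies, Hz, strictly ascending.
#' @slot times frame centre times, seconds from recording start, ascending.
#' @slot windowS,hopS STFT window and hop lengths in seconds.
#' @export
setClass("Spectrogram",
  representation(values = "matrix", freqs = "numeric", times = "numeric",
                 windowS = "numeric", hopS = "numeric"))

setValidity("Spectrogram", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@freqs))
    msg <- c(msg, "nrow(values) must equal length(freqs)")
  if (ncol(object@values) != length(object@times))
    msg <- c(msg, "ncol(values) must equal length(times)")
  if (length(object@freqs) > 1 && any(diff(object@freqs) <= 0))
    msg <- c(msg, "freqs must be strictly increasing")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (object@hopS > object@windowS)
    msg <- c(msg, "hopS must not exceed windowS")
  if (length(msg)) msg else TRUE
})

#' PulseTemplate: spectrogram patch of an exemplar pulse
#'
#' The first detection pass slides this patch along a recording spectrogram.
#' The patch is stored zero-mean so that matching is invariant to a global
#' gain applied to the recording (a gain is an additive offset in the log
#' domain).
#'
#' @slot patch zero-mean log-magnitude matrix (bins x frames).
#' @slot freqs bin centre frequencies of the patch rows, Hz.
#' @slot band analysis band (f_lo, f_hi), Hz.
#' @slot windowS,hopS STFT parameters the patch was computed with.
#' @export
setClass("PulseTemplate",
  representation(patch = "matrix", freqs = "numeric", band = "numeric",
                 windowS = "numeric", hopS = "numeric"))

setValidity("PulseTemplate", function(object) {
  msg <- character()
  if (ncol(object@patch) < 3L)
    msg <- c(msg, "template must span at least 3 frames")
  if (!all(is.finite(object@patch)))
    msg <- c(msg, "template patch must be finite")
  if (nrow(object@patch) != length(object@freqs))
    msg <- c(msg, "one frequency per patch row required")
  if (length(object@band) != 2L || object@band[1] >= object@band[2])
    msg <- c(msg, "band must be (f_lo, f_hi) with f_lo < f_hi")
  if (length(msg)) msg else TRUE
})

#' CandidateSet: first-pass detections with their spectrogram patches
#'
#' @slot events data.frame with columns time (s, absolute), channel,
#'   criterion (unitless match score C).
#' @slot patches numeric array (bins x frames x n events); the local
#'   spectrogram excerpt at each detection, retained for the second pass.
#' @export
setClass("CandidateSet",
  representation(events = "data.frame", patches = "array"))

setValidity("CandidateSet", function(object) {
  msg <- character()
  need <- c("time", "channel", "criterion")
  if (!all(need %in% names(object@events)))
    msg <- c(msg, paste("events must have columns:", paste(need, collapse = ", ")))
  n <- nrow(object@events)
  if (length(dim(object@patches)) != 3L || dim(object@patches)[3] != n)
    msg <- c(msg, "patches must be a bins x frames x n array matching events")
  if (n > 0 && any(object@events$criterion <= 0))
    msg <- c(msg, "criterion scores must be positive")
  if (length(msg)) msg else TRUE
})

CandidateSet <- function(events, patches) {
  new("CandidateSet", events = events, patches = patches)
}

#' ClassifierModel: standardisation + PCA basis + discriminant function
#'
#' The second-pass model: flattened log-spectrogram patches are standardised
#' per dimension, projected onto the retained principal components, and
#' scored along a two-class Fisher discriminant axis.
#'
#' @slot featureMean,featureScale per-dimension standardisation.
#' @slot rotation PCA basis, dims x components, columns orthonormal.
#' @slot explainedVar explained-variance fraction per retained component.
#' @slot dfWeights discriminant axis in PCA-score space.
#' @slot dfThreshold scalar decision boundary (midpoint of projected class
#'   means); scores strictly above it are called whoop.
#' @slot classLabels c(positive = "whoop", negative = "non_whoop").
#' @slot patchDim c(bins, frames) of the patches the model was trained on.
#' @slot trainError training misclassification fraction, recorded at fit time.
#' @export
setClass("ClassifierModel",
  representation(featureMean = "numeric", featureScale = "numeric",
                 rotation = "matrix", explainedVar = "numeric",
                 dfWeights = "numeric", dfThreshold = "numeric",
                 classLabels = "character", patchDim = "integer",
                 trainError = "numeric"))

setValidity("ClassifierModel", function(object) {
  msg <- character()
  k <- ncol(object@rotation)
  if (length(object@dfWeights) != k)
    msg <- c(msg, "dfWeights must have one entry per retained component")
  if (!is.finite(object@dfThreshold))
    msg <- c(msg, "dfThreshold must be finite")
  g <- crossprod(object@rotation)
  if (max(abs(g - diag(k))) > 1e-6)
    msg <- c(msg, "PCA components must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' SynthSession: synthetic two-channel recording with ground truth
#'
#' @slot recording the generated two-channel \linkS4class{Recording}.
#' @slot truth ground-truth event log (one row per event and channel on which
#'   the event is supra-threshold) with per-event class, f0, duration,
#'   per-channel amplitude, and a co-detected flag.
#' @slot seed integer seed the session was generated from.
#' @slot config full generator parameterisation.
#' @export
setClass("SynthSession",
  representation(recording = "Recording", truth = "data.frame",
                 seed = "integer", config = "list"))

setValidity("SynthSession", function(object) {
  msg <- character()
  if (nrow(object@truth)) {
    span <- nrow(object@recording@samples) / object@recording@rate
    t0 <- object@recording@startEpoch
    if (any(object@truth$timestamp < t0 | object@truth$timestamp > t0 + span))
      msg <- c(msg, "truth timestamps must lie within the recording span")
  }
  if (length(msg)) msg else TRUE
})
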