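#' @include AllClasses.R
NULL

#' Accessors for Recording and Spectrogram objects
#'
#' @param x a \linkS4class{Recording} or \linkS4class{Spectrogram}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("startEpoch", function(x) standardGeneric("startEpoch"))
#' @rdname accessors
#' @export
setGeneric("recTimezone", function(x) standardGeneric("recTimezone"))
#' @rdname accessors
#' @export
setGeneric("durationSec", function(x) standardGeneric("durationSec"))
#' @rdname accessors
#' @export
setGeneric("specValues", function(x) standardGeneric("specValues"))
#' @rdname accessors
#' @export
setGeneric("specFreqs", function(x) standardGeneric("specFreqs"))
#' @rdname accessors
#' @export
setGeneric("specTimes", function(x) standardGeneric("specTimes"))

#' @rdname accessors
#' @export
setMethod("samples", "Recording", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("sampleRate", "Recording", function(x) x@rate)
#' @rdname accessors
#' @export
setMethod("channelNames", "Recording", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("startEpoch", "Recording", function(x) x@startEpoch)
#' @rdname accessors
#' @export
setMethod("recTimezone", "Recording", function(x) x@tz)
#' @rdname accessors
#' @export
setMethod("durationSec", "Recording", function(x) nrow(x@samples) / x@rate)

#' @rdname accessors
#' @export
setMethod("specValues", "Spectrogram", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("specFreqs", "Spectrogram", function(x) x@freqs)
#' @rdname accessors
#' @export
setMethod("specTimes", "Spectrogram", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("truthLog", function(x) standardGeneric("truthLog"))
#' @rdname accessors
#' @export
setMethod("truthLog", "SynthSession", function(x) x@truth)
#' @rdname accessors
#' @export
setGeneric("sessionRecording", function(x) standardGeneric("sessionRecording"))
#' @rdname accessors
#' @export
setMethod("sessionRecording", "SynthSession", function(x) x@recording)

#' @rdname accessors
#' @export
setGeneric("candidateEvents", function(x) standardGeneric("candidateEvents"))
#' @rdname accessors
#' @export
setMethod("candidateEvents", "CandidateSet", function(x) x@events)
#' @rdname accessors
#' @export
setGeneric("candidatePatches", function(x) standardGeneric("candidatePatches"))
#' @rdname accessors
#' @export
setMethod("candidatePatches", "CandidateSet", function(x) x@patches)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              ncol(object@samples), nrow(object@samples), object@rate,
              durationSec(object)))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  cat(sprintf("  start: %s (%s)\n",
              format(as.POSIXct(object@startEpoch, origin = "1970-01-01",
                                tz = object@tz)), object@tz))
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf("Spectrogram: %d bins (%.0f-%.0f Hz) x %d frames (%.2f-%.2f s)\n",
              nrow(object@values), min(object@freqs), max(object@freqs),
              ncol(object@values), min(object@times), max(object@times)))
  cat(sprintf("  window %.4g s, hop %.4g s\n", object@windowS, object@hopS))
})

setMethod("show", "PulseTemplate", function(object) {
  cat(sprintf("PulseTemplate: %d bins x %d frames, band %g-%g Hz\n",
              nrow(object@patch), ncol(object@patch),
              object@band[1], object@band[2]))
})

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d candidate(s)\n", nrow(object@events)))
  if (nrow(object@events))
    print(utils::head(object@events, 5))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf(
    "ClassifierModel: %d features -> %d PCs (%.1f%% var) -> Fisher DF\n",
    nrow(object@rotation), ncol(object@rotation),
    100 * sum(object@explainedVar)))
  cat(sprintf("  threshold %.4g, training error %.3f\n",
              object@dfThreshold, object@trainError))
})

setMethod("show", "SynthSession", function(object) {
  cat("SynthSession (seed", object@seed, ")\n")
  show(object@recording)
  cat(sprintf("  truth: %d event-channel rows\n", nrow(object@truth)))
})
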