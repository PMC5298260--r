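# Shared fixtures, built lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

withr_tempfile <- function(ext) tempfile(fileext = ext)

# the default whoop template (deterministic, seed baked into the default)
fxTemplate <- function() fixture("template", function() makeWhoopTemplate())

# 60 s two-channel session at the study defaults
fxSession60 <- function() fixture("session60", function()
  synthSession(synthSessionConfig(duration_s = 60), seed = 7))

fxDetect60 <- function() fixture("detect60", function()
  detect(sessionRecording(fxSession60()), fxTemplate(),
         defaultPipelineConfig()))

# labelled whoop/droplet patches for classifier module tests
fxPatches <- function() fixture("patches", function()
  synthLabeledPatches(nPerClass = 150L, seed = 5))
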