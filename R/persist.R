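#' @include AllClasses.R
NULL

#' Persist and restore templates and classifier models
#'
#' Templates and models are written as single self-describing RDS files
#' with a format-version field, so a newer package version can refuse or
#' migrate old files explicitly.
#'
#' @param x a \linkS4class{PulseTemplate} or \linkS4class{ClassifierModel}.
#' @param path file path.
#' @return \code{path} invisibly (writers); the restored object (readers).
#' @name persistence
NULL

#' @rdname persistence
#' @export
writeTemplate <- function(x, path) {
  stopifnot(is(x, "PulseTemplate"))
  saveRDS(list(format = "hivewhoop-template", version = 1L, object = x),
          path)
  invisible(path)
}

#' @rdname persistence
#' @export
readTemplate <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hivewhoop-template"))
    stop(path, " is not a template file")
  validObject(obj$object)
  obj$object
}

#' @rdname persistence
#' @export
writeClassifierModel <- function(x, path) {
  stopifnot(is(x, "ClassifierModel"))
  saveRDS(list(format = "hivewhoop-model", version = 1L, object = x), path)
  invisible(path)
}

#' @rdname persistence
#' @export
readClassifierModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hivewhoop-model"))
    stop(path, " is not a classifier model file")
  validObject(obj$object)
  obj$object
}
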