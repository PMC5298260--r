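#' @include AllClasses.R
NULL

#' Default pipeline configuration
#'
#' One nested list carrying every tunable of the pipeline, grouped by
#' stage. All values can be overridden via \code{...} (named nested lists)
#' or a YAML file through \code{\link{readPipelineConfig}}.
#'
#' \describe{
#'   \item{stft}{window_s / hop_s (NULL: 512 and 128 samples at the
#'     recording rate), band_hz (default 100-1500 Hz, covering a 200-500 Hz
#'     fundamental and its second and third harmonics), epsilon (magnitude
#'     floor).}
#'   \item{background}{enabled, window_s: rolling-median window (default
#'     60 s, much longer than any pulse).}
#'   \item{detect}{threshold (NULL: adaptive), threshold_mult (default 8x
#'     the median absolute criterion), min_separation_s, eps, chunk_s.}
#'   \item{classify}{variance_target, max_components, ridge.}
#'   \item{duplicates}{dt_ms: coincidence window (default 10 ms).}
#'   \item{trends}{timezone.}
#'   \item{simulate}{generator defaults, see
#'     \code{\link{synthSessionConfig}}.}
#' }
#'
#' @param ... named overrides merged over the defaults.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(...) {
  cfg <- list(
    stft = list(window_s = NULL, hop_s = NULL, band_hz = c(100, 1500),
                epsilon = 1e-10),
    background = list(enabled = TRUE, window_s = 60),
    detect = list(threshold = NULL, threshold_mult = 8,
                  min_separation_s = 0.1, eps = 1e-3, chunk_s = 300),
    classify = list(variance_target = 0.95, max_components = 20L,
                    ridge = 1e-6),
    duplicates = list(dt_ms = 10),
    trends = list(timezone = "UTC"),
    filename_time_format = "%Y-%m-%d_%H-%M-%S",
    simulate = synthSessionConfig(),
    seed = 1L,
    log_level = "info")
  over <- list(...)
  if (length(over)) {
    .check_config_keys(over, cfg, "")
    cfg <- utils::modifyList(cfg, over)
  }
  .normalize_config(cfg)
}

# YAML flattens the 2 x 2 sensor-position matrix to a plain numeric
# vector (column-major) and drops its row names; rebuild it so configs
# survive a write/read round trip.
.normalize_config <- function(cfg) {
  s <- cfg$simulate$geometry$sensors
  if (!is.null(s) && !is.matrix(s)) {
    v <- as.numeric(unlist(s))
    if (length(v) %% 2L != 0L)
      stop("simulate.geometry.sensors must hold (x, y) pairs")
    m <- matrix(v, ncol = 2L)
    rownames(m) <- if (nrow(m) == 2L) c("central", "peripheral")
                   else paste0("ch", seq_len(nrow(m)))
    cfg$simulate$geometry$sensors <- m
  }
  cfg
}

.check_config_keys <- function(x, ref, path) {
  for (k in names(x)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(ref))
      stop("unknown config key: ", full)
    if (is.list(x[[k]]) && is.list(ref[[k]]) && !is.null(names(ref[[k]])) &&
        !is.null(names(x[[k]])))
      .check_config_keys(x[[k]], ref[[k]], full)
  }
  invisible(TRUE)
}

#' Read a YAML pipeline configuration
#'
#' Unknown keys are rejected with a message naming the offending key;
#' known keys override the defaults.
#'
#' @param path YAML file.
#' @return full configuration list (defaults + overrides).
#' @export
readPipelineConfig <- function(path) {
  over <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig()
  if (length(over)) {
    .check_config_keys(over, cfg, "")
    cfg <- utils::modifyList(cfg, over)
  }
  .normalize_config(cfg)
}

#' Write a configuration as YAML
#'
#' Used to echo the effective configuration into output directories so
#' every run is reproducible from its artefacts.
#'
#' @param config configuration list.
#' @param path output YAML file.
#' @return \code{path}, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
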