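#' @include AllClasses.R detection.R spectral.R colocation.R
NULL

# Tukey (tapered cosine) window
.tukey <- function(n, alpha = 0.25) {
  if (alpha <= 0) return(rep(1, n))
  if (alpha >= 1) return(signal::hanning(n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}

.rms <- function(x) sqrt(mean(x^2))

# run expr with a private, seeded RNG stream, restoring global state after
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthesise one whooping pulse
#'
#' A sum of three harmonics of a frequency trajectory that rises by
#' \code{glideExtent} up to \code{f0} over \code{glideTime} at onset, holds
#' \code{f0}, and falls back over \code{glideTime} at offset -- the
#' ultra-short frequency glides seen at the start and end of real pulses.
#' Phase is continuous (cumulative phase of the trajectory) and the
#' amplitude follows a Tukey envelope whose taper spans the glides.
#'
#' @param f0 fundamental frequency, Hz (3 f0 must be below Nyquist).
#' @param duration pulse length, s.
#' @param harmonicRatios amplitudes (a1, a2, a3) of harmonics 1..3, with
#'   a1 > a2 >= a3 >= 0.
#' @param glideExtent onset/offset frequency excursion, Hz (0 disables).
#' @param glideTime glide length, s.
#' @param amplitude peak amplitude, a.u.
#' @param rate samples/s.
#' @return numeric waveform of length round(duration * rate).
#' @export
synthWhoop <- function(f0, duration, harmonicRatios = c(1, 0.3, 0.2),
                       glideExtent = 50, glideTime = 0.005, amplitude = 1,
                       rate = 22050) {
  if (3 * f0 >= rate / 2) stop("3*f0 must be below the Nyquist frequency")
  if (duration <= 0 || 2 * glideTime > duration)
    stop("invalid duration/glideTime")
  a <- harmonicRatios
  if (length(a) != 3 || !(a[1] > 0) || a[1] < a[2] || a[2] < a[3] || a[3] < 0)
    stop("harmonicRatios must satisfy a1 > 0, a1 >= a2 >= a3 >= 0")
  n <- round(duration * rate)
  tt <- (seq_len(n) - 1) / rate
  f <- rep(f0, n)
  if (glideExtent > 0 && glideTime > 0) {
    on <- tt < glideTime
    off <- tt > duration - glideTime
    f[on] <- f0 - glideExtent * (1 - tt[on] / glideTime)
    f[off] <- f0 - glideExtent * (1 - (duration - tt[off]) / glideTime)
  }
  phase <- 2 * pi * cumsum(f) / rate
  w <- a[1] * sin(phase) + a[2] * sin(2 * phase) + a[3] * sin(3 * phase)
  alpha <- if (glideTime > 0) min(1, max(0.1, 2 * glideTime / duration)) else 0.15
  w <- w * .tukey(n, alpha)
  w * amplitude / max(abs(w))
}

#' Synthesise a confounder transient
#'
#' The non-whoop pulse classes that the second detection pass must reject:
#' rain droplets (band-limited decaying impulses under 20 ms), worker
#' pipes (0.5-2 s tones, flat or sweeping 100 to 200 Hz), queen toots
#' (pulse trains near 400 Hz) and wax-maintenance spikes (near
#' single-sample transients). Droplets and toots consume random numbers
#' from the current RNG stream.
#'
#' @param class one of "droplet", "worker_pipe_sweep", "worker_pipe_flat",
#'   "queen_toot", "spike".
#' @param rate samples/s.
#' @param amplitude peak amplitude, a.u.
#' @param duration class-appropriate length, s (ignored for droplet/spike).
#' @return numeric waveform.
#' @export
synthConfounder <- function(class, rate = 22050, amplitude = 1,
                            duration = 1) {
  w <- switch(class,
    droplet = {
      n <- round(0.015 * rate)
      x <- stats::rnorm(n)
      x <- .bandpass(x, rate, c(200, 2500)) * exp(-(seq_len(n) - 1) /
                                                    (0.003 * rate))
      x
    },
    worker_pipe_sweep = {
      stopifnot(duration >= 0.5, duration <= 2)
      n <- round(duration * rate)
      tt <- (seq_len(n) - 1) / rate
      f <- 100 + 100 * tt / duration
      sin(2 * pi * cumsum(f) / rate) * .tukey(n, 0.1)
    },
    worker_pipe_flat = {
      stopifnot(duration >= 0.5, duration <= 2)
      n <- round(duration * rate)
      sin(2 * pi * 150 * (seq_len(n) - 1) / rate) * .tukey(n, 0.1)
    },
    queen_toot = {
      f <- 400 * stats::runif(1, 0.95, 1.05)
      pulse <- sin(2 * pi * f * (seq_len(round(0.12 * rate)) - 1) / rate) *
        .tukey(round(0.12 * rate), 0.3)
      gap <- numeric(round(0.06 * rate))
      do.call(c, rep(list(c(pulse, gap)), 5L))
    },
    spike = {
      k <- round(0.0005 * rate)
      exp(-(seq_len(4 * k) - 1) / k) * c(1, -1)[1 + (seq_len(4 * k) %% 2)]
    },
    stop("unknown confounder class: ", class))
  w * amplitude / max(abs(w))
}

#' Synthesise the hive's stationary background
#'
#' Narrowband noise centred on the colony hum (default 125 Hz, 20 Hz
#' bandwidth) plus pink (1/f) broadband noise, each scaled to a target RMS.
#' Consumes random numbers from the current RNG stream.
#'
#' @param durationS length, s.
#' @param rate samples/s.
#' @param humFreq hum centre frequency, Hz.
#' @param humBw hum bandwidth, Hz.
#' @param humLevel hum RMS, a.u. (0 disables).
#' @param noiseLevel broadband RMS, a.u. (0 disables).
#' @return numeric waveform.
#' @export
synthBackground <- function(durationS, rate = 22050, humFreq = 125,
                            humBw = 20, humLevel = 0.01,
                            noiseLevel = 0.005) {
  n <- round(durationS * rate)
  out <- numeric(n)
  if (humLevel > 0) {
    h <- stats::rnorm(n)
    bf <- signal::butter(2, c(humFreq - humBw / 2, humFreq + humBw / 2) /
                              (rate / 2), type = "pass")
    h <- as.numeric(signal::filter(bf, h)) # drop ts attributes: ts + ts
                                           # addition realigns and truncates
    out <- out + h * (humLevel / .rms(h))
  }
  if (noiseLevel > 0) {
    x <- stats::rnorm(n)
    # classic 3-pole/3-zero pink-noise shaping filter
    b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
    a <- c(1, -2.494956002, 2.017265875, -0.522189400)
    p <- as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
    out <- out + p * (noiseLevel / .rms(p))
  }
  as.numeric(out)
}

#' Default synthetic-session configuration
#'
#' The deployment the generator emulates: a 35 x 21 cm brood frame with two
#' accelerometers on its vertical midline 7 cm apart, exponential
#' amplitude attenuation with comb distance (decay length
#' \code{lambda_cm}), a circadian emission schedule with a midday dip and
#' night maximum, the 125 Hz colony hum plus pink broadband noise, and a
#' source level chosen so that a pulse at the edge of the sensitivity
#' radius arrives at \code{snr_db} above the background RMS.
#'
#' @param duration_s session length (default 600 s).
#' @param rate samples/s (default 22050).
#' @param hourly_rate 24 frame-wide emission rates (events/hour) indexed by
#'   hour of day; the default peaks at night and dips ~50\% at midday.
#' @param radius_cm sensitivity radius the source level is calibrated to
#'   (default 3.5 cm).
#' @param snr_db peak-amplitude SNR (dB re background RMS) of a pulse
#'   arriving exactly at the sensitivity radius (default 10).
#' @param confounder_rate events/hour for each confounder class.
#' @param ... overrides for any other listed element. Two switches exist
#'   for geometric studies: \code{fixed_position} (an (x, y) position in
#'   cm; when non-NULL every event is placed there instead of uniformly)
#'   and \code{render_audio} (when FALSE only the truth log is produced
#'   and the waveform stays zero, making large event counts cheap).
#' @return named list of generator parameters.
#' @export
synthSessionConfig <- function(duration_s = 600, rate = 22050,
                               hourly_rate = NULL, radius_cm = 3.5,
                               snr_db = 10,
                               confounder_rate = c(droplet = 120,
                                                   worker_pipe_sweep = 6,
                                                   worker_pipe_flat = 6,
                                                   queen_toot = 2,
                                                   spike = 30), ...) {
  if (is.null(hourly_rate)) {
    shape <- c(rep(1, 7), 0.9, 0.8, 0.7, 0.6, 0.5, 0.5, 0.5, 0.6, 0.7,
               0.8, 0.9, 1, 1, 1, 1, 1, 1)
    hourly_rate <- 6000 * shape
  }
  cfg <- list(
    duration_s = duration_s, rate = rate, start_epoch = 0, tz = "UTC",
    hourly_rate = hourly_rate,
    whoop = list(f0_mean = 380, f0_sd = 40, f0_range = c(200, 500),
                 duration_range = c(0.05, 0.2),
                 harmonic_ratios = c(1, 0.3, 0.2),
                 glide_extent = 50, glide_time = 0.005),
    geometry = list(frame_w_cm = 35, frame_h_cm = 21,
                    sensors = rbind(central = c(17.5, 14),
                                    peripheral = c(17.5, 7)),
                    lambda_cm = 2),
    radius_cm = radius_cm, snr_db = snr_db,
    background = list(hum_freq = 125, hum_bw = 20, hum_level = 0.01,
                      noise_level = 0.005),
    confounder_rate = confounder_rate,
    fixed_position = NULL, render_audio = TRUE)
  utils::modifyList(cfg, list(...), keep.null = TRUE)
}

#' Generate a synthetic two-channel session with ground truth
#'
#' Draws event counts from the per-hour emission schedule (Poisson), places
#' each event uniformly on the comb, synthesises its waveform, and adds it
#' to both channels with amplitude source x exp(-d / lambda) for the
#' distance d to each sensor. The truth log carries one row per event and
#' channel with the arriving amplitude, a supra-threshold flag (amplitude
#' at or above the level a pulse at the sensitivity radius would have) and
#' a co-detected flag (supra-threshold on both channels). Identical seed
#' and config give bit-identical output; random numbers are drawn in a
#' fixed order (event times, positions, pulse parameters, confounders,
#' then per-channel noise).
#'
#' @param config from \code{\link{synthSessionConfig}}.
#' @param seed integer seed.
#' @return a \linkS4class{SynthSession}.
#' @export
synthSession <- function(config = synthSessionConfig(), seed = 1L) {
  .with_seed(seed, {
    rate <- config$rate
    n <- round(config$duration_s * rate)
    geo <- config$geometry
    sensors <- geo$sensors
    lam <- geo$lambda_cm
    sigmaBg <- sqrt(config$background$hum_level^2 +
                    config$background$noise_level^2)
    thr <- 10^(config$snr_db / 20) * sigmaBg     # amplitude at radius
    a0 <- thr * exp(config$radius_cm / lam)      # source level
    # --- event times from the hour-of-day schedule
    t0 <- config$start_epoch
    times <- numeric(0)
    edges <- seq(0, config$duration_s, by = 3600)
    if (edges[length(edges)] < config$duration_s)
      edges <- c(edges, config$duration_s)
    for (i in seq_len(length(edges) - 1)) {
      span <- edges[i + 1] - edges[i]
      hr <- as.POSIXlt(as.POSIXct(t0 + edges[i], origin = "1970-01-01",
                                  tz = "UTC"), tz = config$tz)$hour
      k <- stats::rpois(1, config$hourly_rate[hr + 1] * span / 3600)
      times <- c(times, sort(stats::runif(k, edges[i], edges[i + 1])))
    }
    nev <- length(times)
    # --- positions and pulse parameters
    pos <- if (is.null(config$fixed_position))
      cbind(stats::runif(nev, 0, geo$frame_w_cm),
            stats::runif(nev, 0, geo$frame_h_cm))
    else
      matrix(rep(config$fixed_position, each = nev), nev, 2L)
    wcf <- config$whoop
    f0 <- stats::rnorm(nev, wcf$f0_mean, wcf$f0_sd)
    f0 <- pmin(pmax(f0, wcf$f0_range[1]), wcf$f0_range[2])
    dur <- stats::runif(nev, wcf$duration_range[1], wcf$duration_range[2])
    # --- confounder schedule
    ctimes <- list()
    for (cls in names(config$confounder_rate)) {
      k <- stats::rpois(1, config$confounder_rate[[cls]] *
                             config$duration_s / 3600)
      ctimes[[cls]] <- sort(stats::runif(k, 0, config$duration_s))
    }
    ncf <- sum(lengths(ctimes))
    cpos <- if (is.null(config$fixed_position))
      cbind(stats::runif(ncf, 0, geo$frame_w_cm),
            stats::runif(ncf, 0, geo$frame_h_cm))
    else
      matrix(rep(config$fixed_position, each = ncf), ncf, 2L)
    render <- !isFALSE(config$render_audio)
    # --- assemble channels
    xs <- matrix(0, n, nrow(sensors))
    truth <- list()
    addPulse <- function(x, w, center) {
      a <- round(center * rate) - length(w) %/% 2L
      b <- a + length(w) - 1L
      wa <- max(1L, a); wb <- min(n, b) # clip pulses straddling the edges
      if (wa > wb) return(x)
      x[wa:wb] <- x[wa:wb] + w[(wa - a + 1L):(wb - a + 1L)]
      x
    }
    for (e in seq_len(nev)) {
      d <- sqrt(colSums((t(sensors) - pos[e, ])^2))
      amp <- a0 * exp(-d / lam)
      supra <- amp >= thr * (1 - 1e-9) # tolerance: sources exactly at radius
      if (render && any(supra)) {
        w <- synthWhoop(f0[e], dur[e], wcf$harmonic_ratios,
                        wcf$glide_extent, wcf$glide_time, amplitude = a0,
                        rate = rate)
        for (s in which(supra))
          xs[, s] <- addPulse(xs[, s], w * exp(-d[s] / lam), times[e])
      }
      truth[[length(truth) + 1L]] <- data.frame(
        event_id = e, timestamp = t0 + times[e],
        channel = rownames(sensors), event_class = "whoop",
        f0 = f0[e], duration = dur[e], amplitude = amp,
        supra = supra, co_detected = all(supra),
        stringsAsFactors = FALSE)
    }
    ci <- 0L
    for (cls in names(ctimes)) {
      short <- sub("worker_pipe_.*", "worker_pipe", cls)
      for (tcf in ctimes[[cls]]) {
        ci <- ci + 1L
        d <- sqrt(colSums((t(sensors) - cpos[ci, ])^2))
        amp <- a0 * exp(-d / lam)
        supra <- amp >= thr * (1 - 1e-9) # tolerance: sources exactly at radius
        if (render) {
          w <- synthConfounder(cls, rate, amplitude = a0,
                               duration = stats::runif(1, 0.5, 2))
          if (any(supra))
            for (s in which(supra))
              xs[, s] <- addPulse(xs[, s], w * exp(-d[s] / lam), tcf)
          cdur <- length(w) / rate
        } else cdur <- NA_real_
        truth[[length(truth) + 1L]] <- data.frame(
          event_id = nev + ci, timestamp = t0 + tcf,
          channel = rownames(sensors), event_class = short,
          f0 = NA_real_, duration = cdur, amplitude = amp,
          supra = supra, co_detected = all(supra),
          stringsAsFactors = FALSE)
      }
    }
    if (render) for (s in seq_len(ncol(xs)))
      xs[, s] <- xs[, s] +
        synthBackground(config$duration_s, rate,
                        config$background$hum_freq, config$background$hum_bw,
                        config$background$hum_level,
                        config$background$noise_level)[seq_len(n)]
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(event_id = integer(0), timestamp = numeric(0),
                 channel = character(0), event_class = character(0),
                 f0 = numeric(0), duration = numeric(0),
                 amplitude = numeric(0), supra = logical(0),
                 co_detected = logical(0), stringsAsFactors = FALSE)
    truth <- truth[order(truth$channel, truth$timestamp), , drop = FALSE]
    rownames(truth) <- NULL
    rec <- Recording(xs, rate, rownames(sensors),
                     startEpoch = config$start_epoch, tz = config$tz)
    new("SynthSession", recording = rec, truth = truth,
        seed = as.integer(seed), config = config)
  })
}

#' Build the default whoop template from synthetic exemplars
#'
#' Synthesises \code{n} whoops with jittered fundamentals over a hum+noise
#' background, computes their background-subtracted log-spectrogram
#' patches centred on the pulse, and averages them into a
#' \linkS4class{PulseTemplate}.
#'
#' @param rate samples/s.
#' @param n number of exemplars (default 20).
#' @param f0Mean,f0Jitter exemplar fundamentals drawn uniformly in
#'   f0Mean +/- f0Jitter (defaults 380 and 30 Hz).
#' @param duration exemplar duration, s (default 0.1).
#' @param nFrames template length in frames (default 24, ~0.14 s at the
#'   default hop).
#' @param snrDb exemplar SNR over the background (default 20 dB: clean
#'   labelled clips).
#' @param seed RNG seed for the exemplar draw.
#' @param config pipeline config (STFT band and parameters).
#' @return a \linkS4class{PulseTemplate}.
#' @export
makeWhoopTemplate <- function(rate = 22050, n = 20L, f0Mean = 380,
                              f0Jitter = 30, duration = 0.1, nFrames = 24L,
                              snrDb = 20, seed = 99L,
                              config = defaultPipelineConfig()) {
  .with_seed(seed, {
    f0s <- stats::runif(n, f0Mean - f0Jitter, f0Mean + f0Jitter)
    patches <- vector("list", n)
    meta <- NULL
    for (i in seq_len(n)) {
      p <- .synth_patch(synthWhoop(f0s[i], duration, rate = rate), rate,
                        nFrames, snrDb, config)
      patches[[i]] <- p$patch
      meta <- p
    }
    buildTemplate(patches, meta$freqs, meta$windowS, meta$hopS)
  })
}

# place a pulse at the centre of a 2 s background segment at the requested
# peak SNR, and return its background-subtracted log patch of nFrames
# frames centred on the pulse
.synth_patch <- function(w, rate, nFrames, snrDb,
                         config = defaultPipelineConfig(), segS = 2) {
  bgc <- config$simulate$background %||%
    list(hum_freq = 125, hum_bw = 20, hum_level = 0.01, noise_level = 0.005)
  sigma <- sqrt(bgc$hum_level^2 + bgc$noise_level^2)
  amp <- 10^(snrDb / 20) * sigma
  x <- synthBackground(segS, rate, bgc$hum_freq, bgc$hum_bw,
                       bgc$hum_level, bgc$noise_level)
  a <- round(length(x) / 2) - length(w) %/% 2L
  x[a:(a + length(w) - 1L)] <- x[a:(a + length(w) - 1L)] +
    w * amp / max(abs(w))
  rec <- Recording(x, rate)
  spec <- stftLogSpectrogram(rec, 1L, config$stft$window_s,
                             config$stft$hop_s, config$stft$band_hz,
                             config$stft$epsilon)
  spec <- subtractBackground(spec, min(config$background$window_s, segS / 2))
  centerT <- (a - 1 + length(w) / 2) / rate
  jc <- which.min(abs(spec@times - centerT))
  j0 <- max(1L, min(jc - (nFrames - 1L) %/% 2L, ncol(spec@values) - nFrames + 1L))
  list(patch = spec@values[, j0:(j0 + nFrames - 1L), drop = FALSE],
       freqs = spec@freqs, windowS = spec@windowS, hopS = spec@hopS)
}

#' Synthesise labelled training patches
#'
#' Generates \code{nPerClass} pulses of each requested class over the
#' default background at the given SNR and returns their
#' background-subtracted log-spectrogram patches plus labels; the material
#' for training and evaluating the second-pass classifier.
#'
#' @param nPerClass pulses per class.
#' @param classes classes to draw (default whoop and droplet).
#' @param rate samples/s.
#' @param snrDb peak SNR over the background RMS (default 10 dB).
#' @param nFrames patch length in frames (default 24).
#' @param seed RNG seed.
#' @param config pipeline config.
#' @return list: patches (bins x frames x n array), labels (character),
#'   f0 (NA for non-whoops), duration.
#' @export
synthLabeledPatches <- function(nPerClass = 100L,
                                classes = c("whoop", "droplet"),
                                rate = 22050, snrDb = 10, nFrames = 24L,
                                seed = 1L,
                                config = defaultPipelineConfig()) {
  .with_seed(seed, {
    total <- nPerClass * length(classes)
    labels <- rep(classes, each = nPerClass)
    f0 <- rep(NA_real_, total)
    dur <- rep(NA_real_, total)
    patches <- NULL
    for (i in seq_len(total)) {
      if (labels[i] == "whoop") {
        f0[i] <- min(max(stats::rnorm(1, 380, 40), 200), 500)
        dur[i] <- stats::runif(1, 0.05, 0.2)
        w <- synthWhoop(f0[i], dur[i], rate = rate)
      } else {
        w <- synthConfounder(labels[i], rate,
                             duration = stats::runif(1, 0.5, 2))
        dur[i] <- length(w) / rate
      }
      p <- .synth_patch(w, rate, nFrames, snrDb, config)
      if (is.null(patches))
        patches <- array(0, c(dim(p$patch), total))
      patches[, , i] <- p$patch
    }
    list(patches = patches, labels = labels, f0 = f0, duration = dur)
  })
}

#' Score detections against a session's ground truth
#'
#' Greedy nearest-time matching (the same machinery as the duplication
#' analysis) of detected events to truth rows per channel. Detections
#' matching a supra-threshold whoop are true positives; detections
#' matching any other truth row (confounders, or pulses below the
#' audibility threshold) are ignored; unmatched detections are false
#' positives. Recall is counted over supra-threshold whoop truth rows.
#'
#' @param session a \linkS4class{SynthSession}.
#' @param events data.frame with \code{time} and \code{channel} (e.g.
#'   \code{candidateEvents(detect(...))}), optionally pre-filtered to
#'   classified whoops.
#' @param tolS match tolerance, s (default 0.075: covers the worst-case offset between the matched-window centre and the true pulse centre when the pulse outlasts the template, while staying below the peak-separation floor).
#' @return list: tp, fp, fn, precision, recall.
#' @export
scoreDetections <- function(session, events, tolS = 0.075) {
  truth <- session@truth
  tp <- fp <- fn <- 0L
  for (ch in unique(c(truth$channel, events$channel))) {
    tt <- truth[truth$channel == ch, , drop = FALSE]
    tt <- tt[order(tt$timestamp), , drop = FALSE]
    det <- sort(events$time[events$channel == ch])
    # match detections against the target class first, so a detection of a
    # supra-threshold whoop cannot be claimed by a nearby sub-threshold
    # event whose truth timestamp happens to sit marginally closer
    isTarget <- tt$event_class == "whoop" & tt$supra
    target <- tt$timestamp[isTarget]
    m <- matchDuplicates(target, det, tolS)
    tp <- tp + nrow(m$pairs)
    fn <- fn + sum(isTarget) - nrow(m$pairs)
    # a leftover detection inside any truth event's span (long confounders
    # fire the first pass at several lags) is ignored, not a false positive
    loose <- det[!det %in% m$pairs$time_b]
    inSpan <- vapply(loose, function(t)
      any(abs(t - tt$timestamp) <= tt$duration / 2 + tolS), logical(1))
    fp <- fp + sum(!inSpan)
  }
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
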