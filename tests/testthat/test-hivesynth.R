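test_that("synthWhoop closure: 355 Hz / 60 ms recovered by the estimators", {
  w <- synthWhoop(355, 0.06)
  seg <- c(numeric(2000), w, numeric(2000))
  expect_lt(abs(estimateFundamental(seg, 22050)$f0 - 355), 2)
  expect_lt(abs(measureDuration(seg, 22050)$duration - 0.06), 0.010)
  expect_equal(length(w), round(0.06 * 22050))
  expect_equal(max(abs(w)), 1)
})

test_that("zero upper harmonic ratios give a pure tone", {
  w <- synthWhoop(400, 0.1, c(1, 0, 0), glideExtent = 0)
  h <- harmonicProfile(w, 22050, 400)
  expect_lt(h[2] / h[1], 0.01)
  expect_lt(h[3] / h[1], 0.01)
})

test_that("glide: instantaneous frequency rises at onset, falls at offset", {
  rate <- 22050
  w <- synthWhoop(400, 0.1, c(1, 0, 0), glideExtent = 50,
                  glideTime = 0.005, rate = rate)
  f <- oracleInstFreq(w, rate)
  n <- length(f)
  onset <- f[seq(round(0.0002 * rate), round(0.004 * rate))]
  mid <- f[seq(round(0.03 * rate), round(0.07 * rate))]
  offset <- f[seq(n - round(0.004 * rate), n - round(0.0002 * rate))]
  expect_lt(abs(mean(mid) - 400), 3)
  expect_lt(mean(onset), mean(mid) - 15)
  expect_lt(mean(offset), mean(mid) - 15)
})

test_that("synthWhoop validates its parameters", {
  expect_error(synthWhoop(4000, 0.1), "Nyquist")
  expect_error(synthWhoop(300, 0.005, glideTime = 0.004), "duration")
  expect_error(synthWhoop(300, 0.1, c(1, 0.5, 0.6)), "harmonicRatios")
})

test_that("worker pipe sweep rises 100 to 200 Hz", {
  w <- synthConfounder("worker_pipe_sweep", duration = 1)
  rec <- Recording(matrix(w), 22050)
  spec <- stftLogSpectrogram(rec, band = c(50, 500))
  ridge <- specFreqs(spec)[apply(specValues(spec), 2, which.max)]
  nf <- length(ridge)
  early <- mean(ridge[seq(2, nf %/% 4)])
  late <- mean(ridge[seq(3 * nf %/% 4, nf - 1)])
  expect_lt(abs(early - 125), 30)
  expect_lt(abs(late - 190), 30)
  expect_gt(late, early + 40)
})

test_that("droplet is a sub-20 ms transient; spike is near-instant", {
  set.seed(71)
  d <- synthConfounder("droplet")
  expect_lt(length(d) / 22050, 0.020)
  s <- synthConfounder("spike")
  expect_lt(length(s) / 22050, 0.005)
  expect_error(synthConfounder("meteor"), "unknown confounder")
})

test_that("queen toot is a pulse train near 400 Hz", {
  set.seed(72)
  w <- synthConfounder("queen_toot")
  f <- estimateFundamental(w[1:round(0.12 * 22050)], 22050,
                           searchBand = c(150, 600))
  expect_lt(abs(f$f0 - 400), 25)
})

test_that("background spectrum peaks at 125 Hz; zero levels are silent", {
  set.seed(73)
  x <- synthBackground(5, 22050)
  spec <- stftLogSpectrogram(Recording(matrix(x), 22050), band = c(50, 500))
  pk <- specFreqs(spec)[which.max(rowMeans(specValues(spec)))]
  expect_lt(abs(pk - 125), 5)
  expect_true(all(synthBackground(1, 22050, humLevel = 0,
                                  noiseLevel = 0) == 0))
})

test_that("background component levels hit their target RMS", {
  set.seed(74)
  hum <- synthBackground(10, 22050, humLevel = 0.01, noiseLevel = 0)
  expect_equal(sqrt(mean(hum^2)), 0.01, tolerance = 1e-6)
  pink <- synthBackground(10, 22050, humLevel = 0, noiseLevel = 0.005)
  expect_equal(sqrt(mean(pink^2)), 0.005, tolerance = 1e-6)
})

test_that("identical seed and config give bit-identical sessions", {
  cfg <- synthSessionConfig(duration_s = 10)
  s1 <- synthSession(cfg, seed = 42)
  s2 <- synthSession(cfg, seed = 42)
  expect_identical(samples(sessionRecording(s1)),
                   samples(sessionRecording(s2)))
  expect_identical(truthLog(s1), truthLog(s2))
  s3 <- synthSession(cfg, seed = 43)
  expect_false(identical(samples(sessionRecording(s1)),
                         samples(sessionRecording(s3))))
})

test_that("zero rate schedule gives background only and empty truth", {
  cfg <- synthSessionConfig(duration_s = 5, hourly_rate = rep(0, 24),
                            confounder_rate = c(droplet = 0,
                                                worker_pipe_sweep = 0,
                                                worker_pipe_flat = 0,
                                                queen_toot = 0, spike = 0))
  ses <- synthSession(cfg, seed = 44)
  expect_equal(nrow(truthLog(ses)), 0L)
  expect_gt(stats::sd(samples(sessionRecording(ses))[, 1]), 0)
})

test_that("truth invariants hold on a default session", {
  tt <- truthLog(fxSession60())
  expect_true(all(tt$timestamp >= 0 & tt$timestamp <= 60))
  wh <- tt[tt$event_class == "whoop", ]
  expect_true(all(wh$f0 >= 200 & wh$f0 <= 500))
  expect_true(all(wh$duration >= 0.05 & wh$duration <= 0.2))
  expect_true(all(tt$amplitude > 0))
  # co_detected consistent across the two channel rows of each event
  agg <- tapply(tt$supra, tt$event_id, all)
  expect_equal(unname(tapply(tt$co_detected, tt$event_id, unique)[
    names(agg)]), unname(agg))
})

test_that("all events at the sensor midpoint are co-detected (100%)", {
  cfg <- synthSessionConfig(duration_s = 600, rate = 100,
                            fixed_position = c(17.5, 10.5),
                            hourly_rate = rep(600, 24),
                            confounder_rate = c(droplet = 0,
                                                worker_pipe_sweep = 0,
                                                worker_pipe_flat = 0,
                                                queen_toot = 0, spike = 0),
                            render_audio = FALSE)
  ses <- synthSession(cfg, seed = 45)
  tt <- truthLog(ses)
  expect_gt(nrow(tt), 50)
  expect_true(all(tt$supra))
  expect_true(all(tt$co_detected))
  a <- sort(tt$timestamp[tt$channel == "central"])
  b <- sort(tt$timestamp[tt$channel == "peripheral"])
  m <- matchDuplicates(a, b, 0.010)
  pct <- duplicationPercentage(m, a, b)
  expect_true(all(pct$pct == 100))
})

test_that("co-detected fraction matches the geometric overlap oracle", {
  cfg <- synthSessionConfig(duration_s = 600, rate = 100, radius_cm = 5,
                            hourly_rate = rep(36000, 24),
                            confounder_rate = c(droplet = 0,
                                                worker_pipe_sweep = 0,
                                                worker_pipe_flat = 0,
                                                queen_toot = 0, spike = 0),
                            render_audio = FALSE)
  ses <- synthSession(cfg, seed = 46)
  tt <- truthLog(ses)
  tt <- tt[tt$channel == "central", ] # one row per event
  geo <- cfg$geometry
  pGeo <- oracleCoFraction(geo$frame_w_cm, geo$frame_h_cm, geo$sensors, 5)
  pObs <- mean(tt$co_detected)
  n <- nrow(tt)
  tol <- 4 * sqrt(pGeo * (1 - pGeo) / n)
  expect_lt(abs(pObs - pGeo), tol)
  # and each sensor's audible fraction matches its single-disc area
  for (ch in c("central", "peripheral")) {
    pDisc <- oracleCoFraction(geo$frame_w_cm, geo$frame_h_cm,
                              geo$sensors[ch, , drop = FALSE], 5)
    pS <- mean(truthLog(ses)$supra[truthLog(ses)$channel == ch])
    expect_lt(abs(pS - pDisc), 4 * sqrt(pDisc * (1 - pDisc) / n))
  }
})

test_that("default radius 3.5 with 7 cm spacing gives ~no co-detection", {
  cfg <- synthSessionConfig(duration_s = 600, rate = 100,
                            hourly_rate = rep(18000, 24),
                            confounder_rate = c(droplet = 0,
                                                worker_pipe_sweep = 0,
                                                worker_pipe_flat = 0,
                                                queen_toot = 0, spike = 0),
                            render_audio = FALSE)
  ses <- synthSession(cfg, seed = 47)
  tt <- truthLog(ses)
  expect_equal(mean(tt$co_detected), 0) # discs touch at a single point
})

test_that("makeWhoopTemplate is deterministic and correctly shaped", {
  t1 <- fxTemplate()
  t2 <- makeWhoopTemplate()
  expect_identical(t1@patch, t2@patch)
  expect_equal(ncol(t1@patch), 24L)
  expect_equal(mean(t1@patch), 0, tolerance = 1e-12)
})

test_that("scoreDetections arithmetic on a constructed case", {
  ses <- fxSession60()
  tt <- truthLog(ses)
  wh <- tt[tt$event_class == "whoop" & tt$supra & tt$channel == "central", ]
  # feed the truth back: perfect recall and precision
  ev <- data.frame(time = wh$timestamp, channel = "central")
  s <- scoreDetections(ses, ev)
  expect_equal(s$recall,
               nrow(wh) / sum(tt$event_class == "whoop" & tt$supra))
  expect_equal(s$precision, 1)
  # one spurious detection in the widest gap between events is a FP
  ts <- sort(tt$timestamp[tt$channel == "central"])
  gap <- which.max(diff(ts))
  ev2 <- rbind(ev, data.frame(time = (ts[gap] + ts[gap + 1]) / 2,
                              channel = "central"))
  s2 <- scoreDetections(ses, ev2)
  expect_equal(s2$fp, 1L)
})
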