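test_that("buildTemplate: single exemplar equals itself zero-meaned", {
  set.seed(21)
  m <- matrix(stats::runif(32 * 8), 32, 8)
  tpl <- buildTemplate(list(m), freqs = seq_len(32) * 43.066,
                       windowS = 512 / 22050, hopS = 128 / 22050)
  expect_equal(tpl@patch, m - mean(m))
  expect_equal(mean(tpl@patch), 0)
})

test_that("buildTemplate: identical exemplars average to the same template", {
  set.seed(22)
  m <- matrix(stats::runif(32 * 8), 32, 8)
  t1 <- buildTemplate(list(m), seq_len(32), 0.02, 0.005)
  t2 <- buildTemplate(list(m, m, m), seq_len(32), 0.02, 0.005)
  expect_equal(t2@patch, t1@patch)
})

test_that("buildTemplate rejects shape mismatches naming the exemplar", {
  a <- matrix(0, 4, 3); b <- matrix(0, 4, 5)
  expect_error(buildTemplate(list(a, b), 1:4, 0.02, 0.005), "exemplar 2")
})

test_that("default template ridge sits at the exemplar mean f0", {
  tpl <- fxTemplate()
  prof <- rowMeans(tpl@patch)
  ridge <- tpl@freqs[which.max(prof)]
  expect_lt(abs(ridge - 380), 45) # within one STFT bin of 380 Hz
})

test_that("criterion peaks at the lag of an embedded template copy", {
  set.seed(23)
  tpl <- fxTemplate()
  nb <- nrow(tpl@patch); nf <- ncol(tpl@patch)
  vals <- matrix(stats::runif(nb * 300, 0, 2), nb, 300)
  at <- 137L
  vals[, at:(at + nf - 1L)] <- vals[, at:(at + nf - 1L)] + 10 * tpl@patch
  spec <- new("Spectrogram", values = vals, freqs = tpl@freqs,
              times = (seq_len(300) - 1) * tpl@hopS, windowS = tpl@windowS,
              hopS = tpl@hopS)
  mc <- matchingCriterion(spec, tpl)
  expect_equal(which.max(mc$criterion), at)
})

test_that("fast matching equals the per-lag brute-force oracle", {
  set.seed(24)
  tpl <- fxTemplate()
  nb <- nrow(tpl@patch)
  S <- matrix(stats::runif(nb * 400, 0, 30), nb, 400)
  spec <- new("Spectrogram", values = S, freqs = tpl@freqs,
              times = (seq_len(400) - 1) * tpl@hopS, windowS = tpl@windowS,
              hopS = tpl@hopS)
  mc <- matchingCriterion(spec, tpl)
  orc <- oracleMatch(S, tpl@patch)
  expect_equal(mc$xc, orc$xc, tolerance = 1e-9)
  expect_equal(mc$ed, orc$ed, tolerance = 1e-9)
  C <- (orc$xc / stats::median(abs(orc$xc))) /
       (orc$ed / stats::median(orc$ed) + 1e-3)
  expect_equal(mc$criterion, C, tolerance = 1e-9)
})

test_that("constant spectrogram yields zero criterion with a warning", {
  tpl <- fxTemplate()
  vals <- matrix(5, nrow(tpl@patch), 100)
  spec <- new("Spectrogram", values = vals, freqs = tpl@freqs,
              times = (seq_len(100) - 1) * tpl@hopS, windowS = tpl@windowS,
              hopS = tpl@hopS)
  expect_warning(mc <- matchingCriterion(spec, tpl), "constant")
  expect_true(all(mc$criterion == 0))
})

test_that("band-mismatched spectrogram is rejected", {
  tpl <- fxTemplate()
  spec <- new("Spectrogram", values = matrix(0, 5, 50), freqs = 1:5,
              times = (1:50) * 0.005, windowS = 0.02, hopS = 0.005)
  expect_error(matchingCriterion(spec, tpl), "band")
})

test_that("pickCandidates keeps the higher of two close peaks", {
  tpl <- fxTemplate()
  n <- 60L
  C <- rep(1, n)
  C[30] <- 20; C[34] <- 15 # ~23 ms apart at the default hop
  times <- (seq_len(n) - 1) * tpl@hopS
  mc <- list(criterion = C, times = times, nFrames = ncol(tpl@patch))
  vals <- matrix(0, nrow(tpl@patch), n + ncol(tpl@patch))
  spec <- new("Spectrogram", values = vals, freqs = tpl@freqs,
              times = (seq_len(ncol(vals)) - 1) * tpl@hopS,
              windowS = tpl@windowS, hopS = tpl@hopS)
  cs <- pickCandidates(mc, spec, tpl, threshold = 10,
                       minSeparationS = 0.1)
  expect_equal(nrow(candidateEvents(cs)), 1L)
  expect_equal(candidateEvents(cs)$criterion, 20)
  # with a smaller separation both survive
  cs2 <- pickCandidates(mc, spec, tpl, threshold = 10,
                        minSeparationS = 0.01)
  expect_equal(nrow(candidateEvents(cs2)), 2L)
})

test_that("pickCandidates returns patches matching the template shape", {
  cs <- fxDetect60()
  d <- dim(candidatePatches(cs))
  expect_equal(d[1:2], dim(fxTemplate()@patch))
  expect_equal(d[3], nrow(candidateEvents(cs)))
  expect_true(all(candidateEvents(cs)$criterion > 0))
})

test_that("silence yields an empty candidate set", {
  rec <- Recording(matrix(0, 22050 * 20, 1), 22050)
  cs <- suppressWarnings(detect(rec, fxTemplate(), defaultPipelineConfig()))
  expect_equal(nrow(candidateEvents(cs)), 0L)
})

test_that("pure background stays within the false-positive budget", {
  set.seed(25)
  x <- synthBackground(600, 22050)
  rec <- Recording(matrix(x), 22050)
  cs <- detect(rec, fxTemplate(), defaultPipelineConfig())
  expect_lte(nrow(candidateEvents(cs)), 6L) # <= 6 per hour budget, on 1/6 h
})

test_that("100 injected whoops at 10 dB SNR: >= 95 recovered within 20 ms", {
  set.seed(26)
  rate <- 22050
  x <- synthBackground(600, rate)
  sigma <- sqrt(0.01^2 + 0.005^2)
  amp <- 10^(10 / 20) * sigma
  centers <- 3 + (0:99) * 5.97
  for (tc in centers) {
    w <- synthWhoop(stats::runif(1, 350, 410), 0.1, amplitude = amp,
                    rate = rate)
    a <- round(tc * rate) - length(w) %/% 2
    x[a:(a + length(w) - 1)] <- x[a:(a + length(w) - 1)] + w
  }
  cs <- detect(Recording(matrix(x), rate), fxTemplate(),
               defaultPipelineConfig())
  det <- candidateEvents(cs)$time
  hit <- vapply(centers, function(tc) any(abs(det - tc) <= 0.020),
                logical(1))
  expect_gte(sum(hit), 95)
})

test_that("criterion and detections are invariant to a global gain", {
  ses <- fxSession60()
  rec <- sessionRecording(ses)
  rec10 <- Recording(samples(rec) * 10, sampleRate(rec), channelNames(rec),
                     startEpoch(rec), recTimezone(rec))
  cs1 <- fxDetect60()
  cs2 <- detect(rec10, fxTemplate(), defaultPipelineConfig())
  expect_equal(candidateEvents(cs2)$time, candidateEvents(cs1)$time)
  expect_equal(candidateEvents(cs2)$criterion,
               candidateEvents(cs1)$criterion, tolerance = 1e-8)
})

test_that("recall is monotone non-increasing in added noise power", {
  ses <- fxSession60()
  rec <- sessionRecording(ses)
  recall_at <- function(noiseSd) {
    set.seed(27)
    m <- samples(rec) + matrix(stats::rnorm(length(samples(rec)),
                                            sd = noiseSd),
                               nrow(samples(rec)))
    r <- Recording(m, sampleRate(rec), channelNames(rec))
    cs <- detect(r, fxTemplate(), defaultPipelineConfig())
    scoreDetections(ses, candidateEvents(cs))$recall
  }
  r0 <- scoreDetections(ses, candidateEvents(fxDetect60()))$recall
  r1 <- recall_at(0.02)
  r2 <- recall_at(0.1)
  expect_lte(r1, r0 + 1e-9)
  expect_lte(r2, r1 + 1e-9)
})

test_that("chunked detection equals monolithic detection exactly", {
  ses <- fxSession60()
  cfg <- defaultPipelineConfig()
  mono <- fxDetect60()
  chunk <- detectChunked(sessionRecording(ses), fxTemplate(), cfg,
                         chunkS = 13)
  expect_equal(candidateEvents(chunk), candidateEvents(mono))
  expect_equal(candidatePatches(chunk), candidatePatches(mono))
})

test_that("chunked detection from a WAV path matches in-memory detection", {
  ses <- fxSession60()
  p <- withr_tempfile(".wav")
  writeRecording(sessionRecording(ses), p)
  cfg <- defaultPipelineConfig()
  disk <- detectChunked(p, fxTemplate(), cfg, chunkS = 17,
                        channelNames = channelNames(sessionRecording(ses)))
  mono <- fxDetect60()
  # float32 storage perturbs samples at 1e-8 relative; times must agree
  expect_equal(candidateEvents(disk)$time, candidateEvents(mono)$time)
  expect_equal(candidateEvents(disk)$criterion,
               candidateEvents(mono)$criterion, tolerance = 1e-4)
})
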