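test_that("one event at 13:30 local lands in cell (day, 13)", {
  ts <- as.numeric(as.POSIXct("2016-07-03 13:30:00", tz = "UTC"))
  m <- occurrenceMatrix(data.frame(timestamp = ts), timezone = "UTC")
  expect_equal(sum(m), 1L)
  expect_equal(m["2016-07-03", "13"], 1L)
})

test_that("empty log gives a zero matrix", {
  m <- occurrenceMatrix(data.frame(timestamp = numeric(0)))
  expect_equal(sum(m), 0L)
})

test_that("events outside the date range are excluded with a message", {
  ts <- as.numeric(as.POSIXct(c("2016-07-01 05:00:00",
                                "2016-07-09 05:00:00"), tz = "UTC"))
  expect_message(
    m <- occurrenceMatrix(data.frame(timestamp = ts),
                          dateRange = c("2016-07-01", "2016-07-02")),
    "excluded")
  expect_equal(sum(m), 1L)
})

test_that("10^4 uniform timestamps match the brute-force recount", {
  set.seed(61)
  ts <- stats::runif(1e4, 0, 5 * 86400)
  m <- occurrenceMatrix(data.frame(timestamp = ts), timezone = "UTC")
  orc <- oracleOccurrence(ts, "UTC")
  expect_equal(m, orc)
  expect_equal(sum(m), 10000L) # conservation
})

test_that("aggregation is permutation-invariant in input order", {
  set.seed(62)
  ts <- stats::runif(500, 0, 2 * 86400)
  m1 <- occurrenceMatrix(data.frame(timestamp = ts))
  m2 <- occurrenceMatrix(data.frame(timestamp = sample(ts)))
  expect_equal(m2, m1)
})

test_that("hour bucketing follows local civil time", {
  ts <- as.numeric(as.POSIXct("2016-07-03 23:30:00", tz = "UTC"))
  m <- occurrenceMatrix(data.frame(timestamp = ts),
                        timezone = "Europe/London") # UTC+1 in July
  expect_equal(m["2016-07-04", "0"], 1L)
})

test_that("hourly profile: constant schedule has SE 0", {
  occ <- matrix(5L, 4, 24, dimnames = list(paste0("d", 1:4), 0:23))
  p <- hourlyProfile(occ)
  expect_equal(p$mean, rep(5, 24))
  expect_equal(p$se, rep(0, 24))
})

test_that("hourly profile: 0/10 alternation over 2 days -> mean 5, SE 5", {
  occ <- rbind(rep(0L, 24), rep(10L, 24))
  rownames(occ) <- c("d1", "d2"); colnames(occ) <- 0:23
  p <- hourlyProfile(occ)
  expect_equal(p$mean, rep(5, 24))
  expect_equal(p$se, rep(5, 24)) # sd(c(0,10))/sqrt(2) = 5
})

test_that("single-day matrix has no SE", {
  occ <- matrix(1L, 1, 24, dimnames = list("d", 0:23))
  expect_true(all(is.na(hourlyProfile(occ)$se)))
})

test_that("generator schedule produces the midday dip in the profile", {
  cfg <- synthSessionConfig(
    duration_s = 3 * 86400, rate = 1,
    hourly_rate = synthSessionConfig()$hourly_rate / 100,
    confounder_rate = c(droplet = 0, worker_pipe_sweep = 0,
                        worker_pipe_flat = 0, queen_toot = 0, spike = 0),
    render_audio = FALSE)
  ses <- synthSession(cfg, seed = 63)
  tt <- truthLog(ses)
  tt <- tt[tt$channel == "central", ]
  occ <- occurrenceMatrix(data.frame(timestamp = tt$timestamp),
                          timezone = "UTC")
  p <- hourlyProfile(occ)
  expect_true(p$hour[which.min(p$mean)] %in% 11:14)
  # night rate roughly double the midday rate, as scheduled
  expect_gt(mean(p$mean[1:6]), 1.5 * min(p$mean))
})

test_that("profile of a circularly shifted schedule is the shifted profile", {
  set.seed(64)
  span <- 2 * 86400
  ts <- sort(stats::runif(2000, 0, span) %/% 1)
  p1 <- hourlyProfile(occurrenceMatrix(data.frame(timestamp = ts)))
  ts2 <- (ts + 5 * 3600) %% span
  p2 <- hourlyProfile(occurrenceMatrix(data.frame(timestamp = ts2)))
  expect_equal(p2$mean, p1$mean[((0:23 - 5) %% 24) + 1])
})

test_that("dailyMeanSpectrum: identical pulses reproduce their spectrum", {
  sp <- matrix(rep(c(1, 5, 2, 0.5), each = 6), 6, 4)
  ts <- as.numeric(as.POSIXct("2016-07-01 10:00", tz = "UTC")) +
    c(0, 3600, 86400, 86400 + 60, 2 * 86400, 2 * 86400 + 1)
  out <- dailyMeanSpectrum(sp, ts)
  expect_equal(nrow(out), 3L)
  for (r in 1:3) expect_equal(unname(out[r, ]), c(1, 5, 2, 0.5))
})

test_that("dailyMeanSpectrum: stable 380 Hz ridge and a bimodal day", {
  freqs <- seq(100, 600, by = 10)
  mk <- function(f0) exp(-(freqs - f0)^2 / 200)
  sp <- rbind(mk(380), mk(380), mk(350), mk(450))
  ts <- as.numeric(as.POSIXct("2016-07-01 10:00", tz = "UTC")) +
    c(0, 60, 86400, 86400 + 60)
  out <- dailyMeanSpectrum(sp, ts)
  expect_equal(freqs[which.max(out[1, ])], 380)
  # day 2 mixes 350/450: local maxima at both modes
  row2 <- out[2, ]
  i350 <- which(freqs == 350); i450 <- which(freqs == 450)
  expect_gt(row2[i350], row2[i350 + 2])
  expect_gt(row2[i450], row2[i450 - 2])
})

test_that("freqAmpHistograms: single record fills one bin per panel", {
  rec <- data.frame(timestamp = 3600 * 5 + 30, f0_hz = 382,
                    amplitude = 0.2)
  h <- freqAmpHistograms(rec)
  expect_equal(sum(h$f0_hist), 1L)
  expect_equal(sum(h$hour_amp), 1L)
  expect_equal(sum(h$day_f0), 1L)
  expect_equal(sum(h$hour_amp["5", ]), 1L)
})

test_that("freqAmpHistograms conserve the record count", {
  set.seed(65)
  n <- 700L
  rec <- data.frame(timestamp = stats::runif(n, 0, 3 * 86400),
                    f0_hz = pmin(pmax(stats::rnorm(n, 380, 40), 200), 500),
                    amplitude = exp(stats::rnorm(n)))
  h <- freqAmpHistograms(rec)
  expect_equal(sum(h$f0_hist), n)
  expect_equal(sum(h$hour_amp), n)
  expect_equal(sum(h$day_f0), n)
  # modal f0 bin within the 300-450 Hz range
  modal <- h$f0_breaks[which.max(h$f0_hist)]
  expect_true(modal >= 300 && modal <= 450)
})

test_that("modalAmplitudeDaily: constant noise gives a constant mode", {
  set.seed(66)
  rate <- 10
  n <- 2 * 86400 * rate
  x <- stats::rnorm(n, sd = 0.1)
  rec <- Recording(matrix(x), rate, "central")
  md <- modalAmplitudeDaily(rec)
  expect_equal(nrow(md), 2L)
  expect_lt(abs(log(md$mode[2] / md$mode[1])), log(1.3))
})

test_that("modalAmplitudeDaily: doubled amplitude doubles the mode", {
  set.seed(67)
  rate <- 10
  n <- 86400 * rate
  base <- stats::rnorm(n, sd = 0.1)
  x <- c(base, 2 * base)
  rec <- Recording(matrix(x), rate, "central")
  md <- modalAmplitudeDaily(rec)
  expect_lt(abs(log(md$mode[2] / md$mode[1] / 2)), log(1.3))
})

test_that("rankCorrelation: monotone 1, reversed -1, oracle at n=20", {
  x <- sort(stats::runif(10)); y <- x^3
  expect_equal(rankCorrelation(x, y)$rho, 1)
  expect_equal(rankCorrelation(x, rev(y))$rho, -1)
  set.seed(68)
  f0 <- sample(c(300, 350, 350, 380, 400, 420), 20, replace = TRUE)
  amp <- stats::runif(20)
  expect_equal(rankCorrelation(f0, amp)$rho, oracleSpearman(f0, amp),
               tolerance = 1e-12)
})

test_that("rankCorrelation flags constant input", {
  expect_warning(r <- rankCorrelation(rep(1, 5), stats::runif(5)),
                 "constant")
  expect_true(r$flagged)
  expect_true(is.na(r$rho))
})
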