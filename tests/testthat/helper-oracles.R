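# Independent brute-force oracles. Each re-derives a quantity from its
# definition with no shared code path with the implementation under test.

# per-lag template matching: excerpt zero-meaned, direct summation
oracleMatch <- function(S, Tm) {
  nF <- ncol(Tm)
  L <- ncol(S) - nF + 1L
  xc <- ed <- numeric(L)
  for (j in seq_len(L)) {
    E <- S[, j:(j + nF - 1L), drop = FALSE]
    E <- E - mean(E)
    xc[j] <- sum(Tm * E)
    ed[j] <- sqrt(sum((Tm - E)^2))
  }
  list(xc = xc, ed = ed)
}

# exhaustive O(n^2) nearest-match pairing, greedy by smallest |dt|,
# each event used once; ties broken by earlier A then B time
oraclePairs <- function(a, b, thr) {
  out <- data.frame(time_a = numeric(0), time_b = numeric(0),
                    dt = numeric(0))
  if (!length(a) || !length(b)) return(out)
  g <- expand.grid(i = seq_along(a), j = seq_along(b))
  g$dt <- a[g$i] - b[g$j]
  g <- g[abs(g$dt) < thr, , drop = FALSE]
  if (!nrow(g)) return(out)
  g <- g[order(abs(g$dt), a[g$i], b[g$j]), , drop = FALSE]
  usedA <- logical(length(a)); usedB <- logical(length(b))
  keep <- logical(nrow(g))
  for (r in seq_len(nrow(g))) {
    if (!usedA[g$i[r]] && !usedB[g$j[r]]) {
      keep[r] <- TRUE; usedA[g$i[r]] <- TRUE; usedB[g$j[r]] <- TRUE
    }
  }
  g <- g[keep, , drop = FALSE]
  o <- order(a[g$i])
  data.frame(time_a = a[g$i][o], time_b = b[g$j][o], dt = g$dt[o])
}

# Spearman's rho from the rank definition with average ranks for ties
oracleSpearman <- function(x, y) {
  rk <- function(v) vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# independent day x hour recount
oracleOccurrence <- function(timestamps, timezone) {
  lt <- as.POSIXlt(as.POSIXct(timestamps, origin = "1970-01-01",
                              tz = "UTC"), tz = timezone)
  days <- format(seq(as.Date(format(min(lt), "%Y-%m-%d")),
                     as.Date(format(max(lt), "%Y-%m-%d")), by = 1),
                 "%Y-%m-%d")
  m <- matrix(0L, length(days), 24L, dimnames = list(days, 0:23))
  for (i in seq_along(timestamps)) {
    d <- format(lt[i], "%Y-%m-%d")
    m[d, lt$hour[i] + 1L] <- m[d, lt$hour[i] + 1L] + 1L
  }
  m
}

# instantaneous frequency (Hz) from the analytic-signal phase derivative
oracleInstFreq <- function(x, rate) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2
  } else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  z <- stats::fft(X * h, inverse = TRUE) / n
  dphi <- diff(Arg(z))
  dphi <- (dphi + pi) %% (2 * pi) - pi
  dphi * rate / (2 * pi)
}

# fraction of the comb area audible to (>= radius of) both sensors,
# by grid quadrature
oracleCoFraction <- function(frameW, frameH, sensors, radius, step = 0.02) {
  xs <- seq(step / 2, frameW - step / 2, by = step)
  ys <- seq(step / 2, frameH - step / 2, by = step)
  g <- expand.grid(x = xs, y = ys)
  inAll <- rep(TRUE, nrow(g))
  for (s in seq_len(nrow(sensors))) {
    d <- sqrt((g$x - sensors[s, 1])^2 + (g$y - sensors[s, 2])^2)
    inAll <- inAll & d <= radius
  }
  mean(inAll)
}
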