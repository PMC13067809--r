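test_that("variance SNR follows the closed form", {
  set.seed(1)
  s <- rnorm(1000)
  expect_equal(snrVariance(s, s), 0)
  n <- rnorm(1000, sd = 1)
  expect_equal(snrVariance(n * 10, n), 20, tolerance = 1e-9)
  expect_equal(snrVariance(n * 2, n), 6.0206, tolerance = 1e-4)
  expect_error(snrVariance(s, rep(1, 100)), "zero variance")
  expect_error(snrVariance(numeric(0), s), "nonempty")
})

test_that("noise windows sit halfway between successive R peaks", {
  w <- ecgNoiseWindows(c(1.0, 2.0), width = 0.1, duration = 30)
  expect_equal(w$start, 1.45)
  expect_equal(w$end, 1.55)
  expect_warning(w1 <- ecgNoiseWindows(1.0), "fewer")
  expect_identical(nrow(w1), 0L)
  w30 <- ecgNoiseWindows(seq(0.5, by = 0.8, length.out = 30), duration = 30)
  expect_identical(nrow(w30), 29L)
  # windows crossing the record bounds are dropped
  wb <- ecgNoiseWindows(c(0.02, 0.06), width = 0.1, duration = 30)
  expect_identical(nrow(wb), 0L)
})

test_that("Welch PSD satisfies Parseval and localizes tones", {
  set.seed(2)
  fs <- 200
  y <- rnorm(20 * fs)
  ps <- welchPsd(y, fs)
  df <- ps$freq[2] - ps$freq[1]
  expect_lt(abs(sum(ps$psd) * df / var(y) - 1), 0.05)
  # deterministic signal: Parseval within 1%
  t <- (0:(20 * fs - 1)) / fs
  z <- 1.5 * sin(2 * pi * 2 * t)
  ps2 <- welchPsd(z, fs)
  expect_lt(abs(sum(ps2$psd) * df / mean(z^2) - 1), 0.01)
  expect_lt(abs(sum(ps2$psd) * df - 1.5^2 / 2), 0.05 * 1.5^2 / 2)
  expect_gt(bandPower(ps2$freq, ps2$psd, 0.5, 4) / (sum(ps2$psd) * df), 0.9)
  # zero signal -> all-zero density; short record errors
  expect_true(all(welchPsd(numeric(1000), fs)$psd == 0))
  expect_error(welchPsd(rnorm(100), fs), "shorter")
  expect_error(bandPower(ps$freq, ps$psd, 5, 5), "empty band")
})

test_that("band-power ratios are 1 for identity and small in a notched band", {
  set.seed(3)
  fs <- 200
  rec <- vecRecording(rnorm(60 * fs), fs)
  bp <- bandPowerRatio(rec, rec)
  expect_equal(bp$ratio, rep(1, nrow(bp)), tolerance = 1e-12)
  # strong 50 Hz tone notched out: 49-51 Hz ratio < 0.1
  t <- (0:(60 * fs - 1)) / fs
  x <- rnorm(60 * fs, sd = 0.1) + sin(2 * pi * 50 * t)
  raw <- vecRecording(x, fs)
  proc <- ecgChain(raw, "notch50")$recording
  b <- bandPowerRatio(raw, proc, bands = data.frame(name = "mains",
                                                    lo = 49, hi = 51))
  expect_lt(b$ratio, 0.1)
  # zero raw power in a band is flagged as NaN
  zero <- vecRecording(numeric(60 * fs), fs)
  tone30 <- vecRecording(sin(2 * pi * 30 * t), fs)
  expect_warning(bz <- bandPowerRatio(zero, tone30,
                                      bands = data.frame(name = "dc",
                                                         lo = 0.05, hi = 0.1)))
  expect_true(is.nan(bz$ratio))
})

test_that("baseline removal suppresses only the lowest band", {
  set.seed(9)
  fs <- 200
  rec <- vecRecording(rnorm(60 * fs), fs)
  st <- ecgChain(rec, "baseline_ma")$recording
  bp <- bandPowerRatio(rec, st)
  expect_lt(bp$ratio[bp$name == "motion"], 1)
  above5 <- bp$ratio[bp$lo >= 5]
  expect_true(all(abs(above5 - 1) < 0.05))
})

test_that("PPHG-model SNR exceeds the AgCl model at equal injected noise", {
  tpl <- beatTemplate()
  ns <- noiseSpec()
  pphg <- electrodeModel("PPHG")
  agcl <- electrodeModel("AgCl", noiseGain = pphg@noiseGain,
                         driftGain = pphg@driftGain)
  snrOf <- function(em, s) {
    rec <- synthesizeECG(tpl, 1, 60, 200, ns, em, seed = s)
    pp <- suppressMessages(ecgChain(rec, "full"))
    rt <- detectRPeaks(pp$recording)
    ecgSnrReport(pp$recording, rt)$snr_db
  }
  for (s in 1:3) expect_gt(snrOf(pphg, s), snrOf(agcl, s))
})

test_that("time-resolved delta power tracks stationarity and transitions", {
  fs <- 200
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 2 * t)
  dp <- deltaPowerTimeseries(x, fs)
  expect_identical(nrow(dp), 17L)                    # (10 - 2)/0.5 + 1
  expect_lt(diff(range(dp$power)) / mean(dp$power), 0.1)
  # tone only in the second half: half-mean ratio > 5
  x2 <- c(numeric(10 * fs) + rnorm(10 * fs, sd = 0.01),
          sin(2 * pi * 2 * t) + rnorm(10 * fs, sd = 0.01))
  dp2 <- deltaPowerTimeseries(x2, fs)
  firstHalf <- dp2$power[dp2$time < 9]
  secondHalf <- dp2$power[dp2$time > 11]
  expect_gt(mean(secondHalf) / mean(firstHalf), 5)
})

test_that("scalograms ridge at tone frequency and rise for a chirp", {
  fs <- 200
  t <- (0:(20 * fs - 1)) / fs
  sc <- scalogram(sin(2 * pi * 10 * t), fs)
  core <- sc$mag[, (2 * fs):(18 * fs)]
  ridge <- sc$freq[which.max(rowMeans(core))]
  step <- sc$freq[2] / sc$freq[1]
  expect_lt(abs(log(ridge / 10)), log(step) * 1.5)   # within one scale step
  expect_true(all(scalogram(numeric(1000), fs)$mag == 0))
  # chirp 2 -> 20 Hz: ridge frequency increases monotonically
  f0 <- 2; f1 <- 20; Tn <- 20
  chirp <- sin(2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * Tn)))
  scc <- scalogram(chirp, fs)
  mids <- seq(3 * fs, 17 * fs, by = 2 * fs)
  ridges <- vapply(mids, function(i) scc$freq[which.max(scc$mag[, i])],
                   numeric(1))
  expect_true(all(diff(ridges) > 0))
})
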