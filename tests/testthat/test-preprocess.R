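test_that("single ECG steps behave as designed filters", {
  fs <- 200
  t <- (0:(30 * fs - 1)) / fs
  # moving-average baseline removal of a constant leaves ~0 after warm-up
  const <- vecRecording(rep(1, length(t)), fs)
  out <- ecgChain(const, "baseline_ma")$recording
  expect_lt(max(abs(signalMatrix(out)[1, (fs + 1):length(t)])), 1e-6)
  # 50 Hz tone through the notch: steady-state RMS <= 0.1 x input RMS
  tone <- sin(2 * pi * 50 * t)
  out <- ecgChain(vecRecording(tone, fs), "notch50")$recording
  mid <- (2 * fs):(28 * fs)
  expect_lte(sqrt(mean(signalMatrix(out)[1, mid]^2)),
             0.1 * sqrt(mean(tone[mid]^2)))
  # 5 Hz tone through the 90 Hz low-pass: passband RMS within 2%
  tone5 <- sin(2 * pi * 5 * t)
  out <- ecgChain(vecRecording(tone5, fs), "lowpass")$recording
  expect_lt(abs(sqrt(mean(signalMatrix(out)[1, mid]^2)) /
                sqrt(mean(tone5[mid]^2)) - 1), 0.02)
  expect_error(ecgChain(vecRecording(tone, fs = 150)), "cutoff")
  expect_error(ecgChain(vecRecording(tone, fs), "nonsense"), "unknown")
})

test_that("full ECG chain equals the composition of its isolated steps", {
  rec <- synthesizeECG(beatTemplate(), leads = 1, duration = 30,
                       noise = noiseSpec(artifactRate = 0), seed = 8)
  full <- suppressMessages(ecgChain(rec, "full"))
  step <- ecgChain(rec, "lowpass")$recording
  step <- ecgChain(step, "notch50")$recording
  step <- ecgChain(step, "notch80")$recording
  step <- ecgChain(step, "baseline_ma")$recording
  keep <- full$mask@keep
  expect_equal(signalMatrix(full$recording)[1, keep],
               signalMatrix(step)[1, keep], tolerance = 1e-12)
})

test_that("clean signal passes the full ECG chain nearly unchanged", {
  # rrMean matched to the 1 s baseline window so the periodic train's
  # moving average vanishes (the record is AC-coupled by construction)
  rec <- cleanRecording(rrMean = 1.0, duration = 30, seed = 2)
  pp <- suppressMessages(ecgChain(rec, "full"))
  rAmp <- max(signalMatrix(rec)[1, ])
  core <- (3 * 200):(27 * 200)          # away from filter warm-up
  dev <- max(abs(signalMatrix(pp$recording)[1, core] -
                 signalMatrix(rec)[1, core]))
  expect_lt(dev, 0.01 * rAmp)
})

test_that("variance rejection flags bursts and spares clean records", {
  fs <- 200
  set.seed(42)
  x <- rnorm(60 * fs, sd = 0.05)
  burst <- (30 * fs + 1):(31 * fs)     # aligned inside one 2 s window
  x[burst] <- rnorm(length(burst), sd = 0.5)   # 10x amplitude burst
  mask <- suppressMessages(rejectBadSegments(vecRecording(x, fs)))
  expect_true(all(!mask@keep[burst]))
  expect_true(all(mask@reason[!mask@keep] == "variance"))
  # homogeneous noise at a high threshold: nothing rejected
  y <- rnorm(60 * fs, sd = 0.05)
  m2 <- suppressMessages(rejectBadSegments(vecRecording(y, fs), varianceZ = 8))
  expect_true(all(m2@keep))
  # all-zero signal: zero variance everywhere, nothing rejected
  m3 <- suppressMessages(rejectBadSegments(vecRecording(numeric(1000), fs)))
  expect_true(all(m3@keep))
  # impedance rule
  m4 <- suppressMessages(rejectBadSegments(
    vecRecording(y, fs), impedanceSeries = c(rep(1, 1000), rep(100, 11000)),
    impedanceThreshold = 50))
  expect_true(all(!m4@keep[1001:12000]))
  expect_true(all(m4@reason[1001:12000] == "impedance"))
})

test_that("EOG chain removes offsets and mains but keeps slow gaze steps", {
  fs <- 200
  t <- (0:(30 * fs - 1)) / fs
  # DC offset is removed
  out <- eogChain(vecRecording(rep(5, length(t)) + 0.01 * sin(2 * pi * t), fs))
  expect_lt(abs(mean(signalMatrix(out)[1, ])), 1e-3)
  # 0.3 Hz square-wave gaze: transition amplitude preserved within 20%
  sq <- ifelse(sin(2 * pi * 0.3 * t) > 0, 0.5, -0.5)
  out <- eogChain(vecRecording(sq, fs))
  y <- signalMatrix(out)[1, (2 * fs):(28 * fs)]
  expect_gt(max(y) - min(y), 0.8 * 1.0)
  # 50 Hz attenuated by >= 20 dB
  tone <- sin(2 * pi * 50 * t)
  out <- eogChain(vecRecording(tone, fs))
  att <- 20 * log10(sqrt(mean(tone^2)) /
                    sqrt(mean(signalMatrix(out)[1, (2*fs):(28*fs)]^2)))
  expect_gte(att, 20)
  expect_error(eogChain(vecRecording(rnorm(20), fs)), "too short")
})

test_that("EMG chain subtracts scaled cardiac templates and rejects 10 Hz", {
  fs <- 200
  rec <- cleanRecording(rrMean = 0.9, duration = 40, seed = 6)
  rt <- truthRTimes(rec)
  x <- signalMatrix(rec)[1, ]
  bp <- butterBandpass(x, 20, 90, fs)     # ECG content reaching the EMG band
  out <- emgChain(rec, rTimes = rt)
  y <- signalMatrix(out)[1, ]
  idx <- unlist(lapply(rt, function(r) {
    cc <- round(r * fs) + 1
    (cc - 20):(cc + 20)
  }))
  idx <- idx[idx >= 1 & idx <= length(x)]
  expect_lte(sqrt(mean(y[idx]^2)), 0.2 * sqrt(mean(bp[idx]^2)))
  # no R times: bandpass + notch + wavelet only
  out2 <- emgChain(rec, rTimes = numeric(0))
  ref <- waveletDenoise(butterNotch(butterBandpass(x, 20, 90, fs), 50, fs))
  expect_equal(signalMatrix(out2)[1, ], ref, tolerance = 1e-12)
  # < 3 r_times skips the template step with a warning
  expect_warning(emgChain(rec, rTimes = rt[1:2]), "skipped")
  # 10 Hz tone attenuated >= 20 dB by the 20-90 Hz bandpass
  t <- (0:(30 * fs - 1)) / fs
  tone <- sin(2 * pi * 10 * t)
  out3 <- emgChain(vecRecording(tone, fs))
  att <- 20 * log10(sqrt(mean(tone^2)) /
                    sqrt(mean(signalMatrix(out3)[1, (2*fs):(28*fs)]^2)))
  expect_gte(att, 20)
})

test_that("EEG chain detrends and low-passes as specified", {
  fs <- 200
  t <- (0:(30 * fs - 1)) / fs
  ramp <- 0.5 * t
  out <- eegChain(vecRecording(ramp, fs))
  slope <- coef(lm(signalMatrix(out)[1, ] ~ t))[2]
  expect_lt(abs(slope), 1e-6)
  mid <- (2 * fs):(28 * fs)
  alpha <- sin(2 * pi * 10 * t)
  out <- eegChain(vecRecording(alpha, fs))
  expect_lt(abs(sqrt(mean(signalMatrix(out)[1, mid]^2)) /
                sqrt(mean(alpha[mid]^2)) - 1), 0.05)
  hum <- sin(2 * pi * 60 * t)
  out <- eegChain(vecRecording(hum, fs))
  att <- 20 * log10(sqrt(mean(hum[mid]^2)) /
                    sqrt(mean(signalMatrix(out)[1, mid]^2)))
  expect_gte(att, 15)
})

test_that("chains preserve length and denoising never adds energy", {
  fs <- 200
  set.seed(11)
  x <- rnorm(4096)                         # zero-mean broadband input
  rec <- vecRecording(x, fs)
  for (f in list(function(r) suppressMessages(ecgChain(r, "full"))$recording,
                 eogChain, function(r) emgChain(r), eegChain)) {
    out <- f(rec)
    expect_identical(ncol(signalMatrix(out)), length(x))
  }
  xm <- x - mean(x)
  expect_lte(sum(waveletDenoise(xm)^2), sum(xm^2))
  expect_lte(sum(medianSmooth(xm, fs)^2), sum(xm^2))
  # rerunning a chain is deterministic
  expect_identical(signalMatrix(eogChain(rec)), signalMatrix(eogChain(rec)))
})

test_that("the db4 transform reconstructs perfectly without thresholding", {
  x <- sin(2 * pi * 3 * (1:1024) / 200) + 0.5 * cos(2 * pi * 7 * (1:1024) / 200)
  dec <- ElectrodeBench:::dwtPeriodic(x, 3)
  expect_equal(ElectrodeBench:::idwtPeriodic(dec), x, tolerance = 1e-9)
  # orthonormality: coefficient energy equals signal energy
  ce <- sum(dec$approx^2) + sum(vapply(dec$details, function(d) sum(d^2),
                                       numeric(1)))
  expect_equal(ce, sum(x^2), tolerance = 1e-9)
})
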