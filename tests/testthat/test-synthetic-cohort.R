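test_that("cohort templates are valid, distinct and seed-deterministic", {
  tpls <- sampleCohortTemplates(39, seed = 7)
  expect_length(tpls, 39)
  for (tp in tpls) expect_true(validObject(tp))
  rAmps <- vapply(tpls, function(tp) tp@waveParams["R", "amplitude"],
                  numeric(1))
  expect_equal(anyDuplicated(rAmps), 0L)
  # centers strictly ordered, widths positive (class validity re-checked)
  for (tp in tpls) {
    expect_true(all(diff(tp@waveParams[, "center"]) > 0))
    expect_true(all(tp@waveParams[, "width"] > 0))
    expect_gt(tp@rrMean,
              2 * (tp@waveParams["T", "center"] - tp@waveParams["P", "center"]))
  }
  expect_identical(sampleCohortTemplates(1, seed = 0),
                   sampleCohortTemplates(1, seed = 0))
  expect_error(sampleCohortTemplates(0), "count")
})

test_that("sampled RR means are consistent with the configured prior", {
  tpls <- sampleCohortTemplates(200, seed = 3)
  rr <- vapply(tpls, function(tp) tp@rrMean, numeric(1))
  prior <- cohortPriors()$rr_mean
  se <- sd(rr) / sqrt(length(rr))
  expect_lt(abs(mean(rr) - prior[1]), 3 * se)
})

test_that("clean synthesis places the expected R peaks and no mains power", {
  rec <- cleanRecording(rrMean = 1.0, duration = 30, seed = 2)
  nR <- length(truthRTimes(rec))
  expect_true(nR %in% c(29L, 30L))
  # mean heart rate within 2% of 60/rrMean at zero RR variability
  rt <- truthRTimes(rec)
  expect_lt(abs(mean(diff(rt)) - 1.0), 0.02)
  ps <- welchPsd(leadVec <- signalMatrix(rec)[1, ], fs = 200)
  tot <- sum(ps$psd) * (ps$freq[2] - ps$freq[1])
  p50 <- ps$psd[which.min(abs(ps$freq - 50))] * (ps$freq[2] - ps$freq[1])
  expect_lt(p50, 1e-6 * tot)
  expect_error(synthesizeECG(beatTemplate(rrMean = 1, rrSd = 0),
                             duration = 3), "duration")
})

test_that("injected powerline produces a PSD peak at the 50 Hz bin", {
  tpl <- beatTemplate(rrMean = 1.0, rrSd = 0)
  rec <- synthesizeECG(tpl, leads = 1, duration = 30, fs = 200,
                       noise = noiseSpec(baselineAmp = 0, powerline50 = 0.1,
                                         powerline80 = 0, broadbandSd = 0,
                                         artifactRate = 0),
                       electrode = electrodeModel("ideal"), seed = 4)
  ps <- welchPsd(signalMatrix(rec)[1, ], fs = 200)
  i50 <- which.min(abs(ps$freq - 50))
  # local maximum at the 50 Hz bin
  expect_gt(ps$psd[i50], ps$psd[i50 - 2])
  expect_gt(ps$psd[i50], ps$psd[i50 + 2])
})

test_that("synthesis is bit-identical for a fixed seed", {
  tpl <- sampleCohortTemplates(1, seed = 5)[[1]]
  a <- synthesizeECG(tpl, leads = 3, duration = 20, seed = 9)
  b <- synthesizeECG(tpl, leads = 3, duration = 20, seed = 9)
  expect_identical(signalMatrix(a), signalMatrix(b))
  expect_identical(truthRTimes(a), truthRTimes(b))
})

test_that("electrode low-pass contrast shows in the 40-90 Hz band", {
  tpl <- beatTemplate()
  ns <- noiseSpec()
  pphg <- electrodeModel("PPHG")
  agcl <- electrodeModel("AgCl", noiseGain = pphg@noiseGain,
                         driftGain = pphg@driftGain)
  expect_lt(pphg@lpCutoff, agcl@lpCutoff)
  for (s in 1:3) {
    v1 <- var(butterBandpass(
      signalMatrix(synthesizeECG(tpl, 1, 60, 200, ns, pphg, seed = s))[1, ],
      40, 90, 200))
    v2 <- var(butterBandpass(
      signalMatrix(synthesizeECG(tpl, 1, 60, 200, ns, agcl, seed = s))[1, ],
      40, 90, 200))
    expect_lt(v1, v2)
  }
})

test_that("equivalent-circuit spectra have the analytic semicircle apex", {
  freqs <- 10^seq(-2, 2, length.out = 81)
  sp <- synthesizeEIS(rs = 0, rct = 1000, cdl = 159.15e-6, freqs = freqs)
  apex <- which.max(-sp@zImag)
  expect_equal(sp@freq[apex], freqs[which.min(abs(freqs - 1))])
  # circuit limits
  expect_lt(abs(sp@zReal[1] - 1000), 1)            # w -> 0: rs + rct
  expect_lt(tail(sp@zReal, 1), 1)                  # w -> inf: rs = 0
  sp2 <- synthesizeEIS(rs = 50, rct = 1000, cdl = 1e-4)
  expect_lt(abs(head(sp2@zReal, 1) - 1050), 1)
  expect_lt(abs(tail(sp2@zReal, 1) - 50), 1)
  expect_error(synthesizeEIS(rs = 1, rct = -5, cdl = 1e-4), "rct")
})

test_that("relaxation time recovers rct*cdl from synthesized spectra", {
  freqs <- 10^seq(-2, 3, by = 0.05)
  rct <- 2000; cdl <- 2e-5                      # f = 1/(2 pi rct cdl) ~ 3.98 Hz
  sp <- synthesizeEIS(rs = 10, rct = rct, cdl = cdl, freqs = freqs)
  rt <- relaxationTime(sp)
  fTrue <- 1 / (2 * pi * rct * cdl)
  iTrue <- which.min(abs(freqs - fTrue))
  expect_lte(abs(rt$index - iTrue), 1L)          # within one grid step
  expect_equal(rt$tau, 1 / (2 * pi * rt$fMax))
})
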