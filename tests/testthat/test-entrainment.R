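# Welch coherence spectra, reversed-stimulus surrogates and band peaks.

test_that("self-coherence is exactly one on every bin", {
  set.seed(3)
  x <- abs(rnorm(30 * 200) + 3)
  env <- envelopeSignal(x, 200)
  neu <- roiTimeSeries(x, 200)
  coh <- coherenceValues(coherenceSpectrum(env, neu))
  expect_true(all(abs(coh - 1) < 1e-10))
})

test_that("coherence stays in [0,1] and input contracts are enforced", {
  set.seed(4)
  env <- envelopeSignal(abs(rnorm(25 * 200) + 3), 200)
  neu <- roiTimeSeries(rnorm(25 * 200), 200)
  coh <- coherenceSpectrum(env, neu)
  expect_true(all(coherenceValues(coh) >= 0 & coherenceValues(coh) <= 1))
  expect_identical(spectrumFreqs(coh), seq(0.5, 10, by = 0.5))

  expect_error(coherenceSpectrum(envelopeSignal(abs(rnorm(5000)), 250), neu),
               "sampling rates")
  expect_error(
    coherenceSpectrum(envelopeSignal(abs(rnorm(3000)), 200),
                      roiTimeSeries(rnorm(3000), 200)),
    ">= 20 s")
})

test_that("a reversal-symmetric envelope gives surrogate equal to real", {
  # 1 + cos over whole periods is invariant under time reversal up to a
  # one-sample shift, which magnitude-squared coherence ignores
  fs <- 200
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  set.seed(5)
  env <- envelopeSignal(1 + cos(2 * pi * 5 * t), fs)
  neu <- roiTimeSeries(cos(2 * pi * 5 * t) + 0.5 * rnorm(length(t)), fs)
  real <- coherenceValues(coherenceSpectrum(env, neu))
  surr <- coherenceValues(surrogateCoherenceSpectrum(env, neu))
  expect_equal(surr, real, tolerance = 0.02)
})

test_that("reversal nulls are centered: real - surrogate has no sign bias", {
  # coupling-free pairs: envelope vs independent noise, 100 subjects
  set.seed(6)
  diffs <- replicate(100, {
    env <- envelopeSignal(abs(rnorm(22 * 200) + 3), 200)
    neu <- roiTimeSeries(rnorm(22 * 200), 200)
    th <- bandDefinition("theta", 4, 8)
    bandPeak(coherenceSpectrum(env, neu), th)$cohMax -
      bandPeak(surrogateCoherenceSpectrum(env, neu), th)$cohMax
  })
  expect_gt(stats::binom.test(sum(diffs > 0), length(diffs))$p.value, 0.01)
})

test_that("band peaks use the argmax with ties toward low frequencies", {
  sp <- toySpectrum(c(0.05, 0.1, 0.3, 0.2, 0.05),
                    freqs = c(4.0, 4.5, 5.0, 5.5, 6.0))
  pk <- bandPeak(sp, bandDefinition("theta", 4.5, 5.5))
  expect_equal(pk$cohMax, 0.3)
  expect_equal(pk$fC, 5.0)

  flat <- toySpectrum(rep(0.2, 5), freqs = c(4.0, 4.5, 5.0, 5.5, 6.0))
  expect_equal(bandPeak(flat, bandDefinition("theta", 4.5, 6))$fC, 4.5)

  expect_error(bandPeak(sp, bandDefinition("x", 8, 9)), "no grid")
  expect_error(bandDefinition("x", 0, 2), "lo")
})

test_that("entrained cohorts put the theta coherence peak at the true rate", {
  cfg <- cohortConfig(nSubjects = 5, trialDuration = 60, rois = "LAC",
                      tempoFactors = c(normal = 1), snr = 1, seed = 8)
  coh <- generateCohort(cfg)
  band <- bandDefinition("theta", 3, 9)
  fc <- vapply(groundTruth(coh)$subject, function(sid) {
    sp <- coherenceSpectrum(cohortEnvelope(coh, sid, "normal"),
                            cohortNeural(coh, sid, "normal", "LAC"))
    bandPeak(sp, band)$fC
  }, numeric(1))
  expect_equal(mean(fc), 5.5, tolerance = 0.5)
  # zero entrainment strength: coherence at the rate drops to chance
  cfg0 <- cohortConfig(nSubjects = 2, trialDuration = 60, rois = "LAC",
                       tempoFactors = c(normal = 1), seed = 8,
                       entrainmentStrength = 0, couplingDepth = 0)
  coh0 <- generateCohort(cfg0)
  sp0 <- coherenceSpectrum(cohortEnvelope(coh0, "s01", "normal"),
                           cohortNeural(coh0, "s01", "normal", "LAC"))
  expect_lt(coherenceValues(sp0)[spectrumFreqs(sp0) == 5.5], 0.2)
})
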