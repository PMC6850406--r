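# Synthetic cohort generator: spectral ground truth, tempo manipulation,
# determinism and cohort structure.

test_that("generated envelopes are nonnegative with the right spectral peaks", {
  cfg <- smallConfig(trialDuration = 60, nSubjects = 1)
  env <- generateEnvelope(cfg, "normal")
  expect_gte(min(samples(env)), 0)
  expect_true(all(is.finite(samples(env))))
  expect_equal(length(samples(env)), round(60 * cfg@fs))

  ps <- envelopePowerSpectrum(env)
  expect_equal(spectralArgmax(ps$freqs, ps$power, 4, 8), 5.5,
               tolerance = 0.51)
  # local maxima in both the delta (<3 Hz) and theta (4-7 Hz) ranges
  isPeak <- c(FALSE, diff(sign(diff(ps$power))) < 0, FALSE)
  peaks <- ps$freqs[isPeak]
  expect_true(any(peaks < 3))
  expect_true(any(peaks >= 4 & peaks <= 7))
})

test_that("envelope generation is deterministic under a fixed seed", {
  cfg <- smallConfig()
  e1 <- generateEnvelope(cfg, "normal", seed = 9)
  e2 <- generateEnvelope(cfg, "normal", seed = 9)
  expect_identical(samples(e1), samples(e2))
  e3 <- generateEnvelope(cfg, "normal", seed = 10)
  expect_false(identical(samples(e1), samples(e3)))
})

test_that("unknown condition and invalid configurations are rejected", {
  cfg <- smallConfig()
  expect_error(generateEnvelope(cfg, "whispered"), "whispered")
  expect_error(cohortConfig(snr = 0), "snr")
  expect_error(cohortConfig(couplingDepth = 1.3), "couplingDepth")
  expect_error(cohortConfig(tempoFactors = c(fast = 2)), "normal")
  expect_error(cohortConfig(fs = 80, gammaFreq = 20, syllableRate = 45),
               "fs/2")
  expect_error(cohortConfig(fs = 100, gammaFreq = 40), "4 \\* gammaFreq")
})

test_that("tempo rescaling shifts spectral peaks by the factor", {
  cfg <- smallConfig(trialDuration = 60, nSubjects = 1)
  env <- generateEnvelope(cfg, "normal")
  expect_identical(applyTempo(env, 1), env)
  for (f in c(1.25, 0.75)) {
    sc <- applyTempo(env, f)
    expect_equal(length(samples(sc)), round(length(samples(env)) / f))
    ps <- envelopePowerSpectrum(sc)
    expect_equal(spectralArgmax(ps$freqs, ps$power, 5.5 * f - 2,
                                5.5 * f + 2),
                 5.5 * f, tolerance = 0.51)
  }
  expect_error(applyTempo(env, 0), "positive")
  expect_error(applyTempo(env, -1), "positive")
})

test_that("tempo rescaling composes multiplicatively", {
  cfg <- smallConfig(nSubjects = 1)
  env <- generateEnvelope(cfg, "normal")
  once <- applyTempo(env, 1.25 * 0.8)          # net factor 1.0
  twice <- applyTempo(applyTempo(env, 1.25), 0.8)
  expect_equal(length(samples(twice)), length(samples(once)), tolerance = 0,
               ignore_attr = TRUE)
  scale <- max(samples(env))
  expect_lt(max(abs(samples(twice) - samples(once))) / scale, 0.02)
})

test_that("neural traces embed the configured couplings", {
  cfg <- smallConfig(nSubjects = 1, trialDuration = 40)
  env <- generateEnvelope(cfg, "normal")
  neu <- generateNeural(env, cfg, seed = 5)
  expect_true(all(is.finite(samples(neu))))
  expect_equal(length(samples(neu)), length(samples(env)))
  # oscillation-to-noise ratio is respected on average: total variance is
  # var(osc) * (1 + 1/snr^2)
  neu2 <- generateNeural(env, smallConfig(nSubjects = 1, trialDuration = 40,
                                          snr = 10),
                         seed = 5)
  expect_lt(stats::sd(samples(neu2)), stats::sd(samples(neu)))
  # mislabeled envelope
  env2 <- env; env2@condition <- "unknown"
  expect_error(generateNeural(env2, cfg), "unknown")
})

test_that("cohorts have the right structure, determinism and jitter", {
  cfg <- cohortConfig(nSubjects = 3, trialDuration = 20, seed = 4,
                      rois = c("LAC", "RAC"))
  coh <- generateCohort(cfg)
  expect_equal(length(coh@entries), 3 * 3)       # subject x condition
  nNeural <- sum(vapply(coh@entries, function(e) length(e$neural),
                        integer(1)))
  expect_equal(nNeural, 18)                      # ... x 2 ROIs

  coh2 <- generateCohort(cfg)
  expect_identical(
    samples(cohortNeural(coh, "s02", "accelerated", "RAC")),
    samples(cohortNeural(coh2, "s02", "accelerated", "RAC")))

  flat <- generateCohort(cohortConfig(nSubjects = 3, trialDuration = 20,
                                      subjectRateSD = 0,
                                      subjectGammaSD = 0))
  expect_equal(length(unique(groundTruth(flat)$syllableRate)), 1L)
  expect_equal(length(unique(groundTruth(flat)$gammaFreq)), 1L)
})

test_that("cohort export writes TSVs, a manifest and readable WAV", {
  cfg <- cohortConfig(nSubjects = 1, trialDuration = 20, rois = "LAC",
                      tempoFactors = c(normal = 1), seed = 2)
  coh <- generateCohort(cfg)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir, wav = TRUE, audioFs = 4000)
  expect_true(file.exists(file.path(dir, "s01_normal_LAC.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$config$nSubjects, 1)
  expect_equal(length(man$ground_truth), 1)

  neu <- readRoiTSV(file.path(dir, "s01_normal_LAC.tsv"))
  expect_equal(samplingRate(neu), cfg@fs)
  expect_equal(samples(neu), samples(cohortNeural(coh, "s01", "normal",
                                                  "LAC")),
               tolerance = 1e-6)
  wav <- readWav(file.path(dir, "s01_normal.wav"))
  expect_equal(wav$fs, 4000)
  expect_equal(length(wav$samples), 20 * 4000)
})
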