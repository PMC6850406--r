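# Gammatone filterbank envelope extraction and envelope power spectra.

test_that("ERB-spaced filterbank centers are increasing and bounded", {
  spec <- filterbankSpec(12, 150, 3000)
  expect_equal(spec$nChannels, 12L)
  expect_true(all(diff(spec$channelCenters) > 0))
  expect_equal(spec$channelCenters[1], 150, tolerance = 1e-6)
  expect_equal(spec$channelCenters[12], 3000, tolerance = 1e-6)
  expect_error(filterbankSpec(2), "nChannels")
})

test_that("a constant-amplitude tone gives a flat envelope that scales", {
  fs <- 8000
  spec <- filterbankSpec(16, 100, 3000)
  fc <- spec$channelCenters[10]
  tone <- sin(2 * pi * fc * seq(0, 4, by = 1 / fs))
  env <- samples(cochlearEnvelope(tone, fs = fs, spec = spec, outFs = 200))
  mid <- env[round(0.1 * length(env)):round(0.9 * length(env))]
  expect_lt(stats::sd(mid) / mean(mid), 0.05)
  env3 <- samples(cochlearEnvelope(3 * tone, fs = fs, spec = spec,
                                   outFs = 200))
  mid3 <- env3[round(0.1 * length(env3)):round(0.9 * length(env3))]
  expect_equal(mean(mid3) / mean(mid), 3, tolerance = 0.01)
})

test_that("amplitude-modulated noise yields the modulation frequency", {
  fs <- 8000
  set.seed(2)
  t <- seq(0, 20, by = 1 / fs)
  audio <- (1 + 0.9 * cos(2 * pi * 5.5 * t)) * rnorm(length(t))
  env <- cochlearEnvelope(audio, fs = fs, spec = filterbankSpec(16, 100, 3000),
                          outFs = 200)
  expect_gte(min(samples(env)), 0)
  ps <- envelopePowerSpectrum(env)
  expect_equal(spectralArgmax(ps$freqs, ps$power, 4, 8), 5.5,
               tolerance = 0.51)
})

test_that("degenerate audio inputs are handled explicitly", {
  expect_error(cochlearEnvelope(numeric(0), fs = 8000, outFs = 200),
               "zero-length")
  expect_error(cochlearEnvelope(rnorm(100), fs = 8000, outFs = 9000),
               "outFs")
  expect_warning(
    env <- cochlearEnvelope(numeric(4000), fs = 8000,
                            spec = filterbankSpec(8, 100, 2000),
                            outFs = 200),
    "silent")
  expect_equal(max(samples(env)), 0)
})

test_that("envelope spectra reject too-short input and scale with tempo", {
  cfg <- smallConfig(nSubjects = 1, trialDuration = 60)
  env <- generateEnvelope(cfg, "normal")
  short <- envelopeSignal(samples(env)[1:400], fs = cfg@fs)
  expect_error(envelopePowerSpectrum(short), "too short")
  psN <- envelopePowerSpectrum(env)
  psA <- envelopePowerSpectrum(applyTempo(env, 1.25))
  pkN <- spectralArgmax(psN$freqs, psN$power, 4, 8)
  pkA <- spectralArgmax(psA$freqs, psA$power, 5, 9)
  expect_equal(pkA, 1.25 * pkN, tolerance = 0.51)
})

test_that("sonified envelopes round-trip through WAV and cochlear analysis", {
  cfg <- smallConfig(nSubjects = 1, trialDuration = 30)
  env <- generateEnvelope(cfg, "normal")
  wavPath <- withr::local_tempfile(fileext = ".wav")
  sonifyEnvelope(env, wavPath, audioFs = 4000)
  audio <- readWav(wavPath)
  expect_equal(audio$fs, 4000)
  rec <- cochlearEnvelope(audio, spec = filterbankSpec(12, 100, 1500),
                          outFs = 200)
  ps <- envelopePowerSpectrum(rec)
  expect_equal(spectralArgmax(ps$freqs, ps$power, 4, 8), 5.5,
               tolerance = 0.51)
})
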