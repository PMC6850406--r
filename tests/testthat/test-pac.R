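# Equipopulated binning, MI estimation, bias correction and comodulograms.

test_that("equipopulated binning balances counts and rejects constants", {
  b <- quantizeEquipopulated(c(0.1, 0.4, 0.2, 0.9, 0.5, 0.7), 3)
  expect_equal(as.vector(table(b)), c(2, 2, 2))
  expect_equal(b, c(1L, 2L, 1L, 3L, 2L, 3L))    # quantile order

  set.seed(1)
  b <- quantizeEquipopulated(runif(1000), 10)
  expect_equal(as.vector(table(b)), rep(100L, 10))

  # ties resolved by stable order of occurrence
  b <- quantizeEquipopulated(rep(c(1, 2), each = 3), 2)
  expect_equal(b, c(1L, 1L, 1L, 2L, 2L, 2L))

  expect_error(quantizeEquipopulated(rep(1, 100), 10), "constant")
  expect_error(quantizeEquipopulated(1:5, 10), "shorter")
})

test_that("plug-in MI reproduces closed-form joint distributions", {
  # bijection of a fair bit: 1 bit exactly
  a <- rep(c(1L, 2L), 500)
  expect_equal(miPlugin(a, a, 2), 1)
  # exact independence: 0 bits
  ind <- expand.grid(1:2, 1:2)
  expect_equal(miPlugin(rep(ind[, 1], 100), rep(ind[, 2], 100), 2), 0)
  # joint ((0.4, 0.1), (0.1, 0.4)): direct evaluation of the MI sum
  a <- rep(c(1L, 1L, 2L, 2L), c(40, 10, 10, 40))
  b <- rep(c(1L, 2L, 1L, 2L), c(40, 10, 10, 40))
  oracle <- 2 * 0.4 * log2(0.4 / 0.25) + 2 * 0.1 * log2(0.1 / 0.25)
  expect_equal(miPlugin(a, b, 2), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.278, tolerance = 1e-3)
  expect_error(miPlugin(1:10, 1:9), "lengths differ")
})

test_that("plug-in MI matches an independent brute-force oracle exactly", {
  set.seed(2)
  for (r in 1:20) {
    nBins <- sample(2:10, 1)
    n <- sample(200:500, 1)
    a <- quantizeEquipopulated(runif(n), nBins)
    b <- if (r %% 2) quantizeEquipopulated(runif(n), nBins)
         else quantizeEquipopulated(runif(n) + 0.8 * a, nBins)
    expect_equal(miPlugin(a, b, nBins), miBruteForce(a, b, nBins),
                 tolerance = 1e-12)
    expect_identical(miPlugin(a, b, nBins), miPlugin(b, a, nBins))
    expect_gte(miPlugin(a, b, nBins), 0)
  }
})

test_that("bias correction preserves deterministic MI and needs enough data", {
  set.seed(3)
  b <- quantizeEquipopulated(runif(10000), 10)
  expect_equal(miBiasCorrected(b, b), log2(10), tolerance = 0.02)
  expect_error(miBiasCorrected(b[1:300], b[1:300]), "at least 400")
})

test_that("corrected MI grows monotonically with coupling depth", {
  depths <- c(0, 0.25, 0.5, 0.75, 1)
  miAt <- matrix(0, 20, length(depths))
  for (s in 1:20) {
    for (di in seq_along(depths)) {
      cfg <- cohortConfig(nSubjects = 1, trialDuration = 40, rois = "LAC",
                          couplingDepth = depths[di], subjectRateSD = 0,
                          subjectGammaSD = 0, tempoFactors = c(normal = 1),
                          seed = 100 + s)
      envl <- generateEnvelope(cfg, "normal")
      neu <- generateNeural(envl, cfg, seed = 200 + s)
      ph <- speechPAC:::trialBandDynamics(samples(envl), cfg@fs, 1L,
                                          5.5, 0.5)$phase
      am <- speechPAC:::trialBandDynamics(samples(neu), cfg@fs, 1L,
                                          33, 7)$amplitude
      miAt[s, di] <- miBiasCorrected(
        quantizeEquipopulated(ph[, 1], 10),
        quantizeEquipopulated(am[, 1], 10))
    }
  }
  means <- colMeans(miAt)
  expect_equal(stats::cor(means, depths, method = "spearman"), 1)
})

test_that("comodulograms recover injected coupling at the right cell", {
  cfg <- cohortConfig(nSubjects = 1, trialDuration = 60, rois = "LAC",
                      subjectRateSD = 0, subjectGammaSD = 0, seed = 31)
  envl <- generateEnvelope(cfg, "normal")
  neu <- generateNeural(envl, cfg, seed = 32)
  cmg <- comodulogram(envl, neu, ampFreqs = seq(25, 40, 0.5),
                      ampHalfwidth = 7)
  pk <- pacPeak(cmg)
  expect_equal(pk$fPhase, 5.5, tolerance = 0.51)
  expect_equal(pk$fAmp, 33, tolerance = 1.01)
  expect_gt(pk$miMax, 0.1)
  # plug-in variant is nonnegative everywhere
  cmgP <- comodulogram(envl, neu, phaseFreqs = c(5, 5.5, 6),
                       ampFreqs = c(32, 33), ampHalfwidth = 7,
                       biasCorrected = FALSE)
  expect_true(all(miMatrix(cmgP) >= 0))
  expect_error(comodulogram(envl, neu, phaseSource = "audio"),
               "phaseSource")
})

test_that("stimulus- and neural-phase comodulograms agree when entrained", {
  cfg <- cohortConfig(nSubjects = 1, trialDuration = 60, rois = "LAC",
                      subjectRateSD = 0, subjectGammaSD = 0,
                      entrainmentStrength = 1.5, seed = 33)
  envl <- generateEnvelope(cfg, "normal")
  neu <- generateNeural(envl, cfg, seed = 34)
  pkS <- pacPeak(comodulogram(envl, neu, "stimulus",
                              ampFreqs = seq(28, 38, 0.5), ampHalfwidth = 7))
  pkN <- pacPeak(comodulogram(envl, neu, "neural",
                              ampFreqs = seq(28, 38, 0.5), ampHalfwidth = 7))
  expect_equal(pkS$fPhase, pkN$fPhase, tolerance = 0.51)
  expect_equal(pkS$fAmp, pkN$fAmp, tolerance = 1.01)
})

test_that("surrogate reversal is an involution", {
  cfg <- smallConfig(nSubjects = 1)
  envl <- generateEnvelope(cfg, "normal")
  neu <- generateNeural(envl, cfg, seed = 35)
  grid <- list(phase = c(5, 5.5), amp = c(32.5, 33))
  revEnv <- speechPAC:::reverseSignal(envl)
  a <- surrogateComodulogram(revEnv, neu, phaseFreqs = grid$phase,
                             ampFreqs = grid$amp, ampHalfwidth = 7)
  b <- comodulogram(envl, neu, phaseFreqs = grid$phase,
                    ampFreqs = grid$amp, ampHalfwidth = 7)
  expect_identical(miMatrix(a), miMatrix(b))
})

test_that("PAC peaks respect masks and deterministic tie-breaking", {
  mi <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  cmg <- toyComodulogram(mi)
  expect_equal(pacPeak(cmg)$miMax, 6)
  mask <- matrix(FALSE, 2, 3); mask[1, 2] <- TRUE
  pk <- pacPeak(cmg, mask)
  expect_equal(pk$miMax, 3)
  expect_equal(pk$fPhase, phaseFreqs(cmg)[1])
  expect_equal(pk$fAmp, ampFreqs(cmg)[2])
  # ties: lowest phase frequency, then lowest amplitude frequency
  tie <- toyComodulogram(matrix(c(7, 7, 7, 7), 2, 2))
  pkT <- pacPeak(tie)
  expect_equal(pkT$fPhase, phaseFreqs(tie)[1])
  expect_equal(pkT$fAmp, ampFreqs(tie)[1])
  expect_error(pacPeak(cmg, matrix(FALSE, 2, 3)), "no significant cluster")
})
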