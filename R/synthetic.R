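# Synthetic cohort generator: quasi-rhythmic stimulus envelopes and coupled
# neural traces with known ground truth, used to validate every downstream
# analysis stage.

# Raised-cosine (Hann) pulse kernel of the given width in samples.
hannKernel <- function(width) {
  w <- max(3L, as.integer(width))
  0.5 - 0.5 * cos(2 * pi * seq(0, w - 1) / (w - 1))
}

# Linear convolution via FFT, centered ("same" length as x).
convSame <- function(x, k) {
  n <- length(x); nk <- length(k)
  m <- goodLength(n + nk - 1L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(m - n))) *
                     stats::fft(c(k, numeric(m - nk))), inverse = TRUE)) / m
  off <- (nk - 1L) %/% 2L
  y[(off + 1L):(off + n)]
}

generateEnvelopeTrial <- function(config) {
  fs <- config@fs
  n <- round(config@trialDuration * fs)
  period <- 1 / config@syllableRate
  nPulse <- ceiling(config@trialDuration / period) + 8L
  # renewal timing: Gaussian inter-syllable-interval jitter, SD = 10% of the
  # period, truncated to +/- 45% so intervals stay positive. Cumulative
  # jitter makes the syllabic phase diffuse as in natural speech, so time
  # reversal destroys phase alignment while the spectral peak stays sharp.
  jit <- pmax(-0.45 * period,
              pmin(0.45 * period, stats::rnorm(nPulse, 0, 0.1 * period)))
  tPulse <- cumsum(period + jit) - 0.5 * period
  tPulse <- tPulse[tPulse >= 0 & tPulse < config@trialDuration]
  ampPulse <- stats::runif(length(tPulse), 0.8, 1.2)
  train <- numeric(n)
  idx <- pmin(n, pmax(1L, round(tPulse * fs) + 1L))
  for (k in seq_along(idx)) train[idx[k]] <- train[idx[k]] + ampPulse[k]
  env <- convSame(train, hannKernel(0.6 * period * fs))
  phi <- stats::runif(1, 0, 2 * pi)
  t <- (seq_len(n) - 1) / fs
  env <- env * (1 + 0.4 * cos(2 * pi * config@prosodicRate * t + phi))
  pmax(env, 0)
}

#' Generate a synthetic stimulus envelope
#'
#' Builds a quasi-periodic syllabic pulse train at the configured syllable
#' rate (pulse times jittered by 10\% of the period, pulses smoothed with a
#' raised-cosine kernel), multiplies it by a slow prosodic modulation, and
#' applies the condition's tempo factor by uniform time-axis rescaling. The
#' resulting power spectrum has local maxima near the (tempo-scaled)
#' prosodic and syllable rates.
#'
#' @param config a \linkS4class{CohortConfig}
#' @param condition a condition label present in \code{config}'s
#'   \code{tempoFactors}
#' @param seed RNG seed for this stimulus (default: the config seed)
#' @return an \linkS4class{EnvelopeSignal}
#' @examples
#' env <- generateEnvelope(cohortConfig(trialDuration = 20), "normal")
#' @export
generateEnvelope <- function(config, condition, seed = config@seed) {
  validObject(config)
  if (!condition %in% names(config@tempoFactors))
    stop("unknown condition label '", condition, "'")
  factor <- unname(config@tempoFactors[condition])
  if (config@syllableRate * factor >= config@fs / 2)
    stop("fs = ", config@fs, " Hz too low for syllable rate ",
         config@syllableRate * factor, " Hz")
  set.seed(seed)
  env <- envelopeSignal(
    unlist(lapply(seq_len(config@nTrials),
                  function(k) generateEnvelopeTrial(config))),
    fs = config@fs, condition = condition, nTrials = config@nTrials)
  applyTempo(env, factor)
}

#' Apply a tempo (speech-rate) manipulation to an envelope
#'
#' Uniformly rescales the time axis of an envelope: the output duration is
#' the input duration divided by \code{factor} at unchanged sampling rate, so
#' every spectral peak frequency is multiplied by \code{factor}. Each trial
#' is resampled independently by cubic-spline interpolation. A factor of 1
#' returns the input unchanged.
#'
#' @param envelope an \linkS4class{EnvelopeSignal}
#' @param factor positive tempo factor (> 1 accelerates, < 1 decelerates)
#' @return the rescaled \linkS4class{EnvelopeSignal}
#' @examples
#' env <- generateEnvelope(cohortConfig(trialDuration = 20), "normal")
#' fast <- applyTempo(env, 1.25)
#' @export
applyTempo <- function(envelope, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("tempo factor must be a positive number")
  if (factor == 1) return(envelope)
  trials <- splitTrials(samples(envelope), nTrials(envelope))
  nOut <- round(length(trials[[1]]) / factor)
  out <- unlist(lapply(trials, function(tr) pmax(0, resampleTo(tr, nOut))))
  envelopeSignal(out, fs = samplingRate(envelope),
                 condition = conditionLabel(envelope),
                 nTrials = nTrials(envelope))
}

#' Generate a coupled neural trace for a stimulus envelope
#'
#' Simulates one ROI trace aligned with the given envelope:
#' \deqn{x(t) = e \cdot \cos(\phi_\theta(t)) + a (1 + m \cos(\phi_\theta(t) -
#' \phi_0)) \cos(2\pi f_\gamma t + \psi) + \mathrm{noise}(t)}
#' where the theta phase \eqn{\phi_\theta} is the analytic phase of the
#' envelope band-passed around the (tempo-scaled) syllable rate plus the
#' configured stimulus-brain lag, \eqn{e} is the entrainment strength,
#' \eqn{m} the coupling depth, \eqn{\phi_0} the preferred coupling phase, and
#' \eqn{f_\gamma} the (tempo-scaled) gamma frequency. The background is
#' 1/f^\code{noiseExponent} Gaussian noise scaled so the oscillatory-to-noise
#' RMS ratio equals \code{snr}.
#'
#' @param envelope the driving \linkS4class{EnvelopeSignal}
#' @param config a \linkS4class{CohortConfig} (its rates are interpreted at
#'   normal tempo; the envelope's condition selects the tempo factor)
#' @param seed RNG seed for carrier phase and noise
#' @param subject,roi labels for the returned trace
#' @return a \linkS4class{RoiTimeSeries}
#' @examples
#' cfg <- cohortConfig(trialDuration = 20)
#' env <- generateEnvelope(cfg, "normal")
#' neu <- generateNeural(env, cfg)
#' @export
generateNeural <- function(envelope, config, seed = config@seed,
                           subject = "s01", roi = config@rois[1]) {
  stopIfNot(samplingRate(envelope) == config@fs,
            "envelope fs must equal config fs")
  if (config@snr <= 0) stop("snr must be > 0")
  cond <- conditionLabel(envelope)
  if (!cond %in% names(config@tempoFactors))
    stop("unknown condition label '", cond, "'")
  factor <- unname(config@tempoFactors[cond])
  fs <- config@fs
  rate <- config@syllableRate * factor
  fGamma <- config@gammaFreq * factor
  set.seed(seed)
  trials <- splitTrials(samples(envelope), nTrials(envelope))
  out <- lapply(trials, function(tr) {
    n <- length(tr)
    t <- (seq_len(n) - 1) / fs
    filt <- bandpassFilter(tr - mean(tr), fs, rate,
                           halfwidth = min(1, rate / 2))
    phiTheta <- Arg(analyticOf(filt)) + config@phaseLag
    theta <- cos(phiTheta)
    psi <- stats::runif(1, 0, 2 * pi)
    g <- config@gammaAmplitude *
      (1 + config@couplingDepth * cos(phiTheta - config@couplingPhase)) *
      cos(2 * pi * fGamma * t + psi)
    osc <- config@entrainmentStrength * theta + g
    noise <- oneOverFNoise(n, fs, config@noiseExponent)
    oscRms <- rmsOf(osc)
    noise <- if (oscRms > 0) noise * oscRms / config@snr else noise
    osc + noise
  })
  roiTimeSeries(unlist(out), fs = fs, subject = subject, condition = cond,
                roi = roi, nTrials = nTrials(envelope))
}

#' Generate a multi-subject synthetic cohort
#'
#' For each subject, draws ground-truth syllable rate and gamma frequency
#' (Gaussian between-subject jitter around the configured values), generates
#' the subject's normal-tempo stimulus envelope, derives every condition by
#' the tempo manipulation (\code{\link{applyTempo}}), and simulates one
#' neural trace per ROI with \code{\link{generateNeural}}. All RNG streams
#' are derived deterministically from the config seed and the subject /
#' condition / ROI indices, so identical configs give identical cohorts.
#'
#' @param config a \linkS4class{CohortConfig}
#' @return a \linkS4class{SyntheticCohort}
#' @examples
#' coh <- generateCohort(cohortConfig(nSubjects = 2, trialDuration = 20))
#' groundTruth(coh)
#' @export
generateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  ids <- sprintf("s%02d", seq_len(config@nSubjects))
  subj <- data.frame(
    subject = ids,
    syllableRate = config@syllableRate +
      stats::rnorm(config@nSubjects, 0, config@subjectRateSD),
    gammaFreq = config@gammaFreq +
      stats::rnorm(config@nSubjects, 0, config@subjectGammaSD))
  conds <- names(config@tempoFactors)
  nRoi <- length(config@rois)
  entries <- list()
  for (i in seq_len(config@nSubjects)) {
    cfgI <- config
    cfgI@syllableRate <- subj$syllableRate[i]
    cfgI@gammaFreq <- subj$gammaFreq[i]
    for (ci in seq_along(conds)) {
      env <- generateEnvelope(cfgI, conds[ci],
                              seed = subSeed(config@seed, i, 0L))
      neural <- list()
      for (ri in seq_len(nRoi)) {
        neural[[config@rois[ri]]] <- generateNeural(
          env, cfgI, seed = subSeed(config@seed, i, ci * nRoi + ri),
          subject = ids[i], roi = config@rois[ri])
      }
      entries[[paste(ids[i], conds[ci], sep = "|")]] <-
        list(envelope = env, neural = neural)
    }
  }
  new("SyntheticCohort", config = config, subjects = subj, entries = entries)
}

# Config as a plain list, for manifests and hashing.
configToList <- function(config) {
  sl <- slotNames(config)
  out <- lapply(sl, function(s) slot(config, s))
  names(out) <- sl
  out$tempoFactors <- as.list(config@tempoFactors)
  out
}

#' Write a cohort to disk
#'
#' Writes one TSV per subject x condition x ROI (columns \code{time_s},
#' \code{value}), one TSV per subject x condition stimulus envelope, and a
#' JSON manifest echoing the configuration and the per-subject ground-truth
#' frequencies. Optionally also writes a sonified version of each envelope
#' (amplitude-modulated white noise) as WAV for exercising the cochlear
#' envelope extraction.
#'
#' @param cohort a \linkS4class{SyntheticCohort}
#' @param dir output directory (created if missing)
#' @param wav also write sonified envelopes as WAV (default FALSE)
#' @param audioFs WAV sampling rate (Hz)
#' @return invisibly, the manifest path
#' @export
writeCohort <- function(cohort, dir, wav = FALSE, audioFs = 8000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (key in names(cohort@entries)) {
    entry <- cohort@entries[[key]]
    base <- gsub("\\|", "_", key)
    p <- file.path(dir, paste0(base, "_envelope.tsv"))
    writeSignalTSV(entry$envelope, p)
    files <- c(files, p)
    for (roi in names(entry$neural)) {
      p <- file.path(dir, paste0(base, "_", roi, ".tsv"))
      writeSignalTSV(entry$neural[[roi]], p)
      files <- c(files, p)
    }
    if (wav) {
      p <- file.path(dir, paste0(base, ".wav"))
      sonifyEnvelope(entry$envelope, p, audioFs = audioFs)
      files <- c(files, p)
    }
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(config = configToList(cohortConfigOf(cohort)),
         ground_truth = groundTruth(cohort),
         files = basename(files)),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Sonify an envelope as amplitude-modulated noise
#'
#' Renders an envelope audible by modulating white noise with it and writes
#' the result as a 16-bit PCM WAV. This gives the cochlear envelope
#' extraction a signal whose true wideband envelope is known.
#'
#' @param envelope an \linkS4class{EnvelopeSignal}
#' @param path output WAV path
#' @param audioFs audio sampling rate (Hz, default 8000)
#' @param seed RNG seed for the carrier noise
#' @return invisibly, \code{path}
#' @export
sonifyEnvelope <- function(envelope, path, audioFs = 8000, seed = 1) {
  set.seed(seed)
  env <- samples(envelope)
  nOut <- round(length(env) / samplingRate(envelope) * audioFs)
  envHi <- pmax(0, resampleTo(env, nOut))
  x <- envHi * stats::rnorm(nOut)
  writeWav(0.9 * x / max(abs(x)), audioFs, path)
}
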