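# Accessors, constructors and show() methods.

#' Create a cohort configuration
#'
#' Constructor for \linkS4class{CohortConfig} with defaults emulating the
#' study design the package validates against: a syllabic rhythm at 5.5 Hz
#' with a 1.8 Hz prosodic modulation, a gamma carrier at 33 Hz whose amplitude
#' is modulated by theta phase, tempo factors 0.75 / 1.0 / 1.25, two auditory
#' ROIs and 1/f background noise at unit oscillation-to-noise RMS ratio.
#' Signals are generated at 200 Hz; all analysis bands are below 50 Hz, and a
#' 1 kHz acquisition-style rate remains available through \code{fs}.
#'
#' @param nSubjects number of subjects (default 17)
#' @param fs sampling rate in Hz (default 200)
#' @param trialDuration trial duration in seconds at normal tempo (default 60)
#' @param nTrials trials per subject and condition (default 1)
#' @param syllableRate syllabic (theta) rate in Hz (default 5.5)
#' @param prosodicRate prosodic (delta) modulation rate in Hz (default 1.8)
#' @param gammaFreq gamma carrier frequency in Hz (default 33)
#' @param couplingDepth theta-gamma modulation depth in [0,1] (default 0.7)
#' @param entrainmentStrength entrained theta amplitude (default 1)
#' @param phaseLag stimulus-to-brain theta phase lag in rad (default 0)
#' @param couplingPhase preferred coupling phase in rad (default 0)
#' @param gammaAmplitude gamma amplitude relative to theta (default 0.5)
#' @param noiseExponent background-noise spectral slope (default 1)
#' @param snr oscillation-to-noise RMS ratio (default 1)
#' @param tempoFactors named tempo factors; must contain \code{normal = 1}
#' @param rois ROI labels (default \code{c("LAC", "RAC")})
#' @param subjectRateSD between-subject syllable-rate SD in Hz (default 0.25)
#' @param subjectGammaSD between-subject gamma-frequency SD in Hz (default 1.5)
#' @param seed master seed (default 1)
#' @return a validated \linkS4class{CohortConfig}
#' @examples
#' cfg <- cohortConfig(nSubjects = 3, trialDuration = 20)
#' @export
cohortConfig <- function(nSubjects = 17, fs = 200, trialDuration = 60,
                         nTrials = 1, syllableRate = 5.5, prosodicRate = 1.8,
                         gammaFreq = 33, couplingDepth = 0.7,
                         entrainmentStrength = 1, phaseLag = 0,
                         couplingPhase = 0, gammaAmplitude = 0.5,
                         noiseExponent = 1, snr = 1,
                         tempoFactors = c(decelerated = 0.75, normal = 1,
                                          accelerated = 1.25),
                         rois = c("LAC", "RAC"), subjectRateSD = 0.25,
                         subjectGammaSD = 1.5, seed = 1) {
  new("CohortConfig", nSubjects = as.integer(nSubjects), fs = fs,
      trialDuration = trialDuration, nTrials = as.integer(nTrials),
      syllableRate = syllableRate, prosodicRate = prosodicRate,
      gammaFreq = gammaFreq, couplingDepth = couplingDepth,
      entrainmentStrength = entrainmentStrength, phaseLag = phaseLag,
      couplingPhase = couplingPhase, gammaAmplitude = gammaAmplitude,
      noiseExponent = noiseExponent, snr = snr,
      tempoFactors = tempoFactors, rois = rois,
      subjectRateSD = subjectRateSD, subjectGammaSD = subjectGammaSD,
      seed = as.integer(seed))
}

#' Create an EnvelopeSignal
#'
#' @param samples nonnegative numeric vector
#' @param fs sampling rate (Hz)
#' @param condition condition label
#' @param nTrials number of equal-length trials concatenated in \code{samples}
#' @return an \linkS4class{EnvelopeSignal}
#' @export
envelopeSignal <- function(samples, fs, condition = "unlabeled", nTrials = 1) {
  new("EnvelopeSignal", samples = as.numeric(samples), fs = fs,
      condition = condition, nTrials = as.integer(nTrials))
}

#' Create a RoiTimeSeries
#'
#' @param samples numeric vector
#' @param fs sampling rate (Hz)
#' @param subject subject id
#' @param condition condition label
#' @param roi ROI label
#' @param nTrials number of equal-length trials concatenated in \code{samples}
#' @return a \linkS4class{RoiTimeSeries}
#' @export
roiTimeSeries <- function(samples, fs, subject = "s01",
                          condition = "unlabeled", roi = "ROI", nTrials = 1) {
  new("RoiTimeSeries", samples = as.numeric(samples), fs = fs,
      subject = subject, condition = condition, roi = roi,
      nTrials = as.integer(nTrials))
}

## ---- accessors ----

#' @rdname accessors
setMethod("samples", "EnvelopeSignal", function(x) x@samples)
#' @rdname accessors
setMethod("samples", "RoiTimeSeries", function(x) x@samples)
#' @rdname accessors
setMethod("samplingRate", "EnvelopeSignal", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "RoiTimeSeries", function(x) x@fs)
#' @rdname accessors
setMethod("nTrials", "EnvelopeSignal", function(x) x@nTrials)
#' @rdname accessors
setMethod("nTrials", "RoiTimeSeries", function(x) x@nTrials)
#' @rdname accessors
setMethod("conditionLabel", "EnvelopeSignal", function(x) x@condition)
#' @rdname accessors
setMethod("conditionLabel", "RoiTimeSeries", function(x) x@condition)
#' @rdname accessors
setMethod("conditionLabel", "CoherenceSpectrum", function(x) x@condition)
#' @rdname accessors
setMethod("conditionLabel", "Comodulogram", function(x) x@condition)
#' @rdname accessors
setMethod("subjectId", "RoiTimeSeries", function(x) x@subject)
#' @rdname accessors
setMethod("subjectId", "CoherenceSpectrum", function(x) x@subject)
#' @rdname accessors
setMethod("subjectId", "Comodulogram", function(x) x@subject)
#' @rdname accessors
setMethod("roiLabel", "RoiTimeSeries", function(x) x@roi)
#' @rdname accessors
setMethod("roiLabel", "CoherenceSpectrum", function(x) x@roi)
#' @rdname accessors
setMethod("roiLabel", "Comodulogram", function(x) x@roi)

#' @rdname spectrum-accessors
setMethod("spectrumFreqs", "CoherenceSpectrum", function(x) x@freqs)
#' @rdname spectrum-accessors
setMethod("coherenceValues", "CoherenceSpectrum", function(x) x@coherence)
#' @rdname spectrum-accessors
setMethod("nSegments", "CoherenceSpectrum", function(x) x@nSegments)

#' @rdname comodulogram-accessors
setMethod("miMatrix", "Comodulogram", function(x) x@mi)
#' @rdname comodulogram-accessors
setMethod("phaseFreqs", "Comodulogram", function(x) x@phaseFreqs)
#' @rdname comodulogram-accessors
setMethod("ampFreqs", "Comodulogram", function(x) x@ampFreqs)
#' @rdname comodulogram-accessors
setMethod("phaseSource", "Comodulogram", function(x) x@phaseSource)

#' @rdname cohort-accessors
setMethod("cohortConfigOf", "SyntheticCohort", function(x) x@config)
#' @rdname cohort-accessors
setMethod("groundTruth", "SyntheticCohort", function(x) x@subjects)
#' @rdname cohort-accessors
setMethod("cohortEnvelope", "SyntheticCohort",
  function(x, subject, condition) {
    key <- paste(subject, condition, sep = "|")
    if (!key %in% names(x@entries))
      stop("no cohort entry for subject '", subject, "', condition '",
           condition, "'")
    x@entries[[key]]$envelope
  })
#' @rdname cohort-accessors
setMethod("cohortNeural", "SyntheticCohort",
  function(x, subject, condition, roi) {
    key <- paste(subject, condition, sep = "|")
    if (!key %in% names(x@entries))
      stop("no cohort entry for subject '", subject, "', condition '",
           condition, "'")
    neu <- x@entries[[key]]$neural
    if (!roi %in% names(neu))
      stop("unknown ROI '", roi, "'")
    neu[[roi]]
  })

## ---- show methods ----

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nSubjects, "subjects,",
      length(object@tempoFactors), "conditions,",
      length(object@rois), "ROIs\n")
  cat("  fs", object@fs, "Hz |", object@nTrials, "x",
      object@trialDuration, "s trials\n")
  cat("  syllable", object@syllableRate, "Hz, prosodic",
      object@prosodicRate, "Hz, gamma", object@gammaFreq, "Hz\n")
  cat("  coupling depth", object@couplingDepth, "| entrainment",
      object@entrainmentStrength, "| snr", object@snr, "\n")
  cat("  tempo:", paste(names(object@tempoFactors), object@tempoFactors,
                        sep = "=", collapse = ", "), "\n")
})

setMethod("show", "EnvelopeSignal", function(object) {
  cat("EnvelopeSignal [", object@condition, "]: ",
      length(object@samples), " samples @ ", object@fs, " Hz (",
      signif(length(object@samples) / object@fs, 4), " s, ",
      object@nTrials, " trial(s))\n", sep = "")
})

setMethod("show", "RoiTimeSeries", function(object) {
  cat("RoiTimeSeries ", object@subject, "/", object@condition, "/",
      object@roi, ": ", length(object@samples), " samples @ ",
      object@fs, " Hz\n", sep = "")
})

setMethod("show", "CoherenceSpectrum", function(object) {
  pk <- which.max(object@coherence)
  cat("CoherenceSpectrum ", object@subject, "/", object@condition, "/",
      object@roi, ": ", min(object@freqs), "-", max(object@freqs),
      " Hz (", length(object@freqs), " bins, ", object@nSegments,
      " segments); max ", signif(object@coherence[pk], 3), " @ ",
      object@freqs[pk], " Hz\n", sep = "")
})

setMethod("show", "Comodulogram", function(object) {
  idx <- arrayInd(which.max(object@mi), dim(object@mi))
  cat("Comodulogram ", object@subject, "/", object@condition, "/",
      object@roi, " (phase: ", object@phaseSource, "): ",
      nrow(object@mi), " x ", ncol(object@mi), " cells; max ",
      signif(max(object@mi), 3), " bits @ (",
      object@phaseFreqs[idx[1]], ", ", object@ampFreqs[idx[2]], ") Hz\n",
      sep = "")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@subjects), "subjects x",
      length(object@config@tempoFactors), "conditions x",
      length(object@config@rois), "ROIs\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: extent ", sum(object@mask), ", mass ",
      signif(object@clusterStat, 4), ", p = ", signif(object@pValue, 3),
      ", polarity ", object@polarity, "\n", sep = "")
})
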