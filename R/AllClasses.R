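# Central S4 data containers. All signal classes store one concatenated
# sample vector plus the trial count; trials are equal length, so analysis
# code can split deterministically without per-trial bookkeeping.

#' Configuration of a synthetic cohort
#'
#' Describes the generative model for a multi-subject cohort of stimulus
#' envelopes and coupled neural traces: a quasi-rhythmic syllabic pulse train
#' (rate \code{syllableRate}, Hz) slowly modulated at the prosodic/phrasal
#' rate (\code{prosodicRate}, Hz), driving a neural signal composed of an
#' envelope-entrained theta oscillation (gain \code{entrainmentStrength},
#' phase lag \code{phaseLag} rad), a gamma oscillation at \code{gammaFreq} Hz
#' whose amplitude is modulated by theta phase with depth
#' \code{couplingDepth} (preferred coupling phase \code{couplingPhase} rad,
#' relative gamma amplitude \code{gammaAmplitude}), and 1/f^\code{noiseExponent}
#' background noise scaled so the oscillatory-to-noise RMS ratio equals
#' \code{snr}. \code{tempoFactors} maps condition labels to positive tempo
#' factors (must contain \code{normal = 1}); tempo manipulation rescales the
#' stimulus time axis and the gamma carrier alike. Between-subject variability
#' is Gaussian jitter of the syllable rate (SD \code{subjectRateSD} Hz) and
#' gamma frequency (SD \code{subjectGammaSD} Hz).
#'
#' @slot nSubjects number of subjects
#' @slot fs sampling rate of generated signals (Hz)
#' @slot trialDuration duration of one trial (s), before tempo scaling
#' @slot nTrials trials per subject and condition
#' @slot syllableRate syllabic (theta) rhythm rate (Hz)
#' @slot prosodicRate prosodic (delta) modulation rate (Hz)
#' @slot gammaFreq gamma carrier frequency (Hz)
#' @slot couplingDepth phase-amplitude modulation depth in [0, 1]
#' @slot entrainmentStrength amplitude of the entrained theta component
#' @slot phaseLag stimulus-to-brain theta phase lag (rad)
#' @slot couplingPhase theta phase of maximal gamma amplitude (rad)
#' @slot gammaAmplitude gamma carrier amplitude relative to unit theta
#' @slot noiseExponent spectral slope of the background noise
#' @slot snr oscillatory-to-noise RMS ratio (> 0)
#' @slot tempoFactors named numeric, condition label -> tempo factor
#' @slot rois ROI labels to simulate
#' @slot subjectRateSD between-subject SD of the syllable rate (Hz)
#' @slot subjectGammaSD between-subject SD of the gamma frequency (Hz)
#' @slot seed master seed for the cohort
#' @seealso \code{\link{cohortConfig}}, \code{\link{generateCohort}}
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(
    nSubjects = "integer", fs = "numeric", trialDuration = "numeric",
    nTrials = "integer", syllableRate = "numeric", prosodicRate = "numeric",
    gammaFreq = "numeric", couplingDepth = "numeric",
    entrainmentStrength = "numeric", phaseLag = "numeric",
    couplingPhase = "numeric", gammaAmplitude = "numeric",
    noiseExponent = "numeric", snr = "numeric", tempoFactors = "numeric",
    rois = "character", subjectRateSD = "numeric", subjectGammaSD = "numeric",
    seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (object@fs < 4 * object@gammaFreq)
    msg <- c(msg, "fs must be >= 4 * gammaFreq (amplitude carrier aliasing)")
  if (object@couplingDepth < 0 || object@couplingDepth > 1)
    msg <- c(msg, "couplingDepth must lie in [0, 1]")
  if (object@entrainmentStrength < 0)
    msg <- c(msg, "entrainmentStrength must be >= 0")
  if (object@snr <= 0) msg <- c(msg, "snr must be > 0")
  if (object@trialDuration <= 0) msg <- c(msg, "trialDuration must be > 0")
  if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
  tf <- object@tempoFactors
  if (is.null(names(tf)) || !"normal" %in% names(tf) ||
      !isTRUE(all.equal(unname(tf["normal"]), 1)))
    msg <- c(msg, "tempoFactors must contain \"normal\" mapped to 1.0")
  if (any(tf <= 0)) msg <- c(msg, "tempoFactors must all be positive")
  rates <- c(object@syllableRate, object@prosodicRate, object@gammaFreq) *
    max(c(1, tf))
  if (any(rates >= object@fs / 2))
    msg <- c(msg, "all (tempo-scaled) rates must be below fs/2")
  if (object@subjectRateSD < 0 || object@subjectGammaSD < 0)
    msg <- c(msg, "subject jitter SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Stimulus amplitude envelope
#'
#' A nonnegative wideband amplitude envelope at sampling rate \code{fs},
#' optionally holding several equal-length trials concatenated.
#'
#' @slot samples nonnegative numeric vector
#' @slot fs sampling rate (Hz)
#' @slot condition condition label
#' @slot nTrials number of equal-length trials concatenated in \code{samples}
#' @seealso \code{\link{generateEnvelope}}, \code{\link{cochlearEnvelope}}
#' @exportClass EnvelopeSignal
setClass("EnvelopeSignal",
  representation(samples = "numeric", fs = "numeric", condition = "character",
                 nTrials = "integer"))

setValidity("EnvelopeSignal", function(object) {
  msg <- character(0)
  if (!length(object@samples)) msg <- c(msg, "samples must be non-empty")
  if (any(!is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  else if (any(object@samples < 0)) msg <- c(msg, "samples must be >= 0")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (object@nTrials < 1L ||
      length(object@samples) %% object@nTrials != 0L)
    msg <- c(msg, "samples length must be a multiple of nTrials")
  if (length(msg)) msg else TRUE
})

#' Neural (ROI) time series
#'
#' One subject x condition x ROI neural trace at fixed sampling rate, aligned
#' sample-by-sample with its paired \linkS4class{EnvelopeSignal}.
#'
#' @slot subject subject id
#' @slot condition condition label
#' @slot roi ROI label (e.g. LAC, RAC)
#' @slot samples real-valued numeric vector
#' @slot fs sampling rate (Hz)
#' @slot nTrials number of equal-length trials concatenated in \code{samples}
#' @seealso \code{\link{generateNeural}}
#' @exportClass RoiTimeSeries
setClass("RoiTimeSeries",
  representation(subject = "character", condition = "character",
                 roi = "character", samples = "numeric", fs = "numeric",
                 nTrials = "integer"))

setValidity("RoiTimeSeries", function(object) {
  msg <- character(0)
  if (!length(object@samples)) msg <- c(msg, "samples must be non-empty")
  if (any(!is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (object@nTrials < 1L ||
      length(object@samples) %% object@nTrials != 0L)
    msg <- c(msg, "samples length must be a multiple of nTrials")
  if (length(msg)) msg else TRUE
})

#' Speech-brain coherence spectrum
#'
#' Magnitude-squared coherence between a stimulus envelope and a neural trace
#' on a regular low-frequency grid (default 0.5-10 Hz in 0.5 Hz steps).
#'
#' @slot freqs frequency grid (Hz), strictly increasing
#' @slot coherence coherence values in [0, 1]
#' @slot subject,condition,roi labels
#' @slot nSegments number of Welch segments averaged
#' @seealso \code{\link{coherenceSpectrum}}, \code{\link{bandPeak}}
#' @exportClass CoherenceSpectrum
setClass("CoherenceSpectrum",
  representation(freqs = "numeric", coherence = "numeric",
                 subject = "character", condition = "character",
                 roi = "character", nSegments = "integer"))

setValidity("CoherenceSpectrum", function(object) {
  msg <- character(0)
  if (length(object@freqs) != length(object@coherence))
    msg <- c(msg, "freqs and coherence must have equal length")
  if (any(diff(object@freqs) <= 0))
    msg <- c(msg, "freqs must be strictly increasing")
  if (any(object@coherence < -1e-10 | object@coherence > 1 + 1e-10))
    msg <- c(msg, "coherence must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Phase-amplitude comodulogram
#'
#' Bias-corrected mutual information (bits) between phase dynamics on
#' \code{phaseFreqs} (rows) and neural amplitude dynamics on \code{ampFreqs}
#' (columns). \code{phaseSource} records whether phase came from the stimulus
#' envelope (\code{"stimulus"}) or from the neural signal (\code{"neural"}).
#' Plug-in MI is nonnegative; bias-corrected values may be slightly negative.
#'
#' @slot phaseFreqs phase frequency grid (Hz)
#' @slot ampFreqs amplitude frequency grid (Hz)
#' @slot mi MI matrix, \code{length(phaseFreqs)} x \code{length(ampFreqs)}
#' @slot phaseSource \code{"stimulus"} or \code{"neural"}
#' @slot subject,condition,roi labels
#' @seealso \code{\link{comodulogram}}, \code{\link{pacPeak}}
#' @exportClass Comodulogram
setClass("Comodulogram",
  representation(phaseFreqs = "numeric", ampFreqs = "numeric", mi = "matrix",
                 phaseSource = "character", subject = "character",
                 condition = "character", roi = "character"))

setValidity("Comodulogram", function(object) {
  msg <- character(0)
  if (!identical(dim(object@mi),
                 c(length(object@phaseFreqs), length(object@ampFreqs))))
    msg <- c(msg, "mi must be a phaseFreqs x ampFreqs matrix")
  if (any(!is.finite(object@mi))) msg <- c(msg, "mi must be finite")
  if (!object@phaseSource %in% c("stimulus", "neural"))
    msg <- c(msg, "phaseSource must be \"stimulus\" or \"neural\"")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort
#'
#' Container for a generated cohort: the generating
#' \linkS4class{CohortConfig}, the per-subject ground-truth table
#' (\code{subject}, \code{syllableRate}, \code{gammaFreq}), and one entry per
#' subject x condition holding the stimulus envelope and one neural trace per
#' ROI.
#'
#' @slot config the generating configuration
#' @slot subjects data.frame of per-subject ground-truth frequencies
#' @slot entries named list (\code{"<subject>|<condition>"}), each a list with
#'   elements \code{envelope} (\linkS4class{EnvelopeSignal}) and \code{neural}
#'   (named list of \linkS4class{RoiTimeSeries} by ROI)
#' @seealso \code{\link{generateCohort}}
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(config = "CohortConfig", subjects = "data.frame",
                 entries = "list"))

#' Cluster permutation result
#'
#' One cluster from a cluster-corrected paired permutation test: its boolean
#' mask over the frequency grid (1D vector or 2D matrix), the summed t
#' statistic (cluster mass), the permutation p value and the polarity
#' (+1: real > surrogate, -1: real < surrogate).
#'
#' @slot mask logical vector or matrix over the tested grid
#' @slot clusterStat summed paired-t statistic over the cluster
#' @slot pValue permutation p value in [1/(nPerm+1), 1]
#' @slot polarity +1 or -1
#' @seealso \code{\link{clusterPermutationPaired}}, \code{\link{significantMask}}
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(mask = "ANY", clusterStat = "numeric", pValue = "numeric",
                 polarity = "numeric"))

setValidity("ClusterResult", function(object) {
  msg <- character(0)
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (!object@polarity %in% c(-1, 1)) msg <- c(msg, "polarity must be +/-1")
  if (length(msg)) msg else TRUE
})
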