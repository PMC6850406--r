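# Speech-brain coherence spectra, reversed-stimulus surrogates and
# band-limited peak extraction.

#' Frequency band definition
#'
#' @param name band label (e.g. \code{"delta"}, \code{"theta"})
#' @param lo,hi band edges in Hz, \code{0 < lo < hi}
#' @return list with \code{name}, \code{lo}, \code{hi}
#' @examples
#' thetaBand <- bandDefinition("theta", 4.5, 7.5)
#' @export
bandDefinition <- function(name, lo, hi) {
  stopIfNot(lo > 0 && lo < hi, "need 0 < lo < hi")
  list(name = name, lo = lo, hi = hi)
}

#' Speech-brain coherence spectrum
#'
#' Magnitude-squared coherence \eqn{|S_{xy}|^2 / (S_{xx} S_{yy})} between a
#' stimulus envelope and a neural trace, estimated from Welch cross-spectra
#' (2 s Hann segments, 50\% overlap, segments pooled across trials) and
#' sampled on the regular grid \code{freqs} (default 0.5-10 Hz in 0.5 Hz
#' steps, realized exactly by the 2 s segment length).
#'
#' \code{surrogateCoherenceSpectrum} applies the identical estimator to the
#' time-reversed envelope (reversed within each trial) paired with the
#' unreversed neural trace, giving the chance level expected without
#' stimulus-locked activity.
#'
#' @param envelope an \linkS4class{EnvelopeSignal}
#' @param neural an aligned \linkS4class{RoiTimeSeries} at the same fs
#' @param freqs frequency grid (Hz); must be FFT bins of the segment length
#' @param segSec Welch segment length (s, default 2)
#' @return a \linkS4class{CoherenceSpectrum}
#' @examples
#' cfg <- cohortConfig(trialDuration = 30)
#' env <- generateEnvelope(cfg, "normal")
#' coh <- coherenceSpectrum(env, generateNeural(env, cfg))
#' @export
coherenceSpectrum <- function(envelope, neural,
                              freqs = seq(0.5, 10, by = 0.5), segSec = 2) {
  stopIfNot(samplingRate(envelope) == samplingRate(neural),
            "envelope and neural sampling rates differ")
  stopIfNot(length(samples(envelope)) == length(samples(neural)),
            "envelope and neural traces are not aligned (lengths differ)")
  fs <- samplingRate(envelope)
  dur <- length(samples(envelope)) / fs
  stopIfNot(dur >= 20, "total duration must be >= 20 s (got ",
            round(dur, 1), " s)")
  w <- welchSpectra(samples(envelope), samples(neural), fs = fs,
                    nTrials = nTrials(envelope), segSec = segSec)
  stopIfNot(w$K >= 10L, "fewer than 10 Welch segments (", w$K,
            "): estimate unstable")
  idx <- match(round(freqs * segSec), round(w$freqs * segSec))
  stopIfNot(!anyNA(idx), "requested grid is not aligned with the ",
            1 / segSec, " Hz segment resolution")
  coh <- Mod(w$Sxy[idx])^2 / (w$Sxx[idx] * w$Syy[idx])
  new("CoherenceSpectrum", freqs = freqs,
      coherence = pmin(1, pmax(0, coh)), subject = subjectId(neural),
      condition = conditionLabel(neural), roi = roiLabel(neural),
      nSegments = w$K)
}

#' @rdname coherenceSpectrum
#' @export
surrogateCoherenceSpectrum <- function(envelope, neural,
                                       freqs = seq(0.5, 10, by = 0.5),
                                       segSec = 2) {
  coherenceSpectrum(reverseSignal(envelope), neural, freqs = freqs,
                    segSec = segSec)
}

# Time-reverse a signal within each trial.
reverseSignal <- function(x) {
  rev_ <- unlist(lapply(splitTrials(samples(x), nTrials(x)), rev))
  if (is(x, "EnvelopeSignal"))
    envelopeSignal(rev_, fs = samplingRate(x),
                   condition = conditionLabel(x), nTrials = nTrials(x))
  else
    roiTimeSeries(rev_, fs = samplingRate(x), subject = subjectId(x),
                  condition = conditionLabel(x), roi = roiLabel(x),
                  nTrials = nTrials(x))
}

#' Band-limited coherence peak
#'
#' Maximum coherence within a band and the frequency at which it occurs
#' (Coh_max, f_c). Ties are broken toward the lowest frequency.
#'
#' @param spectrum a \linkS4class{CoherenceSpectrum}
#' @param band a band from \code{\link{bandDefinition}}
#' @return one-row data.frame with columns \code{subject}, \code{condition},
#'   \code{roi}, \code{band}, \code{cohMax}, \code{fC}
#' @examples
#' cfg <- cohortConfig(trialDuration = 30)
#' env <- generateEnvelope(cfg, "normal")
#' coh <- coherenceSpectrum(env, generateNeural(env, cfg))
#' bandPeak(coh, bandDefinition("theta", 4.5, 7.5))
#' @export
bandPeak <- function(spectrum, band) {
  inBand <- which(spectrumFreqs(spectrum) >= band$lo - 1e-9 &
                  spectrumFreqs(spectrum) <= band$hi + 1e-9)
  if (!length(inBand))
    stop("band [", band$lo, ", ", band$hi,
         "] Hz contains no grid frequencies")
  vals <- coherenceValues(spectrum)[inBand]
  k <- inBand[which.max(vals)]        # which.max takes the first maximum
  data.frame(subject = subjectId(spectrum),
             condition = conditionLabel(spectrum),
             roi = roiLabel(spectrum), band = band$name,
             cohMax = coherenceValues(spectrum)[k],
             fC = spectrumFreqs(spectrum)[k])
}
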