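# Cochlear-model wideband envelope extraction and envelope power spectra.

#' Gammatone filterbank specification
#'
#' Defines an ERB-spaced gammatone filterbank modeling peripheral (cochlear)
#' band-pass filtering. Channel centers are placed uniformly on the ERB-rate
#' scale of Glasberg & Moore between \code{fLo} and \code{fHi}.
#'
#' @param nChannels number of channels (default 24)
#' @param fLo lowest center frequency (Hz, default 100)
#' @param fHi highest center frequency (Hz, default 4000)
#' @return list with \code{nChannels}, \code{fLo}, \code{fHi},
#'   \code{spacing = "erb"} and the derived \code{channelCenters} (Hz)
#' @examples
#' filterbankSpec(12, 150, 3000)$channelCenters
#' @export
filterbankSpec <- function(nChannels = 24, fLo = 100, fHi = 4000) {
  stopIfNot(nChannels >= 4, "nChannels must be >= 4")
  stopIfNot(fLo > 0 && fLo < fHi, "need 0 < fLo < fHi")
  erbRate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
  erbRateInv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37
  centers <- erbRateInv(seq(erbRate(fLo), erbRate(fHi),
                            length.out = nChannels))
  list(nChannels = as.integer(nChannels), fLo = fLo, fHi = fHi,
       spacing = "erb", channelCenters = centers)
}

# 4th-order gammatone FIR kernel at center fc, unit peak magnitude response.
gammatoneKernel <- function(fc, fs) {
  erb <- 24.7 * (4.37 * fc / 1000 + 1)
  b <- 1.019 * erb
  dur <- min(0.04, 8 / (2 * pi * b))      # impulse response support
  t <- seq(0, dur, by = 1 / fs)[-1]
  g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * fc * t)
  # normalize to unit gain at the center frequency
  resp <- sum(g * exp(-2i * pi * fc * t))
  g / Mod(resp)
}

#' Cochlear (gammatone filterbank) envelope extraction
#'
#' Estimates the wideband amplitude envelope of an audio signal: the signal
#' is passed through an ERB-spaced gammatone filterbank, the magnitude of the
#' analytic signal is taken per channel, channel envelopes are averaged
#' (keeping the amplitude scale independent of the channel count), low-pass
#' filtered below the output Nyquist frequency and resampled to
#' \code{outFs}.
#'
#' @param audio numeric waveform, or a list with \code{samples} and \code{fs}
#'   as returned by \code{\link{readWav}}
#' @param fs audio sampling rate (Hz); ignored when \code{audio} is a list
#' @param spec filterbank specification from \code{\link{filterbankSpec}};
#'   by default 24 channels spanning 100 Hz to 4 kHz, capped below the audio
#'   Nyquist frequency
#' @param outFs output (envelope) sampling rate (Hz), below \code{fs}
#' @param condition condition label for the returned object
#' @return an \linkS4class{EnvelopeSignal} at \code{outFs}
#' @examples
#' fs <- 8000; t <- seq(0, 2, by = 1/fs)
#' audio <- (1 + 0.9 * cos(2 * pi * 5 * t)) * rnorm(length(t))
#' env <- cochlearEnvelope(audio, fs = fs, outFs = 200)
#' @export
cochlearEnvelope <- function(audio, fs = NULL, spec = NULL,
                             outFs = 200, condition = "unlabeled") {
  if (is.list(audio) && !is.null(audio$fs)) {
    fs <- audio$fs; audio <- audio$samples
  }
  if (is.null(spec))
    spec <- filterbankSpec(24, 100, min(4000, 0.45 * fs))
  stopIfNot(length(audio) > 0, "zero-length audio")
  stopIfNot(all(is.finite(audio)), "audio must be finite")
  stopIfNot(!is.null(fs) && outFs < fs, "outFs must be below the audio fs")
  stopIfNot(max(spec$channelCenters) < fs / 2,
            "filterbank extends beyond the audio Nyquist frequency")
  if (all(audio == 0))
    warning("silent (all-zero) audio; returning an all-zero envelope")
  n <- length(audio)
  m <- goodLength(2L * n)
  A <- stats::fft(c(audio, numeric(m - n)))
  acc <- numeric(n)
  for (fc in spec$channelCenters) {
    k <- gammatoneKernel(fc, fs)
    K <- stats::fft(c(k, numeric(m - length(k))))
    # analytic band signal in one pass: double positive frequencies
    h <- numeric(m); h[1] <- 1
    h[2:(m %/% 2)] <- 2
    if (m %% 2 == 0) h[m %/% 2 + 1] <- 1 else h[(m + 1) %/% 2] <- 2
    band <- stats::fft(A * K * h, inverse = TRUE)[seq_len(n)] / m
    acc <- acc + Mod(band)
  }
  env <- acc / spec$nChannels
  # anti-alias low-pass (zero-phase order-4 Butterworth magnitude) below
  # the output Nyquist, then resample
  cut <- 0.4 * outFs
  mm <- goodLength(2L * n)
  E <- stats::fft(c(env, numeric(mm - n)))
  f <- c(seq(0, mm %/% 2), seq(-(mm - mm %/% 2 - 1), -1)) * fs / mm
  E <- E / (1 + (abs(f) / cut)^8)
  env <- Re(stats::fft(E, inverse = TRUE))[seq_len(n)] / mm
  nOut <- round(n / fs * outFs)
  envelopeSignal(pmax(0, resampleTo(env, nOut)), fs = outFs,
                 condition = condition)
}

#' Envelope power spectrum
#'
#' Welch-averaged power spectrum of a mean-removed envelope on the regular
#' grid set by the segment length (2 s Hann segments with 50\% overlap give
#' the 0.5 Hz grid), up to \code{fmax}.
#'
#' @param envelope an \linkS4class{EnvelopeSignal}
#' @param fmax highest frequency to return (Hz, default 10)
#' @param segSec Welch segment length (s, default 2)
#' @return list with \code{freqs} (Hz) and \code{power}
#' @examples
#' env <- generateEnvelope(cohortConfig(trialDuration = 20), "normal")
#' ps <- envelopePowerSpectrum(env)
#' ps$freqs[which.max(ps$power)]
#' @export
envelopePowerSpectrum <- function(envelope, fmax = 10, segSec = 2) {
  fs <- samplingRate(envelope)
  nTrial <- length(samples(envelope)) / nTrials(envelope)
  if (nTrial < 2 * round(segSec * fs))
    stop("envelope too short: need at least ", 2 * segSec,
         " s per trial for the ", 1 / segSec, " Hz grid")
  w <- welchSpectra(samples(envelope), fs = fs, nTrials = nTrials(envelope),
                    segSec = segSec)
  keep <- w$freqs > 0 & w$freqs <= fmax + 1e-9
  list(freqs = w$freqs[keep], power = w$Sxx[keep])
}
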