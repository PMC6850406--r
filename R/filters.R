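# Narrow-band zero-phase filtering and analytic-signal machinery shared by
# the entrainment and PAC stages.
#
# Filtering applies the squared magnitude response of an order-4 Butterworth
# band-pass in the frequency domain (after reflect padding), which is the
# transfer function of forward-and-reverse (zero-phase) Butterworth
# filtering. Doing this spectrally keeps 1 Hz-wide bands numerically exact
# where high-order IIR recursions in transfer-function form become fragile.

# Power gain of forward+reverse order-n Butterworth band-pass at frequency f.
butterBandGain <- function(f, lo, hi, order = 4) {
  w0sq <- lo * hi
  bw <- hi - lo
  om <- (f^2 - w0sq) / (f * bw)
  g <- 1 / (1 + om^(2 * order))
  g[f == 0] <- 0
  g
}

# Reflect-pad x by `pad` samples on each side.
reflectPad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
}

padSamples <- function(fs, halfwidth, n) {
  # about three filter time constants of the band edge
  min(n - 1L, as.integer(ceiling(3 * fs / halfwidth)))
}

#' Zero-phase narrow-band filtering
#'
#' Band-pass filters a signal with the zero-phase (forward-and-reverse)
#' response of an order-\code{order} Butterworth band-pass centered at
#' \code{center} Hz with half-width \code{halfwidth} Hz. The input is
#' reflect-padded by about three filter time constants before filtering and
#' trimmed afterwards, so output length equals input length and edge
#' transients are suppressed. Stop-band attenuation one octave outside the
#' band exceeds 20 dB by a wide margin.
#'
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @param center band center (Hz)
#' @param halfwidth band half-width (Hz); the pass band is
#'   \code{center +/- halfwidth}
#' @param order order of the Butterworth low-pass prototype applied in each
#'   direction (default 4)
#' @return filtered signal, same length as \code{x}
#' @examples
#' fs <- 200; t <- seq(0, 5, by = 1/fs)
#' y <- bandpassFilter(cos(2*pi*5*t) + cos(2*pi*40*t), fs, 5, 1)
#' @export
bandpassFilter <- function(x, fs, center, halfwidth = 0.5, order = 4) {
  lo <- center - halfwidth
  hi <- center + halfwidth
  if (lo <= 0 || hi >= fs / 2)
    stop(sprintf("band [%g, %g] Hz touches 0 or Nyquist (%g Hz)",
                 lo, hi, fs / 2))
  stopIfNot(length(x) > 1, "signal too short to filter")
  n <- length(x)
  pad <- padSamples(fs, halfwidth, n)
  xp <- reflectPad(x, pad)
  m <- goodLength(length(xp))
  xp <- c(xp, numeric(m - length(xp)))
  f <- c(seq(0, m %/% 2), seq(-(m - m %/% 2 - 1), -1)) * fs / m
  g <- butterBandGain(abs(f), lo, hi, order)
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

#' Analytic phase and amplitude dynamics
#'
#' Computes the discrete analytic signal of an (already narrow-band) series
#' via the frequency-domain Hilbert construction and returns its
#' instantaneous phase (wrapped to (-pi, pi]) and nonnegative amplitude. For
#' a pure tone A cos(2 pi f t + phi) the amplitude is A and the unwrapped
#' phase advances at 2 pi f per second away from the edges; the phase of a
#' cosine at its peak is 0.
#'
#' @param x numeric signal (narrow-band)
#' @param center nominal band center (Hz), carried along as metadata
#' @return list with elements \code{phase}, \code{amplitude}, \code{center}
#' @examples
#' fs <- 200; t <- seq(0, 10, by = 1/fs)
#' dyn <- analyticDynamics(cos(2*pi*5*t), center = 5)
#' @export
analyticDynamics <- function(x, center = NA_real_) {
  if (all(x == 0))
    warning("analyticDynamics: all-zero input; amplitude is zero everywhere")
  a <- analyticOf(x)
  list(phase = Arg(a), amplitude = Mod(a), center = center)
}

# Discrete analytic signal (complex) of a real series.
analyticOf <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Band-pass + analytic signal for many band centers sharing one padded FFT.
# Returns phase and amplitude matrices (length(x) rows, one column per
# center). Pass bands are center +/- halfwidth, with the lower edge clipped
# at `lowClip` Hz so the lowest grid band stays strictly positive.
multiBandDynamics <- function(x, fs, centers, halfwidth = 0.5, order = 4,
                              lowClip = 0.1) {
  n <- length(x)
  pad <- padSamples(fs, halfwidth, n)
  xp <- reflectPad(x, pad)
  m <- goodLength(length(xp))
  xp <- c(xp, numeric(m - length(xp)))
  X <- stats::fft(xp)
  fpos <- seq(0, m %/% 2) * fs / m
  ph <- matrix(0, n, length(centers))
  am <- matrix(0, n, length(centers))
  keep <- (pad + 1L):(pad + n)
  half <- complex(length.out = m)
  for (j in seq_along(centers)) {
    lo <- max(lowClip, centers[j] - halfwidth)
    hi <- centers[j] + halfwidth
    if (hi >= fs / 2)
      stop(sprintf("band [%g, %g] Hz touches 0 or Nyquist (%g Hz)",
                   lo, hi, fs / 2))
    g <- butterBandGain(fpos, lo, hi, order)
    half[] <- 0
    half[seq_along(fpos)] <- X[seq_along(fpos)] * g * 2
    half[1] <- X[1] * g[1]          # DC not doubled (gain 0 anyway)
    a <- (stats::fft(half, inverse = TRUE) / m)[keep]
    ph[, j] <- Arg(a)
    am[, j] <- Mod(a)
  }
  list(phase = ph, amplitude = am, centers = centers)
}

# Welch segment-averaged auto-/cross-spectra on the regular grid defined by
# the segment length (2 s Hann windows, 50% overlap by default, segment
# means removed). Trials are segmented independently so segments never span
# a trial boundary. Returns spectra at all nonnegative FFT bins plus the
# segment count.
welchSpectra <- function(x, y = NULL, fs, nTrials = 1L, segSec = 2,
                         overlap = 0.5) {
  nseg <- round(segSec * fs)
  step <- max(1L, round(nseg * (1 - overlap)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  xT <- splitTrials(x, nTrials)
  yT <- if (is.null(y)) NULL else splitTrials(y, nTrials)
  nb <- nseg %/% 2 + 1L
  Sxx <- numeric(nb); Syy <- numeric(nb)
  Sxy <- complex(length.out = nb)
  K <- 0L
  for (ti in seq_along(xT)) {
    xt <- xT[[ti]]
    starts <- seq(1L, length(xt) - nseg + 1L, by = step)
    for (s in starts) {
      seg <- xt[s:(s + nseg - 1L)]
      X <- stats::fft(win * (seg - mean(seg)))[seq_len(nb)]
      Sxx <- Sxx + Mod(X)^2
      if (!is.null(y)) {
        segY <- yT[[ti]][s:(s + nseg - 1L)]
        Y <- stats::fft(win * (segY - mean(segY)))[seq_len(nb)]
        Syy <- Syy + Mod(Y)^2
        Sxy <- Sxy + X * Conj(Y)
      }
      K <- K + 1L
    }
  }
  scale <- 1 / (K * sum(win^2) * fs)
  list(freqs = seq(0, nb - 1L) * fs / nseg, Sxx = Sxx * scale,
       Syy = Syy * scale, Sxy = Sxy * scale, K = K)
}

# Per-trial band dynamics with edge trimming, concatenated across trials.
# Returns phase and amplitude matrices with sum(trialLen - 2*trim) rows.
trialBandDynamics <- function(x, fs, nTrials, centers, halfwidth, trimSec = 1,
                              lowClip = 0.1, order = 4) {
  trials <- splitTrials(x, nTrials)
  out <- lapply(trials, function(tr) {
    d <- multiBandDynamics(tr, fs, centers, halfwidth, order, lowClip)
    trim <- min(floor(trimSec * fs), (length(tr) - 2L) %/% 2L)
    keep <- (trim + 1L):(length(tr) - trim)
    list(phase = d$phase[keep, , drop = FALSE],
         amplitude = d$amplitude[keep, , drop = FALSE])
  })
  list(phase = do.call(rbind, lapply(out, `[[`, "phase")),
       amplitude = do.call(rbind, lapply(out, `[[`, "amplitude")))
}
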