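# Internal numeric helpers.

# Deterministic per-subject/condition sub-seed, kept inside 32-bit range.
subSeed <- function(seed, subject, cond) {
  as.integer((as.numeric(seed) + 7919 * subject + 104729 * cond) %%
               2147483647)
}

# FFT-friendly length (products of 2, 3, 5) for padded transforms.
goodLength <- function(n) stats::nextn(n, c(2L, 3L, 5L))

# Spectrally shaped Gaussian noise with power spectrum ~ 1/f^exponent,
# standardized to unit RMS. DC is excluded.
oneOverFNoise <- function(n, fs, exponent) {
  m <- goodLength(n)
  freqs <- seq_len(m %/% 2) * fs / m
  amp <- freqs^(-exponent / 2)
  re <- stats::rnorm(length(freqs))
  im <- stats::rnorm(length(freqs))
  spec <- complex(real = re, imaginary = im) * amp
  full <- complex(length.out = m)
  full[2:(length(freqs) + 1)] <- spec
  full[m:(m - length(freqs) + 2)] <- Conj(spec[seq_len(length(freqs) - 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / sqrt(mean(x^2))
}

rmsOf <- function(x) sqrt(mean(x^2))

# Cubic-spline resampling of a band-limited series onto a new length at the
# same sampling rate (uniform time-axis rescale).
resampleTo <- function(x, nOut) {
  if (nOut == length(x)) return(x)
  tOld <- seq(0, 1, length.out = length(x))
  tNew <- seq(0, 1, length.out = nOut)
  stats::spline(tOld, x, xout = tNew, method = "natural")$y
}

# Split a concatenated multi-trial vector into a list of trials.
splitTrials <- function(x, nTrials) {
  n <- length(x) %/% nTrials
  lapply(seq_len(nTrials), function(k) x[((k - 1) * n + 1):(k * n)])
}

# Polynomial rolling hash of a character string, reported as 8 hex digits.
# Used to stamp outputs with a stable configuration fingerprint (not
# cryptographic).
configHash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967291
  sprintf("%08x", h)
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
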