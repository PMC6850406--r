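# Shared fixture builders. Small scales keep unit tests fast; acceptance
# checks use the full study-scale settings inline.

smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(nSubjects = 2, trialDuration = 30, rois = "LAC", seed = 42)
  do.call(cohortConfig, utils::modifyList(defaults, args))
}

# A deterministic comodulogram object for peak-extraction tests.
toyComodulogram <- function(mi, phase = seq(4, 4 + 0.5 * (nrow(mi) - 1), 0.5),
                            amp = seq(30, 30 + 0.5 * (ncol(mi) - 1), 0.5)) {
  new("Comodulogram", phaseFreqs = phase, ampFreqs = amp, mi = mi,
      phaseSource = "stimulus", subject = "s01", condition = "normal",
      roi = "LAC")
}

toySpectrum <- function(values, freqs = seq(0.5, by = 0.5,
                                            length.out = length(values))) {
  new("CoherenceSpectrum", freqs = freqs, coherence = values,
      subject = "s01", condition = "normal", roi = "LAC", nSegments = 20L)
}

spectralArgmax <- function(freqs, power, lo, hi) {
  sel <- freqs >= lo & freqs <= hi
  freqs[sel][which.max(power[sel])]
}

# Independent brute-force MI oracle: explicit double loop over the joint
# histogram, no shared code with miPlugin.
miBruteForce <- function(a, b, nBins) {
  n <- length(a)
  total <- 0
  for (i in seq_len(nBins)) for (j in seq_len(nBins)) {
    nij <- sum(a == i & b == j)
    if (nij == 0) next
    pij <- nij / n
    pi_ <- sum(a == i) / n
    pj <- sum(b == j) / n
    total <- total + pij * log2(pij / (pi_ * pj))
  }
  total
}
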