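# MI-based phase-amplitude comodulograms: equipopulated binning, plug-in MI,
# quadratic-extrapolation bias correction, reversed-stimulus surrogates and
# cluster-restricted peak extraction.

#' Equipopulated quantization
#'
#' Quantizes a real series into \code{nBins} equipopulated bins (bin edges at
#' empirical quantiles). When values are distinct, per-bin counts differ by
#' at most one; rank ties are resolved by stable order of occurrence.
#'
#' @param x numeric series (not constant)
#' @param nBins number of bins (default 10)
#' @return integer vector of bin indices in \code{1:nBins}
#' @examples
#' table(quantizeEquipopulated(runif(1000), 10))
#' @export
quantizeEquipopulated <- function(x, nBins = 10) {
  stopIfNot(nBins >= 2, "nBins must be >= 2")
  stopIfNot(length(x) >= nBins, "series shorter than nBins")
  if (max(x) == min(x)) stop("degenerate (constant) signal")
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * nBins / length(x)))
}

# MI (bits) from a joint count matrix.
miFromCounts <- function(nij) {
  n <- sum(nij)
  p <- nij / n
  pi_ <- rowSums(p)
  pj <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / outer(pi_, pj)[pos]))
}

jointCounts <- function(phaseBins, ampBins, nBins) {
  matrix(tabulate(phaseBins + nBins * (ampBins - 1L), nBins * nBins),
         nBins, nBins)
}

#' Plug-in (direct) mutual information
#'
#' Direct MI estimate \eqn{\sum_{ij} p_{ij} \log_2 (p_{ij} / p_i p_j)} from
#' the joint histogram of two binned series. Nonnegative and symmetric in
#' its arguments.
#'
#' @param phaseBins,ampBins integer bin series of equal length (values in
#'   \code{1:nBins})
#' @param nBins number of bins per margin (default 10)
#' @return MI in bits
#' @examples
#' b <- quantizeEquipopulated(runif(1000), 10)
#' miPlugin(b, b)   # log2(10) for a bijection
#' @export
miPlugin <- function(phaseBins, ampBins, nBins = 10) {
  stopIfNot(length(phaseBins) == length(ampBins),
            "phase and amplitude series lengths differ")
  miFromCounts(jointCounts(as.integer(phaseBins), as.integer(ampBins),
                           as.integer(nBins)))
}

# Quadratic extrapolation to infinite sample size from plug-in MI on the
# full series, the mean over two contiguous halves and the mean over four
# contiguous quarters. With bias ~ b/N + c/N^2 the exact interpolation
# through (1/N, 2/N, 4/N) gives MI_inf = 8/3 y1 - 2 y2 + 1/3 y4.
miQuadExtrap <- function(phaseBins, ampBins, nBins) {
  n <- length(phaseBins)
  cuts <- round(seq(0, n, length.out = 5))
  q <- lapply(1:4, function(k) {
    idx <- (cuts[k] + 1L):cuts[k + 1L]
    jointCounts(phaseBins[idx], ampBins[idx], nBins)
  })
  y1 <- miFromCounts(q[[1]] + q[[2]] + q[[3]] + q[[4]])
  y2 <- (miFromCounts(q[[1]] + q[[2]]) + miFromCounts(q[[3]] + q[[4]])) / 2
  y4 <- mean(vapply(q, miFromCounts, numeric(1)))
  8 / 3 * y1 - 2 * y2 + y4 / 3
}

#' Bias-corrected mutual information (quadratic extrapolation)
#'
#' Computes plug-in MI on the full series (N samples), on its two contiguous
#' halves (averaged) and on its four contiguous quarters (averaged), then
#' extrapolates the quadratic trend in inverse sample size to infinite data.
#' The sample-size bias of the plug-in estimate (about
#' \eqn{(B-1)^2 / (2 N \ln 2)} bits for independent series with B bins) is
#' removed to second order; corrected values on independent data scatter
#' around zero and may be slightly negative.
#'
#' @inheritParams miPlugin
#' @return bias-corrected MI in bits
#' @examples
#' b1 <- quantizeEquipopulated(runif(4000), 10)
#' b2 <- quantizeEquipopulated(runif(4000), 10)
#' miBiasCorrected(b1, b2)   # near zero
#' @export
miBiasCorrected <- function(phaseBins, ampBins, nBins = 10) {
  stopIfNot(length(phaseBins) == length(ampBins),
            "phase and amplitude series lengths differ")
  if (length(phaseBins) < 40 * nBins)
    stop("series too short for bias correction: need at least ",
         40 * nBins, " samples so quarters stay populated")
  miQuadExtrap(as.integer(phaseBins), as.integer(ampBins),
               as.integer(nBins))
}

#' Phase-amplitude comodulogram
#'
#' Builds the MI matrix over all combinations of phase frequencies (default
#' 0.5-10 Hz in 0.5 Hz steps) and amplitude frequencies (default 10-50 Hz in
#' 0.5 Hz steps). Phase dynamics are taken from the stimulus envelope
#' (\code{phaseSource = "stimulus"}) or from the neural signal
#' (\code{phaseSource = "neural"}); amplitude dynamics always come from the
#' neural signal. Each narrow band is filtered per trial with the zero-phase
#' Butterworth response, Hilbert phase/amplitude are extracted, 1 s edges are
#' trimmed per trial, dynamics are concatenated across trials, quantized into
#' \code{nBins} equipopulated bins, and each cell is the (bias-corrected) MI
#' of the binned pair.
#'
#' \code{surrogateComodulogram} runs the identical computation with the
#' time-reversed phase-providing signal (reversed within each trial),
#' preserving all marginal distributions while destroying the temporal
#' alignment between phase and amplitude.
#'
#' Note on amplitude band widths: the analytic amplitude of a band of
#' half-width \eqn{h} Hz only carries modulation below about \eqn{h} Hz, so
#' detecting amplitude modulation at a syllabic (4-8 Hz) phase frequency
#' requires \code{ampHalfwidth} larger than the phase frequency of interest.
#' The default keeps the narrow 0.5 Hz analysis bands; cohort-level analyses
#' in this package use \code{ampHalfwidth = 7}.
#'
#' @param envelope the stimulus \linkS4class{EnvelopeSignal}
#' @param neural the aligned \linkS4class{RoiTimeSeries}
#' @param phaseSource \code{"stimulus"} or \code{"neural"}
#' @param phaseFreqs phase-frequency grid (Hz)
#' @param ampFreqs amplitude-frequency grid (Hz)
#' @param phaseHalfwidth half-width of phase bands (Hz, default 0.5)
#' @param ampHalfwidth half-width of amplitude bands (Hz, default 0.5)
#' @param nBins equipopulated bins per margin (default 10)
#' @param trimSec per-trial edge trim before concatenation (s, default 1)
#' @param biasCorrected use quadratic-extrapolation bias correction (default
#'   TRUE; FALSE gives plug-in MI)
#' @return a \linkS4class{Comodulogram}
#' @examples
#' cfg <- cohortConfig(trialDuration = 30)
#' env <- generateEnvelope(cfg, "normal")
#' neu <- generateNeural(env, cfg)
#' cmg <- comodulogram(env, neu, ampFreqs = seq(25, 40, 1), ampHalfwidth = 7)
#' @export
comodulogram <- function(envelope, neural, phaseSource = "stimulus",
                         phaseFreqs = seq(0.5, 10, by = 0.5),
                         ampFreqs = seq(10, 50, by = 0.5),
                         phaseHalfwidth = 0.5, ampHalfwidth = 0.5,
                         nBins = 10, trimSec = 1, biasCorrected = TRUE) {
  if (!phaseSource %in% c("stimulus", "neural"))
    stop("unknown phaseSource '", phaseSource,
         "' (use \"stimulus\" or \"neural\")")
  phaseSig <- if (phaseSource == "stimulus") envelope else neural
  comodulogramCore(phaseSig, neural, phaseSource, phaseFreqs, ampFreqs,
                   phaseHalfwidth, ampHalfwidth, nBins, trimSec,
                   biasCorrected)
}

#' @rdname comodulogram
#' @export
surrogateComodulogram <- function(envelope, neural, phaseSource = "stimulus",
                                  phaseFreqs = seq(0.5, 10, by = 0.5),
                                  ampFreqs = seq(10, 50, by = 0.5),
                                  phaseHalfwidth = 0.5, ampHalfwidth = 0.5,
                                  nBins = 10, trimSec = 1,
                                  biasCorrected = TRUE) {
  if (!phaseSource %in% c("stimulus", "neural"))
    stop("unknown phaseSource '", phaseSource,
         "' (use \"stimulus\" or \"neural\")")
  phaseSig <- reverseSignal(if (phaseSource == "stimulus") envelope
                            else neural)
  comodulogramCore(phaseSig, neural, phaseSource, phaseFreqs, ampFreqs,
                   phaseHalfwidth, ampHalfwidth, nBins, trimSec,
                   biasCorrected)
}

comodulogramCore <- function(phaseSig, neural, phaseSource, phaseFreqs,
                             ampFreqs, phaseHalfwidth, ampHalfwidth, nBins,
                             trimSec, biasCorrected) {
  stopIfNot(samplingRate(phaseSig) == samplingRate(neural),
            "phase and amplitude signal sampling rates differ")
  stopIfNot(length(samples(phaseSig)) == length(samples(neural)),
            "phase and amplitude signals are not aligned (lengths differ)")
  fs <- samplingRate(neural)
  ph <- trialBandDynamics(samples(phaseSig), fs, nTrials(phaseSig),
                          phaseFreqs, phaseHalfwidth, trimSec)$phase
  am <- trialBandDynamics(samples(neural), fs, nTrials(neural),
                          ampFreqs, ampHalfwidth, trimSec)$amplitude
  n <- nrow(ph)
  if (biasCorrected && n < 40 * nBins)
    stop("too little data after edge trimming (", n, " samples, need ",
         40 * nBins, "); use longer trials")
  phB <- matrix(0L, n, ncol(ph))
  for (j in seq_len(ncol(ph)))
    phB[, j] <- quantizeEquipopulated(ph[, j], nBins)
  amB <- matrix(0L, n, ncol(am))
  for (j in seq_len(ncol(am)))
    amB[, j] <- quantizeEquipopulated(am[, j], nBins)
  mi <- matrix(0, length(phaseFreqs), length(ampFreqs))
  for (i in seq_along(phaseFreqs)) {
    pb <- phB[, i]
    for (j in seq_along(ampFreqs)) {
      mi[i, j] <- if (biasCorrected) miQuadExtrap(pb, amB[, j], nBins)
                  else miFromCounts(jointCounts(pb, amB[, j], nBins))
    }
  }
  new("Comodulogram", phaseFreqs = phaseFreqs, ampFreqs = ampFreqs, mi = mi,
      phaseSource = phaseSource, subject = subjectId(neural),
      condition = conditionLabel(neural), roi = roiLabel(neural))
}

#' Comodulogram peak (MI_max, f_phase, f_amp)
#'
#' Argmax of the MI matrix, optionally restricted to a cluster mask (e.g.
#' from \code{\link{significantMask}}). Ties are broken toward the lowest
#' phase frequency, then the lowest amplitude frequency.
#'
#' @param comod a \linkS4class{Comodulogram}
#' @param clusterMask logical matrix of the same shape, or NULL for the whole
#'   matrix
#' @return one-row data.frame with columns \code{subject}, \code{condition},
#'   \code{roi}, \code{miMax}, \code{fPhase}, \code{fAmp}
#' @export
pacPeak <- function(comod, clusterMask = NULL) {
  mi <- miMatrix(comod)
  if (is.null(clusterMask)) clusterMask <- array(TRUE, dim(mi))
  stopIfNot(identical(dim(clusterMask), dim(mi)),
            "cluster mask shape does not match the comodulogram")
  clusterMask <- array(as.logical(clusterMask), dim(mi))
  if (!any(clusterMask)) stop("no significant cluster")
  vals <- ifelse(clusterMask, mi, -Inf)
  best <- max(vals)
  cand <- arrayInd(which(vals == best), dim(mi))
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  data.frame(subject = subjectId(comod), condition = conditionLabel(comod),
             roi = roiLabel(comod), miMax = best,
             fPhase = phaseFreqs(comod)[cand[1, 1]],
             fAmp = ampFreqs(comod)[cand[1, 2]])
}
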