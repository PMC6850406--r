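---
title: "speechPAC: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{speechPAC: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechPAC)
```

`speechPAC` quantifies two coupled phenomena in auditory neurophysiology:
low-frequency cortical entrainment to the speech envelope, and
phase–amplitude coupling (PAC) between the entrained theta oscillation and
faster gamma activity. This vignette is the package's own account of the
generative model behind its synthetic cohorts, the estimators, the numerical
choices, and the places where the design was genuinely open.

## 1. The generative model

Every validation in this package runs on synthetic cohorts with known
ground truth, produced by `generateCohort()` from a `CohortConfig`.

**Stimulus envelope.** A syllable sequence is modeled as a renewal pulse
train: inter-pulse intervals are $T + \epsilon_k$ with $T = 1/r$ the
syllabic period (`syllableRate` $r$, default 5.5 Hz) and
$\epsilon_k \sim \mathcal N(0, (0.1\,T)^2)$ truncated at $\pm 0.45\,T$ so
intervals stay positive. Pulses (amplitudes jittered uniformly in
[0.8, 1.2]) are smoothed with a raised-cosine kernel of width $0.6\,T$ and
multiplied by a slow prosodic modulation
$1 + 0.4\cos(2\pi r_p t + \varphi)$ (`prosodicRate` $r_p$, default 1.8 Hz).
The resulting nonnegative envelope has spectral peaks at the prosodic
(delta) and syllabic (theta) rates.

The *renewal* (cumulative-interval) form of the jitter matters: it makes the
syllabic phase diffuse, as in natural syllable sequences where timing errors
accumulate. A pulse train jittered around a rigid grid keeps long-range
phase order, and its time-reversed copy stays almost as coherent with the
entrained brain signal as the forward one — which would defeat
reversed-stimulus surrogates entirely. With renewal timing the phase
coherence time is a few seconds, so reversal destroys alignment while the
spectral peak stays within one 0.5 Hz bin of the rate.

**Tempo manipulation.** `applyTempo(envelope, factor)` rescales the time
axis by cubic-spline resampling to duration/factor at unchanged sampling
rate, multiplying every envelope rhythm by the factor — the envelope-level
equivalent of pitch-preserving time compression of the audio. Cohorts
generate each subject's normal-tempo stimulus once and derive the
accelerated (1.25) and decelerated (0.75) conditions from it, so conditions
share underlying "sentences" as in a real tempo-manipulated design.

**Neural trace.** For condition tempo factor $c$, one ROI trace is

$$x(t) = e\,\cos\phi_\theta(t)
 + a\,\bigl(1 + m \cos(\phi_\theta(t) - \phi_0)\bigr)
   \cos(2\pi c f_\gamma t + \psi) + \eta(t),$$

where $\phi_\theta$ is the analytic phase of the envelope band-passed
around $c\,r$ (half-width 1 Hz) plus a stimulus-to-brain lag
(`phaseLag`, default 0); $e$ is `entrainmentStrength` (default 1); $a$ is
`gammaAmplitude` (default 0.5, the gamma-to-theta amplitude ratio); $m$ is
`couplingDepth` (default 0.7); $f_\gamma$ is `gammaFreq` (default 33 Hz,
scaled by the tempo factor so the nested rhythm follows the rate); $\psi$
is a random carrier phase; and $\eta$ is $1/f$ Gaussian noise
(`noiseExponent`, default 1) scaled so the oscillation-to-noise RMS ratio
equals `snr` (default 1). Deriving $\phi_\theta$ from the envelope itself
guarantees that entrainment strength, coupling frequency and coupling depth
are jointly controlled by interpretable dials.

**Between-subject variability.** Subject syllable rates and gamma
frequencies are drawn once per cohort with SDs `subjectRateSD` = 0.25 Hz
and `subjectGammaSD` = 1.5 Hz, giving group-level peak distributions with a
realistic spread of a few bins. All randomness derives deterministically
from the config seed and subject/condition/ROI indices, so identical
configs give bitwise-identical cohorts.

**What the generator does not emulate.** No phonemic/articulatory
structure, no delta-band entrainment component (the prosodic rhythm lives
in the stimulus only), no sensor-level mixing or artifacts, no
heteroscedastic noise across subjects, and gamma is a single
amplitude-modulated carrier rather than broadband activity. Passing tests
therefore demonstrate estimator correctness and pipeline behavior under a
controlled oscillatory model — not robustness to every property of real
recordings.

**Default rates.** Signals are generated at 200 Hz. All analysis bands lie
below 50 Hz, so this is comfortable; `fs = 1000` remains available for
acquisition-style rates at proportional cost.

## 2. Envelope extraction

`cochlearEnvelope()` passes audio through an ERB-spaced gammatone
filterbank (default 24 channels, 100 Hz – 4 kHz, capped below the audio
Nyquist), takes the per-channel analytic amplitude, *averages* across
channels (keeping amplitude scale independent of channel count), applies a
zero-phase order-4 low-pass below the output Nyquist and resamples (default
200 Hz). These are conventional cochlear-model parameters; the channel
count and range are declared defaults, not facts about any particular
dataset. `envelopePowerSpectrum()` uses Welch averaging (2 s Hann, 50 %
overlap) on the mean-removed envelope, giving the 0.5 Hz grid.

## 3. Coherence

`coherenceSpectrum()` estimates magnitude-squared coherence
$|S_{xy}|^2/(S_{xx} S_{yy})$ from Welch cross-spectra: 2 s Hann segments,
50 % overlap, segment means removed, segments pooled across trials (never
spanning a trial boundary), evaluated on the exact FFT bins 0.5–10 Hz. The
segment length is what realizes the 0.5 Hz resolution; the estimator
settings themselves were an open choice and are exposed as arguments.

Two identities anchor the tests: self-coherence is exactly 1 in every bin,
and for independent signals the expected coherence is approximately $1/K$
for $K$ segments (slightly above, because 50 % overlapping segments are
correlated; the tests allow 20 % for this).

`surrogateCoherenceSpectrum()` pairs the within-trial time-reversed
envelope with the unreversed neural trace — same-trial reversal, the
simplest pairing consistent with a reversed-stimulus chance level.
`bandPeak()` extracts (Coh\_max, f\_c) by argmax within a band, ties going
to the lowest frequency.

## 4. PAC comodulograms

For each phase frequency (0.5–10 Hz, 0.5 Hz steps) and amplitude frequency
(10–50 Hz, 0.5 Hz steps), signals are band-pass filtered per trial, the
Hilbert transform gives phase and amplitude dynamics, 1 s edges are trimmed
per trial (filter transients), dynamics are concatenated across trials,
quantized into 10 equipopulated bins, and each cell is the bias-corrected
MI of the binned pair. Phase is binned on its circular value in
$(-\pi,\pi]$ exactly like any real series — for a uniform phase
distribution, equipopulated bins are phase sectors.

**Equipopulated binning** puts bin edges at empirical quantiles
(`rank(..., ties = "first")`), so counts differ by at most one and ties
resolve by order of occurrence. **Plug-in MI** is the direct histogram
estimate; an independent brute-force double loop over the joint histogram
serves as its oracle in the tests. **Bias correction** computes plug-in MI
on the full series, its two contiguous halves (averaged) and its four
contiguous quarters (averaged) and extrapolates the quadratic trend in
$1/N$ to $N \to \infty$; with the three abscissae $1/N, 2/N, 4/N$ the
extrapolation has the closed form
$\mathrm{MI}_\infty = \tfrac83 y_1 - 2 y_2 + \tfrac13 y_4$. Contiguous
blocks (rather than interleaved subsamples) preserve the autocorrelation of
the dynamics within each sub-series, which is what the bias model assumes.
Corrected values on independent data scatter around zero and may be
slightly negative; the minimum series length is 40 × the bin count so
quarters stay populated.

**Amplitude bandwidth.** The analytic amplitude of a band of half-width
$h$ Hz is itself band-limited to about $h$ Hz. Amplitude modulation at a
syllabic phase frequency (4–8 Hz) is therefore *invisible* through ±0.5 Hz
(or ±2 Hz) amplitude bands on an amplitude-modulated carrier: the
modulation sidebands at $f_\gamma \pm f_p$ fall outside the passband. The
comodulogram keeps `ampHalfwidth = 0.5` as the grid-fidelity default, but
every cohort-level analysis in this package (pipeline default, tests,
acceptance) uses `ampHalfwidth = 7`, chosen so that sidebands at the
highest tempo-scaled syllable rate (≈ 6.9 Hz accelerated) lie inside the
amplitude passband. One side effect: amplitude bands centered below ≈ 17 Hz
then overlap the theta/delta range itself, producing genuine (but
uninteresting) MI between theta phase and "amplitude" that contains the
theta oscillation; peak extraction for the theta–gamma cluster therefore
restricts to amplitude frequencies ≥ 20 Hz, and the group cluster test
handles the rest (those cells behave the same in real and surrogate data
only when no stimulus coupling exists).

**Phase source.** Both speech-phase × neural-amplitude
(`phaseSource = "stimulus"`, the default) and neural-phase ×
neural-amplitude (`"neural"`) comodulograms are first-class; on strongly
entrained signals the two agree to within one grid cell (tested), because
the entrained theta inherits the stimulus phase. Neither mode is asserted
to be "the" canonical computation.

`surrogateComodulogram()` time-reverses the phase-providing signal within
each trial; applying the reversal twice reproduces the real comodulogram
exactly. `pacPeak()` extracts (MI\_max, f\_phase, f\_amp), optionally
restricted to a cluster mask, ties toward the lowest phase then amplitude
frequency.

## 5. Group statistics

`clusterPermutationPaired()` implements the paired two-tailed sign-flip
permutation test with cluster correction: per-bin paired $t$ of
(real − surrogate); bins beyond the two-sided $p = 0.05$ point of
$t_{n-1}$ form clusters by adjacency (1D contiguity; 2D 4-connectivity —
the conservative choice, 8-connectivity would merge diagonal neighbors);
cluster mass is the summed $t$; the null is the maximum |mass| over
`nPerm` random sign flips; cluster $p = (1 + \#\{null \ge
|mass|\})/(nPerm + 1)$. The cluster-forming threshold and adjacency were
not externally fixed, so both are configurable. Subjects are put in a
canonical order (sorted difference rows) before the seeded draws, making
p-values invariant to input subject order. `significantMask()` unions
positive clusters below alpha into the mask consumed by peak extraction.

On null cohorts the measured family-wise error at `nPerm = 500` over 200
replicates is within 0.05 ± 0.03 (tested).

## 6. Pipeline and problem sizes

`runAll()` chains simulate → coherence → PAC → cluster statistics → peak
tables → group report, writing tidy TSVs plus a JSON manifest (config echo,
stable config hash, seed, package version, file list). Defaults run 10
subjects × 3 conditions × 2 ROIs at 60 s per condition with a 1 Hz
amplitude-grid step and `nPerm = 200` — a few minutes on one core; the full
0.5 Hz amplitude grid and `nPerm = 1000` are config switches away. Stages
are re-runnable from intermediate TSVs through the thin CLI
(`inst/scripts/speechpac.R`).

Validation scales were chosen to exercise each claim at desk scale: 10–20
subjects or replicates for recovery and surrogate-ordering checks, 100
replicates for MI bias Monte-Carlo, 200 replicates × 500 permutations for
the family-wise-error calibration.

Peak extraction over tempo-manipulated cohorts uses a tempo-agnostic theta
search band of 3–9 Hz: wide enough to contain the syllabic peak under
factors 0.75–1.25 applied to a 5.5 ± 0.75 Hz base rate, while excluding the
prosodic peak. Condition-specific bands remain available through
`bandDefinition()`.

## 7. Numerical choices

* **Filtering** applies the squared magnitude response of an order-4
  Butterworth band-pass in the frequency domain after reflect-padding by
  about three filter time constants. This *is* the forward-and-reverse
  (zero-phase) Butterworth response, while avoiding the numerical fragility
  of 8th-order recursive transfer functions for 1 Hz-wide bands; "order 4"
  refers to the low-pass prototype applied in each direction.
* The lowest analysis band (center 0.5 Hz, half-width 0.5 Hz) would touch
  0 Hz; its low edge is clipped to 0.1 Hz. `bandpassFilter()` itself
  rejects bands touching DC or Nyquist by name.
* All-zero signals: `analyticDynamics()` warns and returns zero amplitude;
  silent audio yields an all-zero envelope with a warning; constant series
  are rejected by the quantizer ("degenerate (constant) signal").
* Argmax ties break toward low frequencies everywhere, making peak tables
  deterministic.
* Quadratic MI extrapolation uses exact interpolation weights (8/3, −2,
  1/3); no least-squares fit is needed for three points.

## 8. Known limitations

* The deterministic AM-carrier gamma makes PAC detection *easier* than in
  broadband gamma; real-data MI values will be far smaller than the ~0.5
  bits seen on default synthetic cohorts (group MI levels around $10^{-3}$
  bits are typical in recordings).
* Welch coherence with 50 % overlap is slightly biased above $1/K$ under
  independence; tests account for this, but users comparing to an exact
  $1/K$ chance level should prefer the surrogate spectra.
* The cluster test assumes exchangeable signs of paired differences under
  the null (symmetric differences) — appropriate for real-vs-surrogate
  designs, not for arbitrary two-sample comparisons.
* `readWav`/`writeWav` cover uncompressed PCM and IEEE-float RIFF only.
* Cubic-spline tempo rescaling is exact only for band-limited envelopes;
  composition of factors agrees to ~1 % of the envelope amplitude, not
  bitwise.

## 9. A two-minute demonstration

```{r demo, eval = FALSE}
cfg <- cohortConfig(nSubjects = 3, trialDuration = 60, rois = "LAC",
                    seed = 1)
coh <- generateCohort(cfg)
env <- cohortEnvelope(coh, "s01", "normal")
neu <- cohortNeural(coh, "s01", "normal", "LAC")

plot(coherenceSpectrum(env, neu))
cmg <- comodulogram(env, neu, ampHalfwidth = 7)
plot(cmg)
pacPeak(cmg)
```
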