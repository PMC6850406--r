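# speechPAC

Speech–brain entrainment and theta–gamma phase–amplitude coupling analysis
for M/EEG-type recordings, with a ground-truth synthetic cohort generator.

## The scientific problem

When people listen to speech, low-frequency cortical oscillations in
auditory cortex align with the slow amplitude modulations of the acoustic
signal: the wideband *speech envelope* carries prosodic (delta, < 3 Hz) and
syllabic (theta, 4–7 Hz) rhythms, and theta-band neural activity tracks the
syllabic rate. On top of that, the phase of the entrained theta oscillation
modulates the amplitude of faster gamma activity (theta–gamma
phase–amplitude coupling, PAC), a putative mechanism for parsing syllables
into finer phonemic units. Two quantitative questions follow: does the
theta entrainment peak follow the speech rate when speech is accelerated or
decelerated, and does the gamma frequency that is coupled to theta phase
shift along with it?

`speechPAC` implements the full analysis chain needed to answer both on
real or simulated data:

1. **Envelope extraction** — gammatone (cochlear-model) filterbank, ERB
   spacing; per-channel analytic amplitude, channel averaging, anti-alias
   low-pass and resampling (`cochlearEnvelope`, `envelopePowerSpectrum`).
2. **Entrainment** — Welch magnitude-squared coherence between envelope and
   neural trace on a 0.5 Hz grid from 0.5–10 Hz
   (`coherenceSpectrum`), with band peaks (Coh\_max, f\_c) via `bandPeak`.
3. **PAC** — mutual-information comodulograms over phase (0.5–10 Hz) ×
   amplitude (10–50 Hz) grids: zero-phase narrow-band filtering, Hilbert
   phase/amplitude, 10 equipopulated bins, direct MI with
   quadratic-extrapolation bias correction (`comodulogram`, `miPlugin`,
   `miBiasCorrected`), peaks (MI\_max, f\_phase, f\_amp) via `pacPeak`.
4. **Chance levels** — reversed-stimulus surrogates
   (`surrogateCoherenceSpectrum`, `surrogateComodulogram`).
5. **Group statistics** — two-tailed paired sign-flip permutation tests
   with cluster-based multiple-comparison correction in 1D and 2D
   (`clusterPermutationPaired`, `significantMask`).
6. **Synthetic cohorts** — multi-subject stimulus/brain pairs with known
   syllable rate, gamma frequency, coupling depth, entrainment strength,
   tempo factors and 1/f noise (`cohortConfig`, `generateCohort`), so every
   stage can be validated against ground truth.

## The core statistic

For phase frequency $f_p$ and amplitude frequency $f_a$, the signals are
band-pass filtered (zero-phase, order-4 Butterworth response, ±0.5 Hz), the
Hilbert transform gives phase $\phi_{f_p}(t)$ and amplitude $A_{f_a}(t)$,
each series is quantized into 10 equipopulated bins, and

$$\mathrm{MI}(f_p, f_a) = \sum_{i,j} p_{ij}\,
\log_2 \frac{p_{ij}}{p_i\, p_j} \quad \text{(bits)}$$

over the 10 × 10 joint histogram. The finite-sample bias of the plug-in
estimate (≈ $(B-1)^2 / (2N\ln 2)$ for independent series with $B$ bins) is
removed by computing MI on the full series, its two halves and its four
quarters and extrapolating the quadratic trend in inverse sample size to
infinite data:
$\mathrm{MI}_\infty = \tfrac{8}{3}\mathrm{MI}_N - 2\,\overline{\mathrm{MI}}_{N/2} + \tfrac13\,\overline{\mathrm{MI}}_{N/4}.$

Entrainment uses Welch magnitude-squared coherence
$C(f) = |S_{xy}(f)|^2 / (S_{xx}(f)\,S_{yy}(f)) \in [0, 1]$
with 2 s Hann segments and 50 % overlap, which realizes the 0.5 Hz grid
exactly.

## Worked example

```r
library(speechPAC)

cfg <- cohortConfig(nSubjects = 3, trialDuration = 60, rois = "LAC", seed = 1)
coh <- generateCohort(cfg)
groundTruth(coh)
#>   subject syllableRate gammaFreq
#> 1     s01     5.343387  35.39292
#> 2     s02     5.545911  33.49426
#> 3     s03     5.291093  31.76930

env <- cohortEnvelope(coh, "s01", "normal")
neu <- cohortNeural(coh, "s01", "normal", "LAC")

coherenceSpectrum(env, neu)
#> CoherenceSpectrum s01/normal/LAC: 0.5-10 Hz (20 bins, 59 segments);
#>   max 0.967 @ 5.5 Hz
bandPeak(coherenceSpectrum(env, neu), bandDefinition("theta", 3, 9))
#>   subject condition roi  band    cohMax  fC
#> 1     s01    normal LAC theta 0.9672909 5.5

cmg <- comodulogram(env, neu, ampHalfwidth = 7)
pacPeak(cmg)
#>   subject condition roi     miMax fPhase fAmp
#> 1     s01    normal LAC 0.7150106    5.5 35.5
```

The coherence peak sits at subject s01's syllable rate (5.34 Hz, nearest
0.5 Hz bin 5.5), and the comodulogram maximum recovers the injected
coupling between theta phase at the syllable rate and the subject's gamma
carrier (35.39 Hz, nearest bin 35.5) — 0.72 bits against a reversed-stimulus
surrogate maximum of 0.019 bits. `runAll()` (or the CLI in
`inst/scripts/speechpac.R`) chains simulation, coherence, PAC,
cluster-corrected group statistics and tidy peak/report tables for a whole
cohort; see the methods vignette for the model and every tunable constant.

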