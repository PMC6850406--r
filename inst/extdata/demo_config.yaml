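# Demo pipeline configuration: 10 subjects, 60 s per condition, two ROIs.
# Every analysis constant is surfaced here; omitted keys take the package
# defaults (see defaultPipelineConfig()).
cohort:
  nSubjects: 10
  fs: 200
  trialDuration: 60
  nTrials: 1
  syllableRate: 5.5
  prosodicRate: 1.8
  gammaFreq: 33
  couplingDepth: 0.7
  entrainmentStrength: 1
  snr: 1
  tempoFactors:
    decelerated: 0.75
    normal: 1.0
    accelerated: 1.25
  rois: [LAC, RAC]
  subjectRateSD: 0.25
  subjectGammaSD: 1.5
  seed: 1
analysis:
  cohGrid: {lo: 0.5, hi: 10, step: 0.5}
  deltaBand: {lo: 0.5, hi: 2}
  thetaBand: {lo: 3, hi: 9}
  phaseSource: stimulus
  phaseGrid: {lo: 0.5, hi: 10, step: 0.5}
  ampGrid: {lo: 10, hi: 50, step: 1}
  phaseHalfwidth: 0.5
  ampHalfwidth: 7
  nBins: 10
stats:
  nPerm: 200
  alpha: 0.05
  clusterFormingP: 0.05
  seed: 1
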