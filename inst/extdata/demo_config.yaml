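# Demo run: synthetic cohort at the study's size, all four mQTL SNPs.
seed: 20260925
snps: all
synthetic:
  n_cases: 412
  n_controls: 424
  prevalence: 0.01
bootstrap:
  B: 200
  stratified: true
  level: 0.95
exclusions: none
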