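# Demonstration pipeline configuration: simulate a small survey cohort,
# score it with both CERT scores, fit the CERT association suite, draw one
# winsorized risk curve and emit the baseline table.
seed: 1
output_dir: certscore-demo
cohort:
  source: simulate
  n_subjects: 2000
scores: [CERT1, CERT2]
associations:
  enabled: true
  predictors: [CERT1, CERT2]
  outcomes: [prevalent, new_onset]
curves:
  - predictor: cer_18_0
    outcome: prevalent
baseline_tables: [prevalent_status]
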