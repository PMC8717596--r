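# Demonstration pipeline configuration: desk-scale synthetic cohort.
seed: 42
generator:
  n_hospitals: 30
  n_patients: 5000
  mean_episodes_per_patient: 4
dea:
  rts: vrs
  bootstrap_B: 1000
  alpha: 0.05
  weights: episodes
pseudonymise: false
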