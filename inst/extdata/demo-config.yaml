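# Demonstration pipeline configuration: simulates a cohort on the packaged
# bilateral language parcellation with a second-period decrease planted on
# a left inferior-parietal subnetwork, then runs the full analysis battery.
seed: 42
fraction: 0.3
scores: true
quiet: false
simulation:
  n_participants: 30
  dropout_per_period: [0, 4]
  asymmetry_delta: 0.15
  plasticity_sd: 1.0
  planted_effects:
    - edges:
        - [L_PF, L_PFm]
        - [L_PFm, L_PGi]
        - [L_PGi, L_PGs]
        - [L_PGs, L_STV]
        - [L_PF, L_PFt]
      period: second
      direction: increase
      magnitude: 1.5
nbs:
  n_perm: 500
  p_threshold: 0.01
  alpha: 0.05
analyses:
  subgroup: false
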