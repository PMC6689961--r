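# Example configuration for the eqnoise command-line pipeline.
# Group locations follow the reported group pseudo-medians of internal
# noise; efficiency is identical across groups by construction.
task:
  n_wavelets: 7
  peak_sf: 6
  sf_bandwidth: 1.6
  ori_bandwidth: 25
  eccentricity: 2.8
  stim_duration: 400
  noise_levels: [0, 8, 16]
  chord_length: 1.4
staircase:
  max_trials: 40
  max_reversals: 12
cohort:
  seed: 20260920
  lapse_range: [0.0, 0.02]
  groups:
    - name: control
      n_subjects: 5
      sigma_int_location: 4.51
      sigma_int_scale: 0.25
      efficiency_location: 0.7
      efficiency_scale: 0.25
    - name: mtbi
      n_subjects: 5
      sigma_int_location: 6.1
      sigma_int_scale: 0.25
      efficiency_location: 0.7
      efficiency_scale: 0.25
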