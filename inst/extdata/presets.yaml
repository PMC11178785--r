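# Frozen phenotype presets. Pilus nucleation rates, pilus-length parameters,
# recoil behavior and tether jitter are free calibration parameters fixed
# once by a coarse grid search against the published cohort statistics and
# not revisited (see the methods vignette); the retraction-speed support is
# the observed 0.3-2 um/s range.
WT:
  mode_fractions: {twitcher: 0.955, tethered: 0.045, roller: 0.0}
  pilus_nucleation_rate: 0.085
  pilus_length_mean: 1.5
  pilus_length_sd: 0.5
  pilus_length_max: 14.0
  retraction_speed_mean: 0.3
  retraction_speed_sd: 0.15
  retraction_speed_min: 0.3
  retraction_speed_max: 2.0
  multi_pilus_max: 3
  recoil_step: 0.3
  recoil_prob: 0.3
  tether_jitter_sd: 0.15
  roller_speed: 0.3
  roller_dwell_max: 60.0
  localization_noise_sd: 0.04
  duration: 300.0
  frame_interval: 1.0
daapF:
  mode_fractions: {twitcher: 0.97, tethered: 0.03, roller: 0.0}
  pilus_nucleation_rate: 0.00317
  pilus_length_mean: 2.5
  pilus_length_sd: 0.2
  pilus_length_max: 14.0
  retraction_speed_mean: 0.3
  retraction_speed_sd: 0.15
  retraction_speed_min: 0.3
  retraction_speed_max: 2.0
  multi_pilus_max: 3
  recoil_step: 0.3
  recoil_prob: 0.25
  tether_jitter_sd: 0.1
  roller_speed: 0.3
  roller_dwell_max: 60.0
  localization_noise_sd: 0.03
  duration: 300.0
  frame_interval: 1.0
darlJ:
  mode_fractions: {twitcher: 0.99, tethered: 0.01, roller: 0.0}
  pilus_nucleation_rate: 0.1
  pilus_length_mean: 1.5
  pilus_length_sd: 0.5
  pilus_length_max: 14.0
  retraction_speed_mean: 0.3
  retraction_speed_sd: 0.15
  retraction_speed_min: 0.3
  retraction_speed_max: 2.0
  multi_pilus_max: 3
  recoil_step: 0.3
  recoil_prob: 0.3
  tether_jitter_sd: 0.15
  roller_speed: 0.3
  roller_dwell_max: 60.0
  localization_noise_sd: 0.04
  duration: 300.0
  frame_interval: 1.0
daapB:
  mode_fractions: {twitcher: 0.05, tethered: 0.75, roller: 0.2}
  pilus_nucleation_rate: 0.00317
  pilus_length_mean: 2.0
  pilus_length_sd: 0.5
  pilus_length_max: 14.0
  retraction_speed_mean: 0.3
  retraction_speed_sd: 0.15
  retraction_speed_min: 0.3
  retraction_speed_max: 2.0
  multi_pilus_max: 3
  recoil_step: 0.3
  recoil_prob: 0.3
  tether_jitter_sd: 0.15
  roller_speed: 0.3
  roller_dwell_max: 60.0
  localization_noise_sd: 0.04
  duration: 300.0
  frame_interval: 1.0
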