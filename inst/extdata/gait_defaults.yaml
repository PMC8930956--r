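# Default study conditions: cohort demographics and level-walking gait
# waveform templates.
#
# Demographics reproduce the study cohort (15 patients, 8 men, age 50 +/- 14 y,
# BMI 30 +/- 4 kg/m2); truncation bounds and height distributions are
# physiological choices (unpublished in the source cohort).
#
# Gait templates are sum-of-harmonics level-walking waveforms: dominant
# flexion/extension, smaller abduction and rotation channels, and a
# double-peaked stance-phase joint reaction force with near-zero swing load.
# peak_bw and the flexion amplitude are the calibration constants anchoring
# the DM22PE cohort-mean volumetric wear to its published control value
# (see the methods vignette); both stay inside physiological ranges
# (peak JRF 2-4 BW, summed angular path 1.0-2.5 rad per cycle).
demographics:
  n: 15
  n_male: 8
  age: {mean: 50.0, sd: 14.0, min: 18.0, max: 90.0}
  bmi: {mean: 30.0, sd: 4.0, min: 18.0, max: 45.0}
  height_male: {mean: 1.76, sd: 0.07, min: 1.40, max: 2.10}
  height_female: {mean: 1.63, sd: 0.06, min: 1.40, max: 2.10}
  jrf_scale: {mean: 1.00, sd: 0.15, min: 0.76, max: 1.28}
gait:
  cycle_duration_s: 1.1
  angles_deg:
    flexion:   {mean: 10.0, c1: 14.0, s1: 0.0, c2: 0.0, s2: 3.0}
    abduction: {mean: 0.0, c1: 0.0, s1: 5.0, c2: 0.0, s2: 0.0}
    rotation:  {mean: 0.0, c1: 0.0, s1: -4.0, c2: 1.0, s2: 0.0}
  jrf:
    stance_fraction: 0.62
    swing_bw: 0.30
    peak_bw: 2.95
    double_peak_depth: 0.50
    direction: {medial: -0.25, anterior_mean: 0.10, anterior_sway: 0.15}
  variability:
    patient_amp_sd: 0.08
    cycle_amp_sd: 0.03
    cycle_jrf_sd: 0.02
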