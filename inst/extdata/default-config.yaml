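# Full default study configuration. Any omitted field falls back to the
# package default; see ?default_config for the schema.
version: 1
seed: 1
calibration:
  extent_px: 1024
  extent_deg: 29.86
  distance_mm: 600
texture:
  mu: 0.07          # band-pass peak, cycles/pixel
  sigma: 120        # bandwidth multiplier (s.d. = sigma * mu cycles/image)
  size: 1024
  n_per_type: 10
  ee_width_deg: 0.63
  ee_offset_L: 60
  ee_profile: flat
leaves:
  n_leaves: 4096
  mean_height_deg: 0.68
  height_jitter: 0.25
  shadow_fraction: 0.30
  n_backgrounds: 10
snake:
  baseline_width_px: 82
  height_deg: 9.73
  thickness_deg: 0.45
  periods: 2.5
  separation_deg: 15.9
  y_offset_max_deg: 1.49
design:
  colourations: [uniform, flat, ee]
  backgrounds: [leafy, grey]
  starts: [1.2, 0.8]
  n_trials: 30
  pedestal_max: 0.2
  pedestal_step: 0.05
  step: 0.05
  min_step: 0.0125
  min_presentation_ms: 1000   # recorded metadata; no timing is simulated
  isi_ms: 2000
cohort:
  n_observers: 26
  threshold_means:
    uniform.leafy: 0.10
    flat.leafy: 0.12
    ee.leafy: 0.20
    uniform.grey: 0.09
    flat.grey: 0.10
    ee.grey: 0.15
  threshold_sd: 0.04
  slope_mean: 20
  slope_sd: 4
  lapse_mean: 0.02
  lapse_sd: 0.01
analysis:
  prior_scale: 0.7071068
  bootstrap_resamples: 2000
  baseline: 1.0
  one_sided_baseline: false
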