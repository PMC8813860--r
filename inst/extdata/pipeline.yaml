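# Default end-to-end run: simulate a shape population with a planted
# vorticity association, generate per-subject flow phantoms, preprocess,
# quantify ROI vorticity, build and score the shape atlas, and fit the
# morphometric mode. Unset fields fall back to package defaults.
seed: 1
n_subjects: 60
stages:
  simulate: true
  flow: true
  atlas: true
  associate: true
shape:
  points_per_surface: 120
  ring_size: 24
  mode_variances: [400.0, 144.0, 49.0, 25.0]
  noise_sd: 0.1
  pose_jitter_deg: 5
  pose_jitter_mm: 5
association_betas: [0.0, 0.0, 0.6, 0.0]
score_noise_sd: 0.5
flow:
  grid_shape: [24, 24, 24]
  spacing_mm: 2.4
  n_frames: 10
  frame_duration_ms: 38.8
  diastole_frames: [4, 5, 6, 7, 8, 9]
  venc_cms: 150
  noise_sd_cms: 3
  gamma0_cm2s: 100
  gamma_scale: 0.25
  core_radius_cm: 1.2
  support_radius_cm: 2.0
  envelope: smooth
  background_order: 1
  denoise: gaussian
  denoise_sd_voxels: 1
roi:
  radius_mm: 12
  region: RV_cavity
window:
  half_width: 2
atlas:
  variance_fraction: 0.9
alpha: 0.05
covariates: [sex, height, weight, age]
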