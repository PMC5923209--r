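# Demo pipeline configuration: one 64x64x16 noisy phantom, both analysis
# paths, tractography enabled. Run with:
#   cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
#                                           package = "cardiohelix"))
#   run_pipeline(cfg, "demo_out")
seed: 42
phantom:
  dim: [64, 64, 16]
  spacing: [125, 125, 125]
  r_endo: 900
  r_epi: 2500
  ha_endo: 60
  ha_epi: -60
  noise: rician
  noise_sigma: 0.02
  lesion: false
optical:
  factor: 3
  wavelength: 250
  window_sigma: 3
  shadow_amplitude: 0.05
  destripe_strength: 1
hat:
  n_rays: 20
  n_stations: 8
track:
  enabled: true
  subdivisions: 1
  max_streamlines: 100
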