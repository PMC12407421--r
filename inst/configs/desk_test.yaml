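# Desk-scale profile: small enough for an end-to-end run in minutes on one
# CPU, while keeping the cross-domain mechanism measurable.
forge:
  n_species: 4
  specimens_per_species: 6        # rendered ("scanned") individuals
  photo_specimens_per_species: 4  # photographed individuals, never shared
  seed: 42
viewsphere:
  yaw_step: 90
  ring_pitches: [0, 40, -40]
  include_poles: false
  distance: 3
  resolution: 32
  photo:
    background_marking_density: 1
    brightness_jitter_sd: 0.15
    color_cast_strength: 0.12
    blur_sigma: 0.8
    noise_sd: 0.04
    distance_jitter_sd: 0.05
    session_confound: false
datapipe:
  test_fraction: 0.2
  subset_fraction: 0.25
training:
  backbone: tiny
  lr: 0.001
  max_epochs: 12
  patience: 6
  batch_size: 32
  seed: 7
  lambda: 1
  regimes: [baseline, mmd, supplemented]
evaluation:
  tsne_seed: 1
  gradcam_n: 20
  gradcam_seed: 1
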