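# Full-scale digitisation protocol: 16 species, 30 scanned + 10 photographed
# individuals each, one corrupted scan dropped from species 16, the 92-pose
# view sphere at 720 px, VGG19-like backbone, 100 epochs with patience 15.
# Intended for multi-core hardware; use desk_test.yaml for quick runs.
forge:
  n_species: 16
  specimens_per_species: 30
  photo_specimens_per_species: 10
  drop: [[16, 1]]
  seed: 42
viewsphere:
  yaw_step: 20
  ring_pitches: [0, 30, -30, 60, -60]
  include_poles: true
  distance: 3
  resolution: 720
  photo:
    background_marking_density: 1
    brightness_jitter_sd: 0.15
    color_cast_strength: 0.12
    blur_sigma: 0.8
    noise_sd: 0.04
    distance_jitter_sd: 0.05
    session_confound: true
datapipe:
  test_fraction: 0.2
  subset_fraction: 0.25
  resize_side: 224
training:
  backbone: vgg19_like
  lr: 0.001
  max_epochs: 100
  patience: 15
  batch_size: 32
  seed: 7
  lambda: 1
  regimes: [baseline, photo_baseline, photo_subset, mmd, finetune, supplemented]
evaluation:
  tsne_seed: 1
  gradcam_n: 100
  gradcam_seed: 1
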