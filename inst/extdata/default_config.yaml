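# Default pipeline configuration: a Zhaodong-like synthetic landscape.
# Band order everywhere: blue, green, red, near-infrared (reflectance, 0-1).
seed: 1
scene:
  class_band_means:
    background:      [0.1000, 0.1200, 0.1500, 0.2800]
    nonlodged_maize: [0.0188, 0.0496, 0.0327, 0.4703]
    lodged_maize:    [0.0400, 0.0829, 0.0639, 0.5389]
  class_band_sds:
    background:      [0.01, 0.01, 0.01, 0.01]
    nonlodged_maize: [0.01, 0.01, 0.01, 0.01]
    lodged_maize:    [0.01, 0.01, 0.01, 0.01]
  lodged_fraction: 0.5456
  maize_fraction: 0.6
  patch_scale: 16
  cell_size: 16
  extent: [256, 256]
paired:
  block_ratio: 4
  coverage_fraction: 0.83
points:
  n: 140
  train_fraction: 0.7
survey:
  n_respondents: 18
  misreport_prob: 0.1
detection:
  threshold: 0.62
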