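seed: 1
segmentation:
  binarize:
    threshold: auto
  clean:
    open_radius: 2.0
    median_size: 3.0
  cht:
    radius_range:
    - 12.0
    - 30.0
    min_votes: 6.0
    glint_radius_range:
    - 2.0
    - 8.0
    glint_min_votes: 6.0
  glint:
    threshold_frac: 0.9
    min_intensity: 180.0
    open_radius: 1.0
  chanvese:
    mu: 0.05
    lambda_in: 1.0
    lambda_out: 1.0
    max_iter: 200.0
  mask:
    pupil_scale: 1.5
    glint_scale: 2.0
    glint_min_radius: 8.0
  roi:
    scale: 3.0
features:
  window: 10.0
  still_threshold: 5.0
  min_amplitude_frac: 0.05
  roi_half_width: 50.0
  roi_half_height: 50.0
fuzzy:
  mode: MIN
  method: COG
  threshold: 0.5
  membership: gap
session:
  fps: 30.0
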