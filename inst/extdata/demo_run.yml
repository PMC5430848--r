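# Example run configuration for the cocultrack CLI:
#   Rscript inst/cli/cocultrack.R run --config inst/extdata/demo_run.yml \
#           --out-dir demo_run
# A short synthetic recording with a strong rightward chemotactic bias.
layout:
  pixel_size: 4
simulate:
  n_dcs: 12
  n_cancer_per_chamber: 4
  n_frames: 90
  frame_interval: 2
  speed_mean: 5
  bias_strength: 0.9
  bias_side: right
  noise:
    background: 0.05
    gradient: 0.01
    shot_scale: 2000
detection:
  smooth_sigma: 1
  min_area: 20
  max_area: 4000
linking:
  gate_distance: 40
  min_track_length: 5
windows:
  windows:
    - [0, 3]
  min_frames_in_window: 5
seed: 11
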