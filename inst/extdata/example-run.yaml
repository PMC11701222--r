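# Example configuration for inst/cli/ipg.R
# All keys are optional; omitted keys take the package defaults shown here.
seed: 1
output_dir: ipg-output
backend: oracle
scene:
  H: 64
  W: 64
  C: 24
  K: 4
  region_model: blobs
  theta_min: 30
  noise_sd: 0.05
oracle:
  flip_rate: 0.15
  band_width: 3
  dilate: 0
sampling:
  per_class: 5
thresholds:
  tau_h: 0.8
  tau_l: 0.5
  kappa_h: 0.2
ipg:
  iterations: 50
  selections_per_class: 1
  min_votes: 1
  lr: 0.01
train:
  lr: 0.05
  momentum: 0.7
  weight_decay: 0.0001
  epochs: 100
  batch_size: 64
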