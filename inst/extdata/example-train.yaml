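# Example configuration for `echoseg train --config <file> --out <dir>`.
# Either point `data:` at a dataset directory written by `echoseg generate`
# (or remove it to train on phantoms generated on the fly via `synthetic:`).
mode: plax
size: 128
crop_size: 96
data: ~          # e.g. /path/to/dataset
synthetic:
  subjects: 10
  frames: 3
  seed: 1
model:
  anchor_seed: 7
  sparsity: 0.5
  seed: 1
train:
  batch_size: 1
  lr: 0.001
  epochs: 30
  coarse_epochs: 15
  loc_epochs: 15
  augment: no
  val_frac: 0.2
  seed: 1
  split: [0.2, 0.6, 0.2]
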