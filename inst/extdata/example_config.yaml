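# Example training configuration. Omitted fields keep the package defaults
# (model width 128, 2 encoder layers, 4 heads, 3 gate blocks, AdamW with
# learning rate 1e-3, betas (0.9, 0.999), eps 1e-8).
model:
  d_model: 32
  n_heads: 4
  n_layers: 1
  ffn_dim: 64
  n_gate_blocks: 1
  dilation_rates: 1
  max_len_drug: 16
  max_len_protein: 32
  scorer_widths: [64, 32]
training:
  learning_rate: 0.002
  batch_size: 32
  max_epochs: 80
  early_stopping_patience: 20
  vocab_drug: 40
  vocab_protein: 60
  seed: 7
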