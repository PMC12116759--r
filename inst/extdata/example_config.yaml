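# Example end-to-end run configuration.
# Unspecified keys fall back to the package defaults; one seed governs the
# whole run and per-model seeds are derived from it.
seed: 1
output_dir: runs/demo
sim:
  n_patients: 200
agent:
  hidden_layers: [48, 48]
  gradient_steps: 5000
  batch_size: 128
  quantile_embed_dim: 16
  n_ood_action_samples: 6
  n_actor_action_samples: 2
  n_cql_quantile_samples: 2
  cql_alpha: 0.5
  actor_lr: 0.001
  critic_lr: 0.001
ope:
  n_models: 3
  fqe_hidden: [64, 64]
  fqe_steps: 2000
  fqe_batch_size: 128
analysis:
  n_bootstrap: 1000
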