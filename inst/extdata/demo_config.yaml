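# Demonstration pipeline configuration: two simulated neutrophil groups
# observed over a 15-minute window at 1.5-minute frames, 50 cells each.
# True random motility coefficients: control mu = 18, tumor mu = 180
# um^2/min (mu = S^2 P / 2).
seed: 20240101
output_dir: demo_output
frame_interval: 1.5
msd:
  max_lag_fraction: 0.5
  pooling: pooled
fit:
  weighting: none
stats:
  alpha: 0.05
  m_rule: lags
groups:
  control:
    simulation:
      speed_S: 6.0
      persistence_P: 1.0
      n_cells: 50
      n_frames: 10
  tumor:
    simulation:
      speed_S: 12.0
      persistence_P: 2.5
      n_cells: 50
      n_frames: 10
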