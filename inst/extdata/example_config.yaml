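# Example bnctsim run configuration: 3D spheroid, high effective dose,
# zero radioresistance threshold, propagation constant 0.1 px^2/MCS.
geometry:
  mode: spheroid
  n_cells: 500
  f_dose: 0.15
field:
  D: 0.1
  mu: 0.01
damage:
  theta: 0.0
  eps_floor: 35.0
run:
  max_mcs: 1000
  plateau_window: 50
seed: 1
replicates: 10
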