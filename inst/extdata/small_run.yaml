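# Small desk-scale configuration: a 300 kb arm that exercises every stage in
# under a minute. The package defaults (sim_config()) define the full-size
# 5 Mb study; this file only shrinks the problem.
seed: 42
simulate:
  arm_length: 300000
  n_genes: 30
  n_gaps: 10
  n_markers: 6
anchor:
  n_qtls: 3
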