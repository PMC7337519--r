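# Demonstration pipeline configuration: a magnesium-like condition in
# which paired complexes can both unloop and be cleaved.
label: demo
n_beads: 30
corrupt_fraction: 0.0
seed: 17
simulation:
  k_loop: 0.3            # per min
  k_unloop: 0.25         # per min
  k_cut: 0.2             # per min
  rmsd_unlooped: 250.0   # nm
  rmsd_looped: 160.0     # nm
  noise_sd: 15.0         # nm per frame
  frame_interval: 1.0    # s
  baseline_duration: 10.0    # min, protein-free
  observation_duration: 60.0 # min
state_calling:
  min_dwell: 30.0        # s
  filter_sd: 8.0         # s
metrics:
  n_boot: 100000
  level: 0.95
kinetics:
  prior_a: 2.0
  prior_b: 1.0
  chains: 4
  warmup: 1000
  draws: 1000
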