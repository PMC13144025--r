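# Example cruspark configuration. Any subset of the model sections
# (ryr, ip3r, transport, buffers) overrides the packaged defaults
# (provenance of every default: cruspark::param_registry()).
# The trial/protocol sections are read by the command-line interface.

ryr:
  ej: 0.1            # allosteric coupling energy, dimensionless

transport:
  c_rest: 0.1        # resting cytosolic [Ca2+], uM

trial:
  duration: 200      # ms
  ip3: 0.1           # uM

protocol:
  n_trials: 100
  duration: 200
  n_ip3r: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
  ip3: [0.0, 0.1, 1.0, 10.0]
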