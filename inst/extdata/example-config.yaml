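# Example configuration for the dualrc command-line interface:
#   dualrc run example-config.yaml
#   dualrc sweep example-config.yaml --param sigma --values 0,0.25,1 --seeds 10
# `experiment` selects the figure-level recipe; all other fields override
# that recipe's defaults (see ?experiment_config).
experiment: fig1_single_chunk
n_neurons: 300
sigma: 0.3
n_steps: 10
seed: 1
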