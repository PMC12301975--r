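# End-to-end synthetic demo for runPipeline(); all inputs are simulated.
seed: 11
horizons: [100, 200, 300, 400]
n_boot: 200
n_perm: 200
method: crude
tissues: [liver, skin, spleen]
simulation:
  nGenes: 2000
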