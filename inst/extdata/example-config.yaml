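# Example run configuration: slow growth (mass-doubling time 150 min)
# with a custom rule override. Parameter names mirror the model's
# parameter table; omitted entries keep their defaults.
parameters:
  mdt: 150
  S0_CV: 0.05
seed: 7
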