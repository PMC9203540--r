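{
  "name": "spheroid",
  "model": "coxian",
  "growth": {
    "variant": "logistic",
    "lambda0": 0.12,
    "umax": 0.0066
  },
  "mortality": {
    "eta": 0.0035
  },
  "tcm": {
    "n": 5,
    "k1": 0.1682,
    "p": 0.9
  },
  "w0": 5e-4,
  "constant_concentration": 0,
  "seed": 1,
  "metadata": {
    "time_unit": "hours",
    "volume_unit": "mm3",
    "concentration_unit": "uM",
    "n_erlang": 4,
    "sampling_times": [0, 1, 2, 3, 6, 24, 48, 72],
    "concentrations": [0, 5, 10],
    "replicates": 30,
    "w0_note": "initial spheroid volume is a documented synthetic choice; the assay does not report it"
  }
}
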