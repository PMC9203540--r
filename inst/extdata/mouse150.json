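{
  "name": "mouse150",
  "model": "coxian",
  "growth": {
    "variant": "simeoni",
    "lambda0": 0.25,
    "lambda1": 0.4603,
    "phi": 20
  },
  "mortality": {
    "eta": 6.199935520671e-05
  },
  "tcm": {
    "n": 4,
    "k1": 0.2859,
    "p": 0.44268
  },
  "pk": {
    "k01": 1.6,
    "k21": 0.2353,
    "k12": 0.1699,
    "V": 1028
  },
  "schedule": {
    "times": [13, 14, 15, 16, 17, 18, 19, 20, 21, 22],
    "amounts": [4.5e7, 4.5e7, 4.5e7, 4.5e7, 4.5e7, 4.5e7, 4.5e7, 4.5e7, 4.5e7, 4.5e7],
    "route": ["bolus", "bolus", "bolus", "bolus", "bolus", "bolus", "bolus", "bolus", "bolus", "bolus"],
    "horizon": 60
  },
  "w0": 0.0121,
  "seed": 1,
  "metadata": {
    "time_unit": "days",
    "mass_unit": "g",
    "concentration_unit": "ng/ml",
    "eta_nominal": 0.7816,
    "eta_note": "kill potency expressed per ng/ml so that the critical infusion concentration lambda0/eta equals 4032.3 ng/ml on the plasma-concentration scale of the PK model; the nominal 0.7816 is quoted in unstated units",
    "infusion_threshold": 4032.3
  }
}
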