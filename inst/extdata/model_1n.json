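{
  "format": "hcn2kinetics/scheme",
  "version": 1,
  "name": "1n",
  "states": [
    {
      "name": "C0",
      "conducting": false
    },
    {
      "name": "C1",
      "conducting": false
    },
    {
      "name": "C2",
      "conducting": false
    },
    {
      "name": "O0",
      "conducting": true
    },
    {
      "name": "O1",
      "conducting": true
    },
    {
      "name": "O2",
      "conducting": true
    }
  ],
  "transitions": [
    {
      "from": "C0",
      "to": "C1",
      "kf": "k1",
      "kb": "k2",
      "z": "z1",
      "pf": 0.5,
      "kf_scale": 1,
      "kb_scale": 1
    },
    {
      "from": "C1",
      "to": "C2",
      "kf": "k3",
      "kb": "k4",
      "z": "z2",
      "pf": 0.5,
      "kf_scale": 1,
      "kb_scale": 1
    },
    {
      "from": "O0",
      "to": "O1",
      "kf": "k9",
      "kb": "k10",
      "z": "z1",
      "pf": 0.5,
      "kf_scale": 1,
      "kb_scale": 1
    },
    {
      "from": "O1",
      "to": "O2",
      "kf": "k11",
      "kb": "k12",
      "z": "z2",
      "pf": 0.5,
      "kf_scale": 1,
      "kb_scale": 1
    },
    {
      "from": "C0",
      "to": "O0",
      "kf": "k5",
      "kb": "k6",
      "z": null,
      "pf": 0.5,
      "kf_scale": 1,
      "kb_scale": 1
    },
    {
      "from": "C2",
      "to": "O2",
      "kf": "k7",
      "kb": "k8",
      "z": null,
      "pf": 0.5,
      "kf_scale": 1,
      "kb_scale": 1
    }
  ],
  "constraints": [
    {
      "kind": "posat",
      "opening": "k7",
      "closing": "k8",
      "posat": 0.71,
      "derived": "k8"
    },
    {
      "kind": "detailed_balance",
      "cycle": ["C0", "C1", "C2", "O2", "O1", "O0"],
      "derived": "k6"
    }
  ],
  "flags": {
    "st": false,
    "ze": false,
    "f": false
  },
  "params": {
    "values": {
      "k1": 0.16,
      "k2": 50.1,
      "z1": 0.79,
      "k3": 8.12e-08,
      "k4": 3320000,
      "z2": 7.31,
      "k5": 0.0177,
      "k7": 3.11,
      "k9": 0.0013,
      "k10": 23.5,
      "k11": 5.11e-05,
      "k12": 8930
    },
    "VT": 25.4,
    "e": 1.602e-19
  }
}
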