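{
  "format": "hcn2kinetics/scheme",
  "version": 1,
  "name": "mwc10",
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
      "name": "C3",
      "conducting": false
    },
    {
      "name": "C4",
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
    },
    {
      "name": "O3",
      "conducting": true
    },
    {
      "name": "O4",
      "conducting": true
    }
  ],
  "transitions": [
    {
      "from": "C0",
      "to": "C1",
      "kf": "a",
      "kb": "b",
      "z": "z",
      "pf": 0.5,
      "kf_scale": 4,
      "kb_scale": 1
    },
    {
      "from": "O0",
      "to": "O1",
      "kf": "a",
      "kb": "b",
      "z": "z",
      "pf": 0.5,
      "kf_scale": 5.65685424949238,
      "kb_scale": 0.707106781186547
    },
    {
      "from": "C1",
      "to": "C2",
      "kf": "a",
      "kb": "b",
      "z": "z",
      "pf": 0.5,
      "kf_scale": 3,
      "kb_scale": 2
    },
    {
      "from": "O1",
      "to": "O2",
      "kf": "a",
      "kb": "b",
      "z": "z",
      "pf": 0.5,
      "kf_scale": 4.24264068711929,
      "kb_scale": 1.41421356237309
    },
    {
      "from": "C2",
      "to": "C3",
      "kf": "a",
      "kb": "b",
      "z": "z",
      "pf": 0.5,
      "kf_scale": 2,
      "kb_scale": 3
    },
    {
      "from": "O2",
      "to": "O3",
      "kf": "a",
      "kb": "b",
      "z": "z",
      "pf": 0.5,
      "kf_scale": 2.82842712474619,
      "kb_scale": 2.12132034355964
    },
    {
      "from": "C3",
      "to": "C4",
      "kf": "a",
      "kb": "b",
      "z": "z",
      "pf": 0.5,
      "kf_scale": 1,
      "kb_scale": 4
    },
    {
      "from": "O3",
      "to": "O4",
      "kf": "a",
      "kb": "b",
      "z": "z",
      "pf": 0.5,
      "kf_scale": 1.4142135623731,
      "kb_scale": 2.82842712474619
    },
    {
      "from": "C0",
      "to": "O0",
      "kf": "ko",
      "kb": "kc",
      "z": null,
      "pf": 0.5,
      "kf_scale": 1,
      "kb_scale": 1
    },
    {
      "from": "C1",
      "to": "O1",
      "kf": "ko",
      "kb": "kc",
      "z": null,
      "pf": 0.5,
      "kf_scale": 1.4142135623731,
      "kb_scale": 0.707106781186548
    },
    {
      "from": "C2",
      "to": "O2",
      "kf": "ko",
      "kb": "kc",
      "z": null,
      "pf": 0.5,
      "kf_scale": 2,
      "kb_scale": 0.5
    },
    {
      "from": "C3",
      "to": "O3",
      "kf": "ko",
      "kb": "kc",
      "z": null,
      "pf": 0.5,
      "kf_scale": 2.82842712474619,
      "kb_scale": 0.353553390593274
    },
    {
      "from": "C4",
      "to": "O4",
      "kf": "ko",
      "kb": "kc",
      "z": null,
      "pf": 0.5,
      "kf_scale": 4,
      "kb_scale": 0.25
    }
  ],
  "constraints": [],
  "flags": {
    "st": true,
    "ze": true,
    "f": true
  },
  "params": {
    "values": {
      "a": 0.5,
      "b": 100,
      "z": 1.5,
      "ko": 1,
      "kc": 10
    },
    "VT": 25.4,
    "e": 1.602e-19
  }
}
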