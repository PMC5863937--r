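{
  "format": "hcn2kinetics/scheme",
  "version": 1,
  "name": "cd",
  "states": [
    {
      "name": "rr",
      "conducting": false
    },
    {
      "name": "ra",
      "conducting": false
    },
    {
      "name": "rf",
      "conducting": false
    },
    {
      "name": "aa",
      "conducting": false
    },
    {
      "name": "af",
      "conducting": false
    },
    {
      "name": "ff",
      "conducting": true
    }
  ],
  "transitions": [
    {
      "from": "rr",
      "to": "ra",
      "kf": "kra",
      "kb": "kar",
      "z": "zd",
      "pf": 0.5,
      "kf_scale": 2,
      "kb_scale": 1
    },
    {
      "from": "ra",
      "to": "aa",
      "kf": "kra",
      "kb": "kar",
      "z": "zd",
      "pf": 0.5,
      "kf_scale": 1,
      "kb_scale": 2
    },
    {
      "from": "rf",
      "to": "af",
      "kf": "kra",
      "kb": "kar",
      "z": "zd",
      "pf": 0.5,
      "kf_scale": 1,
      "kb_scale": 1
    },
    {
      "from": "ra",
      "to": "rf",
      "kf": "kaf",
      "kb": "kfa",
      "z": null,
      "pf": 0.5,
      "kf_scale": 1,
      "kb_scale": 1
    },
    {
      "from": "aa",
      "to": "af",
      "kf": "kaf",
      "kb": "kfa",
      "z": null,
      "pf": 0.5,
      "kf_scale": 2,
      "kb_scale": 1
    },
    {
      "from": "af",
      "to": "ff",
      "kf": "kaf",
      "kb": "kfa",
      "z": null,
      "pf": 0.5,
      "kf_scale": 1,
      "kb_scale": 2
    }
  ],
  "constraints": [],
  "flags": {
    "st": true,
    "ze": true,
    "f": false
  },
  "params": {
    "values": {
      "kra": 0.1,
      "kar": 50,
      "zd": 4,
      "kaf": 5,
      "kfa": 1
    },
    "VT": 25.4,
    "e": 1.602e-19
  }
}
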