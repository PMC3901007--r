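{
  "base_seed": 1234,
  "simulation": {
    "dt": 0.05,
    "duration": 1000,
    "integrator": "euler",
    "spike_threshold": 0
  },
  "parameters": [
    {
      "path": "we",
      "design": "step",
      "range": [0, 8],
      "count": 11
    },
    {
      "path": "wi",
      "design": "step",
      "range": [0, 67],
      "count": 11
    }
  ]
}
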