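{
  "name": "edelstein",
  "description": "Edelstein reaction scheme: autocatalytic species x1 with an enzyme cycle, conserved moiety x2+x3=30. Reduced system: dx1/dt = 8.5 x1 - x1^2 - x1 x2 - x2 + 30, dx2/dt = -x1 x2 + 60 - 2.2 x2.",
  "variables": ["x1", "x2", "x3"],
  "parameters": {"k1": "8.5", "k2": "1", "k3": "1", "k4": "1", "k5": "1", "k6": "0.2"},
  "odes": {
    "x1": "k1*x1 - k2*x1^2 - k3*x1*x2 + k4*x3",
    "x2": "k4*x3 + k5*x3 - k3*x1*x2 - k6*x2"
  },
  "constraints": [
    {"coeffs": {"x2": "1", "x3": "1"}, "total": "30", "victim": "x3"}
  ],
  "outputs": ["x1"],
  "order": ["x2", "x1"]
}
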