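{
  "name": "akt",
  "description": "Minimal dimensionless AKT/insulin signalling model: x1 = pAKT, x2 = pIRS, insulin input lambda. Bistable for lambda between about 0.38 and 0.65; at lambda = 0.4 the upper stable pAKT level is about 0.965.",
  "variables": ["x1", "x2"],
  "parameters": {"k1": "0.909", "k2": "0.909", "beta": "1", "delta": "1",
                 "E2": "1", "K1": "0.05", "K2": "0.05", "theta": "0.99",
                 "lambda": "0.4"},
  "odes": {
    "x1": "-beta*x1*x2/(K1 + x1) + (k2/k1)*E2*(1 - x1)/(K2 + (1 - x1))",
    "x2": "(delta/beta)*(k2/k1)*E2*lambda + theta*(1 - x1) - delta*x2"
  },
  "outputs": ["x1"],
  "order": ["x2", "x1"],
  "scan": {"parameter": "lambda", "lo": 0.3, "hi": 0.7}
}
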