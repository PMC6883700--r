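{
  "name": "example4",
  "description": "Three-species network with a factorizable Y-equation (Y extinction boundary) and constant inflow v; bistable at v=24 with states (Z,X,Y) = (2,4,18), (3,9,19), (4,16,18); switchable in Z and X, not in Y.",
  "variables": ["Z", "X", "Y"],
  "parameters": {"k1": "1", "k2": "1", "k3": "0.166", "k4": "1", "k5": "0.166",
                 "k6": "1.667", "k7": "2", "k8": "16", "k9": "16", "v": "24"},
  "snap": {"0.166": "1/6", "1.667": "5/3"},
  "odes": {
    "Z": "v - k1*Z^2 - k4*Y*Z - k7*Z^3 - k8*Z + k9*Z^2",
    "X": "k1*Z^2 - k2*X",
    "Y": "-k3*X*Y + k4*Y*Z - k5*Y^2 + k6*Y"
  },
  "outputs": ["Z", "X", "Y"],
  "order": ["X", "Y", "Z"],
  "scan": {"parameter": "v", "lo": 20, "hi": 28}
}
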