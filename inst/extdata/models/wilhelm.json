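{
  "name": "wilhelm",
  "description": "Smallest bistable mass-action network: S+Y->2X, 2X->X+Y, X+Y->Y+P, X->P with the constant S lumped into k1 and P an inert product. Steady states (0,0), (2,0.5) saddle, (6,4.5).",
  "variables": ["x", "y"],
  "fixed": ["P"],
  "parameters": {"k1": "8", "k2": "1", "k3": "1", "k4": "1.5"},
  "reactions": [
    {"reactants": {"y": 1}, "products": {"x": 2}, "k": "k1", "label": "S+Y->2X (S lumped)"},
    {"reactants": {"x": 2}, "products": {"x": 1, "y": 1}, "k": "k2", "label": "2X->X+Y"},
    {"reactants": {"x": 1, "y": 1}, "products": {"y": 1, "P": 1}, "k": "k3", "label": "X+Y->Y+P"},
    {"reactants": {"x": 1}, "products": {"P": 1}, "k": "k4", "label": "X->P"}
  ],
  "outputs": ["x", "y"],
  "order": ["y", "x"]
}
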