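{
  "name": "example3",
  "description": "Smallest bistable system with an unswitchable output: dZ/dt = -Z^3 + 6Z^2 - 11Z + 6, dY/dt = -Y - Z^2 + 4Z + 6. Y takes the value 9 at both stable states.",
  "variables": ["Z", "Y"],
  "parameters": {},
  "odes": {
    "Z": "-Z^3 + 6*Z^2 - 11*Z + 6",
    "Y": "-Y - Z^2 + 4*Z + 6"
  },
  "outputs": ["Y", "Z"],
  "order": ["Z", "Y"]
}
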