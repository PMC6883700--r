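{
  "name": "mapk",
  "description": "Dual phosphorylation/dephosphorylation cycle of MEK with distributive kinetics; dimensionless fractions x = MEK/MT, y = MEKpp/MT, z = MEKp/MT with 1 - x - y - z = 0. Competition for the shared kinase and phosphatase yields bistability.",
  "variables": ["x", "y", "z"],
  "parameters": {"a1": "0.0204", "a2": "0.0493", "a3": "0.0564", "a4": "0.0326",
                 "d1": "10.386", "d2": "2.716", "d3": "10.088", "d4": "0.813",
                 "k1": "7", "k2": "11.13", "k3": "3.57", "k4": "1.13",
                 "MT": "5128", "c": "0.6", "p": "1"},
  "derived": {"Ks1": "(d1 + k1)/(MT*a1)", "Ks2": "(d2 + k2)/(MT*a2)",
              "Ks3": "(d3 + k3)/(MT*a3)", "Ks4": "(d4 + k4)/(MT*a4)",
              "Vm1": "k1*c", "Vm2": "k2*p", "Vm3": "k3*c", "Vm4": "k4*p"},
  "odes": {
    "x": "Vm2*(z/Ks2)/(1 + y/Ks4 + z/Ks2) - Vm1*(x/Ks1)/(1 + x/Ks1 + z/Ks3)",
    "y": "Vm3*(z/Ks3)/(1 + x/Ks1 + z/Ks3) - Vm4*(y/Ks4)/(1 + y/Ks4 + z/Ks2)"
  },
  "constraints": [
    {"coeffs": {"x": "1", "y": "1", "z": "1"}, "total": "1", "victim": "z"}
  ],
  "outputs": ["y", "x", "z"],
  "order": ["x", "y"]
}
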