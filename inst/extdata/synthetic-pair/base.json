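{
  "label": "synthetic-base-11",
  "substituent": "synthetic",
  "role": "deprotonated",
  "charge": 0,
  "multiplicity": 2,
  "is_radical": true,
  "atoms": [
    {
      "element": "N",
      "mass": 14.007,
      "x": -0.922472494654357,
      "y": -1.2848599832505,
      "z": -1.96670069359243
    },
    {
      "element": "N",
      "mass": 14.007,
      "x": -1.32260750699788,
      "y": 0.566661462187767,
      "z": -0.429211211390793
    },
    {
      "element": "H",
      "mass": 1.008,
      "x": -1.86441751010716,
      "y": -1.90848902612925,
      "z": 1.25552223715931
    }
  ],
  "frequencies": [49.7236279745121, 1456.68020627927, 1074.23064615577],
  "electronic_energy": {
    "value": -4.95475605392037,
    "unit": "hartree"
  },
  "free_energy_gas": {
    "value": -4.96204769296244,
    "unit": "hartree"
  },
  "solvation_energies": {
    "P6": {
      "value": -0.0124227329760173,
      "unit": "hartree"
    }
  },
  "explicit_waters": 1,
  "water_motif": "HO",
  "symmetry_number": 1,
  "linearity": "auto"
}
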