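{
  "label": "synthetic-acid-11",
  "substituent": "synthetic",
  "role": "protonated",
  "charge": 1,
  "multiplicity": 2,
  "is_radical": true,
  "atoms": [
    {
      "element": "N",
      "mass": 14.007,
      "x": -1.94380836654454,
      "y": -1.65401643514633,
      "z": -1.50713519472629
    },
    {
      "element": "N",
      "mass": 14.007,
      "x": -1.74124089349061,
      "y": -0.840099963359535,
      "z": -1.29954830929637
    },
    {
      "element": "H",
      "mass": 1.008,
      "x": 1.81939690187573,
      "y": 1.52279669139534,
      "z": -0.236998912878335
    }
  ],
  "frequencies": [91.6674549125601, 3008.43816087581, 2622.15872604866],
  "electronic_energy": {
    "value": -5.41051422804594,
    "unit": "hartree"
  },
  "free_energy_gas": {
    "value": -5.41416705162744,
    "unit": "hartree"
  },
  "solvation_energies": {
    "P6": {
      "value": -0.00711876944079033,
      "unit": "hartree"
    }
  },
  "explicit_waters": 1,
  "water_motif": "HO",
  "symmetry_number": 1,
  "linearity": "auto"
}
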