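{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "qcpka species record",
  "description": "One chemical species' quantum-chemistry results and metadata. Energies are {value, unit} objects; accepted unit tags: hartree, kj/mol, kcal/mol, j/mol.",
  "type": "object",
  "required": ["label", "charge", "multiplicity"],
  "properties": {
    "label": { "type": "string" },
    "substituent": { "type": "string" },
    "role": { "enum": ["protonated", "deprotonated"] },
    "charge": { "type": "integer" },
    "multiplicity": { "type": "integer", "minimum": 1 },
    "is_radical": { "type": "boolean" },
    "atoms": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["element", "x", "y", "z"],
        "properties": {
          "element": { "type": "string" },
          "mass": { "type": "number", "exclusiveMinimum": 0 },
          "x": { "type": "number" },
          "y": { "type": "number" },
          "z": { "type": "number" }
        }
      }
    },
    "frequencies": {
      "type": "array",
      "items": { "type": "number" },
      "description": "Harmonic wavenumbers in cm^-1; negative values flag imaginary modes and are rejected unless explicitly dropped."
    },
    "electronic_energy": { "$ref": "#/$defs/energy" },
    "free_energy_gas": { "$ref": "#/$defs/energy" },
    "free_energy_sol": { "$ref": "#/$defs/energy" },
    "solvation_energies": {
      "type": "object",
      "additionalProperties": { "$ref": "#/$defs/energy" },
      "description": "Map from protocol label (P1..P6) to solvation free energy."
    },
    "explicit_waters": { "type": "integer", "minimum": 0 },
    "water_motif": { "type": "string" },
    "symmetry_number": { "type": "integer", "minimum": 1 },
    "linearity": { "enum": ["auto", "linear", "nonlinear"] }
  },
  "$defs": {
    "energy": {
      "type": "object",
      "required": ["value", "unit"],
      "properties": {
        "value": { "type": "number" },
        "unit": { "enum": ["hartree", "kj/mol", "kcal/mol", "j/mol"] }
      }
    }
  }
}
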