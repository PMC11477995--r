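[
  {
    "substituent": "H",
    "system": "radical_cation",
    "pka_calc": 6.75448444870782
  },
  {
    "substituent": "C4H9",
    "system": "radical_cation",
    "pka_calc": 8.21329718450808
  },
  {
    "substituent": "CF3",
    "system": "radical_cation",
    "pka_calc": 4.04172345145907
  },
  {
    "substituent": "CH3",
    "system": "radical_cation",
    "pka_calc": 7.8186733253521
  },
  {
    "substituent": "OCH3",
    "system": "radical_cation",
    "pka_calc": 10.1892445780158
  },
  {
    "substituent": "CN",
    "system": "radical_cation",
    "pka_calc": 3.53292434016332
  },
  {
    "substituent": "COCH3",
    "system": "radical_cation",
    "pka_calc": 6.76180282310601
  },
  {
    "substituent": "I",
    "system": "radical_cation",
    "pka_calc": 7.41245889497236
  },
  {
    "substituent": "NH2",
    "system": "radical_cation",
    "pka_calc": 11.977138522147
  },
  {
    "substituent": "SO3-",
    "system": "radical_cation",
    "pka_calc": 5.29793971216386
  }
]
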