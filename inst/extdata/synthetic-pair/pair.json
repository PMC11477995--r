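{
  "acid": "acid.json",
  "base": "base.json",
  "approach": "direct",
  "correction": "C0",
  "protocol": "P6",
  "water_motif_label": "HO-HO",
  "target_pka": 7.3
}
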