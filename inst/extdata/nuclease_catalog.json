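{
  "catalog_version": "1.0",
  "note": "Window positions are counted from the protospacer 5' end (PAM-proximal for Cas12a, PAM-distal for SpCas9), per common base-editor characterizations: Cas12a-CBE TTTV window ~8-14; SpCas9 BE window ~4-8 of a 20-nt spacer.",
  "editors": [
    {
      "name": "Cas12a-CBE",
      "motif": "TTTV",
      "motif_side": "5prime_of_protospacer",
      "spacer_length": 23,
      "window": [8, 14],
      "chemistry": "CBE"
    },
    {
      "name": "SpCas9-CBE",
      "motif": "NGG",
      "motif_side": "3prime_of_protospacer",
      "spacer_length": 20,
      "window": [4, 8],
      "chemistry": "CBE"
    },
    {
      "name": "SpCas9-ABE",
      "motif": "NGG",
      "motif_side": "3prime_of_protospacer",
      "spacer_length": 20,
      "window": [4, 8],
      "chemistry": "ABE"
    }
  ]
}
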