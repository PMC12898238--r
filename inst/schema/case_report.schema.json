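{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "splicecase CaseReport",
  "type": "object",
  "required": ["variant", "splice_consequence", "cpg", "methylation",
               "editing", "expression", "provenance"],
  "properties": {
    "variant": {
      "type": "object",
      "required": ["contig", "pos", "ref", "alt"],
      "properties": {
        "contig": {"type": "string"},
        "pos": {"type": "integer"},
        "ref": {"type": "string", "pattern": "^[ACGT]$"},
        "alt": {"type": "string", "pattern": "^[ACGT]$"}
      }
    },
    "splice_consequence": {"$ref": "#/$defs/block"},
    "cpg": {"$ref": "#/$defs/block"},
    "methylation": {"$ref": "#/$defs/block"},
    "editing": {"$ref": "#/$defs/block"},
    "expression": {"$ref": "#/$defs/block"},
    "provenance": {
      "type": "object",
      "required": ["tool", "version", "catalog_md5"],
      "properties": {
        "tool": {"type": "string"},
        "version": {"type": "string"},
        "catalog": {"type": "string"},
        "catalog_md5": {"type": "string"},
        "input_md5": {"type": "object"}
      }
    }
  },
  "$defs": {
    "block": {
      "type": "object",
      "description": "A computed stage result, or {skipped: true, reason} or {failed: true, stage, error}."
    }
  }
}
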