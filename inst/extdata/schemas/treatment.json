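{
  "type_name": "treatment",
  "schema_version": 1,
  "required": ["treatment_term_id"],
  "properties": {
    "treatment_term_id": {"kind": "text", "pattern": "CHEBI:[0-9]+",
      "description": "ChEBI term for the applied chemical or agent"},
    "treatment_term_name": {"kind": "text"},
    "amount": {"kind": "number"},
    "amount_units": {"kind": "text", "enum": ["nM", "uM", "mM", "mg/mL"]},
    "duration": {"kind": "number"},
    "duration_units": {"kind": "text", "enum": ["minute", "hour", "day"]},
    "status": {"kind": "text", "enum": ["in progress", "released", "replaced", "deleted"], "description": "lifecycle status"}
  }
}
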