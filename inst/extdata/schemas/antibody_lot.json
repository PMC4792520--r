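{
  "type_name": "antibody_lot",
  "schema_version": 1,
  "required": ["source", "product_id", "lot_id"],
  "properties": {
    "source": {"kind": "text", "description": "vendor or producing lab"},
    "product_id": {"kind": "text"},
    "lot_id": {"kind": "text",
      "description": "production lot; specificity varies lot to lot"},
    "targets": {"kind": "list"},
    "host_organism": {"kind": "text", "enum": ["rabbit", "mouse", "goat", "rat"]},
    "characterizations": {"kind": "list", "link_to": "document"},
    "status": {"kind": "text", "enum": ["in progress", "released", "replaced", "deleted"], "description": "lifecycle status"}
  }
}
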