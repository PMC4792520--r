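{
  "type_name": "donor",
  "schema_version": 1,
  "required": ["organism"],
  "properties": {
    "organism": {"kind": "text", "enum": ["human", "mouse"],
      "description": "species of the donor or strain"},
    "sex": {"kind": "text", "enum": ["male", "female", "unknown"]},
    "age": {"kind": "text"},
    "life_stage": {"kind": "text",
      "enum": ["embryonic", "child", "adult", "unknown"]},
    "strain_background": {"kind": "text"},
    "lab": {"kind": "link", "link_to": "lab"},
    "award": {"kind": "link", "link_to": "award"},
    "status": {"kind": "text", "enum": ["in progress", "released", "replaced", "deleted"], "description": "lifecycle status"}
  }
}
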