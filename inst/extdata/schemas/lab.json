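{
  "type_name": "lab",
  "schema_version": 1,
  "identifying_fields": ["name"],
  "required": ["name"],
  "properties": {
    "name": {"kind": "text", "description": "short lab identifier"},
    "title": {"kind": "text", "description": "display name of the lab"},
    "institute": {"kind": "text"},
    "status": {"kind": "text", "enum": ["in progress", "released", "replaced", "deleted"], "description": "lifecycle status"}
  }
}
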