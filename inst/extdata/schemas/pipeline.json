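{
  "type_name": "pipeline",
  "schema_version": 1,
  "required": ["title"],
  "properties": {
    "title": {"kind": "text"},
    "software": {"kind": "list", "link_to": "software"},
    "status": {"kind": "text", "enum": ["in progress", "released", "replaced", "deleted"], "description": "lifecycle status"}
  }
}
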