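{
  "type_name": "software",
  "schema_version": 1,
  "identifying_fields": ["name"],
  "required": ["name", "version"],
  "properties": {
    "name": {"kind": "text"},
    "version": {"kind": "text"},
    "md5sum": {"kind": "text", "pattern": "[0-9a-f]{32}",
      "description": "checksum of the downloaded software build"},
    "url": {"kind": "text"},
    "status": {"kind": "text", "enum": ["in progress", "released", "replaced", "deleted"], "description": "lifecycle status"}
  }
}
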