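{
  "type_name": "document",
  "schema_version": 1,
  "required": ["document_type"],
  "properties": {
    "document_type": {"kind": "text",
      "enum": ["growth protocol", "extraction protocol", "library protocol",
               "characterization", "analysis", "other"]},
    "description": {"kind": "text"},
    "urls": {"kind": "list"},
    "status": {"kind": "text", "enum": ["in progress", "released", "replaced", "deleted"], "description": "lifecycle status"}
  }
}
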