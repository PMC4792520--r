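{
  "type_name": "library",
  "schema_version": 1,
  "required": ["biosample", "nucleic_acid_term_name"],
  "properties": {
    "biosample": {"kind": "link", "link_to": "biosample"},
    "nucleic_acid_term_name": {"kind": "text",
      "enum": ["DNA", "RNA", "polyadenylated mRNA", "rRNA-depleted RNA", "miRNA"]},
    "spikeins_used": {"kind": "list",
      "description": "spike-in reference sets added for calibration"},
    "fragmentation_method": {"kind": "text"},
    "lysis_method": {"kind": "text"},
    "documents": {"kind": "list", "link_to": "document"},
    "status": {"kind": "text", "enum": ["in progress", "released", "replaced", "deleted"], "description": "lifecycle status"}
  }
}
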