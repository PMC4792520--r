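{
  "type_name": "biosample",
  "schema_version": 1,
  "required": ["biosample_term_name", "donor"],
  "properties": {
    "biosample_term_name": {"kind": "text",
      "description": "human-readable name of the biosample term"},
    "tissue_term_id": {"kind": "text", "pattern": "UBERON:[0-9]+",
      "description": "UBERON term when the biosample is a tissue"},
    "cell_term_id": {"kind": "text", "pattern": "CL:[0-9]+",
      "description": "CL term when the biosample is a primary cell type"},
    "cell_line_term_id": {"kind": "text", "pattern": "EFO:[0-9]+",
      "description": "EFO term when the biosample is an immortalized cell line"},
    "donor": {"kind": "link", "link_to": "donor"},
    "source": {"kind": "text"},
    "starting_amount": {"kind": "number"},
    "starting_amount_units": {"kind": "text", "enum": ["cells", "g", "mg"]},
    "date_obtained": {"kind": "text"},
    "documents": {"kind": "list", "link_to": "document"},
    "treatments": {"kind": "list", "link_to": "treatment"},
    "lab": {"kind": "link", "link_to": "lab"},
    "award": {"kind": "link", "link_to": "award"},
    "status": {"kind": "text", "enum": ["in progress", "released", "replaced", "deleted"], "description": "lifecycle status"}
  }
}
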