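{
  "type_name": "experiment",
  "schema_version": 1,
  "required": [
    "assay_term_id",
    "assay_term_name"
  ],
  "properties": {
    "assay_term_id": {
      "kind": "text",
      "pattern": "OBI:[0-9]+",
      "description": "OBI term coding the assay"
    },
    "assay_term_name": {
      "kind": "text"
    },
    "description": {
      "kind": "text"
    },
    "target": {
      "kind": "text"
    },
    "possible_controls": {
      "kind": "list",
      "link_to": "experiment",
      "description": "control experiments usable for analysis"
    },
    "control_type": {
      "kind": "text",
      "enum": [
        "input library",
        "wild type"
      ],
      "description": "set when this experiment is itself a control"
    },
    "documents": {
      "kind": "list",
      "link_to": "document"
    },
    "lab": {
      "kind": "link",
      "link_to": "lab"
    },
    "award": {
      "kind": "link",
      "link_to": "award"
    },
    "status": {
      "kind": "text",
      "enum": [
        "in progress",
        "released",
        "replaced",
        "deleted"
      ],
      "description": "lifecycle status"
    },
    "replicates": {
      "kind": "list",
      "link_to": "replicate",
      "description": "the experiment's replicates (materialized reverse links)"
    }
  },
  "contained_fields": [
    "replicates"
  ]
}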