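{
  "type_name": "file",
  "schema_version": 1,
  "identifying_fields": ["md5sum"],
  "required": ["dataset", "file_format", "output_type", "md5sum"],
  "properties": {
    "dataset": {"kind": "link", "link_to": "experiment"},
    "file_format": {"kind": "text",
      "enum": ["fastq", "bam", "bigWig", "bigBed", "bed", "tsv"]},
    "output_type": {"kind": "text",
      "description": "short description of the file contents"},
    "md5sum": {"kind": "text", "pattern": "[0-9a-f]{32}"},
    "derived_from": {"kind": "list", "link_to": "file",
      "description": "input files this file was computed from"},
    "replicate": {"kind": "link", "link_to": "replicate"},
    "run_type": {"kind": "text", "enum": ["single-ended", "paired-ended"]},
    "paired_with": {"kind": "link", "link_to": "file"},
    "pipeline": {"kind": "link", "link_to": "pipeline"},
    "file_size": {"kind": "integer"},
    "status": {"kind": "text", "enum": ["in progress", "released", "replaced", "deleted"], "description": "lifecycle status"}
  },
  "dependencies": {
    "run_type": {"trigger_values": ["paired-ended"],
                 "required_fields": ["paired_with"]},
    "paired_with": {"required_fields": ["run_type"]}
  }
}
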