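format-version: 1.2
ontology: cl/toy-slice

[Term]
id: CL:0000000
name: cell

[Term]
id: CL:0000066
name: epithelial cell
is_a: CL:0000000 ! cell

[Term]
id: CL:0000312
name: keratinocyte
is_a: CL:0000066 ! epithelial cell
relationship: part_of UBERON:0001003 ! skin epidermis
synonym: "malpighian cell" EXACT []

[Term]
id: CL:0000182
name: hepatocyte
is_a: CL:0000066 ! epithelial cell
relationship: part_of UBERON:0002107 ! liver

[Term]
id: CL:0000540
name: neuron
is_a: CL:0000000 ! cell
relationship: part_of UBERON:0000955 ! brain

[Term]
id: CL:0000057
name: fibroblast
is_a: CL:0000000 ! cell
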