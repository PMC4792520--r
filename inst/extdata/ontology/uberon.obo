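format-version: 1.2
ontology: uberon/toy-slice

[Term]
id: UBERON:0000061
name: anatomical structure

[Term]
id: UBERON:0000062
name: organ
is_a: UBERON:0000061 ! anatomical structure

[Term]
id: UBERON:0002107
name: liver
is_a: UBERON:0000062 ! organ
synonym: "hepar" EXACT []

[Term]
id: UBERON:0000955
name: brain
is_a: UBERON:0000062 ! organ
synonym: "encephalon" EXACT []

[Term]
id: UBERON:0002097
name: skin of body
is_a: UBERON:0000062 ! organ
synonym: "integument" RELATED []

[Term]
id: UBERON:0001003
name: skin epidermis
is_a: UBERON:0000061 ! anatomical structure
relationship: part_of UBERON:0002097 ! skin of body
synonym: "epidermis" EXACT []

[Term]
id: UBERON:0002048
name: lung
is_a: UBERON:0000062 ! organ

[Term]
id: UBERON:0000948
name: heart
is_a: UBERON:0000062 ! organ

[Term]
id: UBERON:0002113
name: kidney
is_a: UBERON:0000062 ! organ
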