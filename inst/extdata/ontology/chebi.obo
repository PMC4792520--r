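format-version: 1.2
ontology: chebi/toy-slice

[Term]
id: CHEBI:24431
name: chemical entity

[Term]
id: CHEBI:41774
name: tamoxifen
is_a: CHEBI:24431 ! chemical entity

[Term]
id: CHEBI:16240
name: hydrogen peroxide
is_a: CHEBI:24431 ! chemical entity

[Term]
id: CHEBI:28262
name: dimethyl sulfoxide
is_a: CHEBI:24431 ! chemical entity
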