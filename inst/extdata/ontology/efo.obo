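format-version: 1.2
ontology: efo/toy-slice

[Term]
id: EFO:0000001
name: experimental factor

[Term]
id: EFO:0000322
name: cell line
is_a: EFO:0000001 ! experimental factor

[Term]
id: EFO:0001187
name: HepG2
is_a: EFO:0000322 ! cell line
synonym: "Hep G2" EXACT []

[Term]
id: EFO:0002067
name: K562
is_a: EFO:0000322 ! cell line

[Term]
id: EFO:0002791
name: HeLa-S3
is_a: EFO:0000322 ! cell line
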