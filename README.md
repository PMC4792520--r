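# metaforge

Consortium-scale sequencing projects live or die by their metadata: the
biological sample an assay started from, the antibody lot and protocols
used, the raw and processed files produced and the software that produced
them. **metaforge** implements such a metadata standard as an R library
plus CLI — a typed, accessioned, linked metadata object store for
functional-genomics assays (ChIP-seq, RNA-seq, ...), aimed at data
coordination centres, data wranglers and anyone building a lab-scale LIMS
for sequencing assays.

The core pieces:

* **Accessions** — stable identifiers on the grammar
  `ENC(SR|BS|DO|AB|LB|FF)[0-9]{3}[A-Z]{3}` (10³ × 26³ = 17,576,000 per
  entity type), minted by seeded random selection without replacement,
  never re-issued, with file-supersession chains.
* **Schema registry** — per-type JSON schema documents with enumerated
  lists, anchored patterns and conditional dependencies (presence ⇒
  presence and value ⇒ presence: a `paired-ended` file must name its
  mate); validation reports every violation instead of stopping.
* **Object store** — the linked graph donor → biosample → library →
  replicate → experiment plus files with `derived_from` provenance;
  dangling links tolerated during loading, enforced at finalization;
  replicate pairs classify as technical / isogenic-biological /
  anisogenic-biological from the library–biosample–donor chain.
* **Audit engine** — declarative post-submission rules R1–R7 (ChIP-seq
  antibody + control, RNA-seq spike-ins, paired-end reciprocity,
  technical-replicate biosample sharing, file–replicate connectivity,
  replicate–library presence) keyed off ontology-coded assay terms.
* **Ontology service** — OBO-subset loader for UBERON / CL / EFO / OBI /
  ChEBI slices, ancestor closure over `is_a` + `part_of`, slim
  assignment.
* **Search** — inverted keyword index over embedded records with slim and
  synonym expansion (a query for `skin` finds keratinocyte assays whose
  stored text never mentions skin), plus facet counts.
* **Exporters** — ISA-TAB and GEO SOFT writers and a five-check MINSEQE
  compliance report.
* **Fixtures** — a deterministic synthetic-consortium generator, clean or
  with planted, ground-truthed audit violations.

## Worked example

Generate a small consortium with two planted violations, audit it, search
it, and walk a file's provenance:

```r
library(metaforge)

res <- generate_consortium(fixture_spec(seed = 7, violation_plan = c(R1 = 1, R4 = 1)))
res$store
#> <metadata_store> 317 records (finalized)
#>   antibody_lot: 4, award: 1, biosample: 12, document: 2, donor: 6,
#>   experiment: 23, file: 167, lab: 1, library: 48, pipeline: 2,
#>   replicate: 48, software: 2, treatment: 1

cat(render_report(run_audits(res$store), "text"))
#> == error (1) ==
#>   ENCFF318MOA  R4: file 'ENCFF318MOA' names mate 'ENCFF571TGM' but 'paired_with' is not reciprocated
#> == not-compliant (1) ==
#>   rep-ENCSR448NPP-1-1  R1: replicate 'rep-ENCSR448NPP-1-1' of ChIP-seq experiment 'ENCSR448NPP' has no 'antibody' link
```

The two flags are exactly the planted ground truth (`res$truth`): a
one-sided paired-end mate and a ChIP-seq replicate stripped of its
antibody link. Searching for an anatomical term the store never mentions
literally:

```r
idx <- build_index(res$store, facet_fields = "assay_term_name",
                   slim_config = default_slim_config())
keyword_search(idx, "skin")
#> [1] "ENCSR019ZFL" "ENCSR194WUJ" "ENCSR293NOD" "ENCSR434JZC" "ENCSR448NPP"
#> [6] "ENCSR662AKO" "ENCSR711ZVL" "ENCSR755DTV" "ENCSR954XAQ"
facet_counts(idx, keyword_search(idx, "skin"), "assay_term_name")
#> ChIP-seq  RNA-seq
#>        6        3
```

These nine experiments are the ones whose biosample is a keratinocyte:
keratinocyte is `part_of` the skin epidermis, `part_of` the skin of body,
which sits in the default slim set — ontology expansion, not text match.
Finally, provenance and minimum-information compliance:

```r
check_minseqe(res$store, "ENCSR019ZFL")
#> <minseqe_report> ENCSR019ZFL: compliant
#>   [x] assay_described
#>   [x] samples_described
#>   [x] protocols_present
#>   [x] raw_data_present
#>   [x] processed_data_present

provenance_chain(res$store, "ENCFF311KII")   # a pooled bigWig signal track
#> [1] "ENCFF199HWZ" "ENCFF364OZN" "ENCFF019MUS" "ENCFF117ZQP" "ENCFF597OKB"
#> [6] "ENCFF766ANQ"
```

The chain lists the track's ancestors nearest-first: the two bam inputs,
then the four fastq files the bams were aligned from.

The same operations are available from a shell via the wrapper in
`exec/`: `metaforge validate`, `audit`, `search`, `export`, `mint`,
`check-accession`, `fixtures`, `provenance`, `minseqe` (exit code 0 = no
findings, 1 = findings, 2 = usage error).

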