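---
title: "The metaforge metadata model: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The metaforge metadata model: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaforge)
```

## The problem

A data coordination effort for high-throughput sequencing assays has to
describe, for every dataset it distributes, the biological material the
assay started from, the reagents and protocols used, the raw and processed
files produced, and the software that produced them. metaforge implements
such a standard as a typed, accessioned, linked metadata object store. The
record types mirror how the work is actually done in the lab and on the
cluster: a **donor** (or model-organism strain) supplies **biosamples**;
nucleic acid extracted from a biosample becomes a **library**; one
performance of the assay on one library is a **replicate**; replicates are
grouped into an **experiment**; replicates produce raw **files** that
pipelines turn into processed files; **antibody lots** are tracked per
production lot because specificity varies between lots. Supporting types —
documents, treatments, labs, awards, pipelines, software — carry protocol
and provenance detail.

The emphasis throughout is on reuse: a single donor contributes many
biosamples (a liver and a brain can come from the same person), a single
biosample feeds many assays, and files reference the files they were
computed from. Records therefore hold plain-id links and the store enforces
the graph's consistency, rather than each record duplicating context.

## Accessions

Identifiers follow a fixed grammar: `ENC`, a two-letter entity code
(`SR` experiment, `BS` biosample, `DO` donor/strain, `AB` antibody lot,
`LB` library, `FF` file), three decimal digits and three uppercase letters
— eleven characters in all, giving $10^3 \times 26^3 = 17{,}576{,}000$
identifiers per entity type.

```{r}
accession_capacity("SR")
parse_accession("ENCBS046RNA")
```

Design choices here, where the standard itself is silent:

* **Minting is seeded pseudo-random selection without replacement**, not
  sequential. A sequential counter would leak submission order through the
  identifier text; random serials carry no information beyond identity.
  Rejection sampling against the issued set is cheap because the space is
  ~17.6 million per type and realistic registries are far from full.
* **Uppercase only, full A–Z alphabet.** The grammar says uppercase
  letters; we do not adopt an ambiguity-avoiding alphabet, and lowercase
  input is rejected rather than folded so identifiers remain byte-stable.
* **Accessions are never re-issued.** Deletion of a record is a status
  change, not removal, and the registry's issued sets only grow. The
  registry persists as an append-only plain-text ledger so stability
  survives restarts.
* When a file is replaced, the replacement gets a *new* accession and a
  supersession relation to the old one; chains are walkable and cycles and
  double-supersession are rejected.

## Schema documents and validation

Each record type is described by a JSON schema document. The dialect is a
deliberately small, fixed keyword set — `type_name`, `schema_version`,
`properties`, `required`, `dependencies`, `identifying_fields`,
`contained_fields`, and per property `kind`, `enum`, `pattern`, `link_to`,
`description`. Anything else is rejected loudly: for a metadata standard, a
constraint that is silently ignored is worse than a failure at load time.
Two dialect notes:

* `link_to` is valid on `link`, `document-ref` *and* `list` kinds; a list
  with `link_to` is a list of links (needed for `derived_from`,
  `possible_controls`, `documents`).
* `contained_fields` marks link fields that are structural parts of the
  record rather than independent neighbours (see *Embedding* below).

Validation of a record reports every problem instead of stopping at the
first: missing required fields, values outside an enumerated list, pattern
mismatches, primitive-type mismatches, dependency failures, unknown fields,
and (when a store is available) links that resolve to a record of the wrong
type. Enumerated lists keep free-text drift out of curated fields; patterns
are **anchored full matches**, because a partial match would let a
malformed identifier with a valid substring slip through. Unknown fields
are violations by default (curated strictness) with an explicit downgrade
to warnings for exploratory loading.

Dependencies support both conditional forms: *presence implies presence*
(a file that names a mate must state its run type) and *value implies
presence* — the canonical example being paired-end sequencing, where
`run_type = "paired-ended"` requires `paired_with`, so mates are never
separated at submission time. Validation is pure and order-independent:
permuting a record's fields yields an identical report.

The status lifecycle enumerated list is `{in progress, released, replaced,
deleted}`. This exact set is a package choice; the standard requires a
lifecycle but does not enumerate one.

## The store: integrity, replicates, provenance, embedding

Records are validated on insertion, but **dangling links are tolerated
while loading** — partial submission is a requirement (one biological
replicate may arrive before its sibling exists). `finalize_store()` is the
transition to a consistent, released graph: it completes one-sided
`paired_with` declarations (if *a* names *b*, *b* gains the back
reference), materializes each experiment's `replicates` reverse link from
the replicate records, enforces referential integrity and per-experiment
uniqueness of (biological, technical) replicate numbers, and verifies the
`derived_from` graph is acyclic. The audit engine still flags one-sided
pairs on stores examined *before* finalization — which is why the `audit`
subcommand deliberately loads without re-finalizing.

**Replicate classification** follows the library/biosample/donor chain:
two replicates are *technical* when their libraries come from the same
biosample; otherwise *isogenic-biological* when the biosamples share a
donor and *anisogenic-biological* when they do not. Only this library-level
definition of technical replicates is implemented; the predicate sits in
one function, which is the extension point for alternate definitions.

**Provenance** (`provenance_chain()`) returns all transitive
`derived_from` ancestors ordered nearest-first. Ordering is by
longest-path distance from the query file, which is a topological order on
a DAG (every edge increases the rank by at least one), with ties broken by
id so output is deterministic. Cycles are reported with the offending path
spelled out.

**Embedding** (`embed_object()`) expands link fields into nested copies of
their targets up to a depth, keeping bare ids beyond the depth and at any
cyclic back-reference. Fields named in `contained_fields` — an
experiment's `replicates` — embed *without* consuming depth, because an
experiment accession refers to its replicates as a group rather than to
independent neighbours. With that convention the default depth of 3
reaches the donor from an experiment (replicate → library → biosample →
donor) while keeping embedded documents bounded. Embedding is a pure
function of (store, id, depth), so a record reached by two paths embeds
identically.

## Audits

Schema validation is per record; audits are consistency checks over the
finalized graph, run after submission. Rules are data — id, record type,
severity, description, pure predicate — registered in a ruleset, so new
checks need no engine changes. Applicability keys off the experiment's
ontology-coded assay term (OBI CURIE), never free text. The built-ins:

| rule | applies to | severity | check |
|------|------------|----------|-------|
| R1 | replicate  | not-compliant | ChIP-seq replicate links an antibody lot |
| R2 | experiment | not-compliant | ChIP-seq experiment lists a control |
| R3 | library    | warning | RNA-seq library declares its spike-ins |
| R4 | file       | error | paired-ended file has a reciprocated mate |
| R5 | experiment | error | technical replicates share a biosample |
| R6 | file       | error | file connects to a replicate of its experiment |
| R7 | replicate  | error | replicate links a library |

Severity assignments are package choices. R1/R2 are *not-compliant*:
the data are usable but fall short of the standard. R3 is a *warning*
because spike-in-free quantification is legitimate in some designs. R4–R7
are *errors* because each one breaks a structural invariant other code
relies on.

Two semantic decisions deserve spelling out. Control experiments (marked
by `control_type`, e.g. an input library) are exempt from R1 and R2 —
their libraries are immunoprecipitation-free and requiring controls of
controls would recurse forever. R6 accepts a file as connected if *any*
`derived_from` ancestor links a replicate of the file's experiment: pooled
processed files (a signal track computed from both replicates' alignments)
legitimately have no single replicate but are fully attributable through
provenance. Which assays require controls is configurable; the default is
ChIP-seq only.

## Ontologies, slims and search

Controlled vocabulary fields are ontology terms: UBERON for tissues, CL
for primary cell types, EFO for immortalized cell lines, OBI for assay
names, ChEBI for treatments. The loader reads an OBO subset (`[Term]`
stanzas with `id`, `name`, `is_a`, `relationship: part_of`, `synonym`) and
verifies acyclicity and parent resolution across the whole bundle, since
cell types legitimately sit `part_of` anatomical structures in another
namespace. Toy slices (~30 terms over five namespaces) ship with the
package; the format handles larger files but no functionality depends on
ontology size. Synonyms are indexed for search but never accepted as term
identifiers in records.

Ancestor computation traverses both `is_a` and `part_of` edges by default
— that is precisely what lets an anatomical query group cell types located
in the relevant structure — and the edge labels are preserved so stricter
traversal can be configured. A *slim* is a small curated set of high-level
terms; a record annotated with a term is assigned the slims among the
term's ancestors. The shipped default slim set is organ-level anatomy plus
the cell-line root.

The search index is a token → postings inverted index over the
depth-embedded record text plus slim names and synonyms of annotated
terms. This is how a query for "skin" finds keratinocyte experiments whose
stored text nowhere contains that string: keratinocyte is `part_of` the
skin epidermis, `part_of` the skin of body, which is in the slim set.
Tokenization is lowercase, split on non-alphanumerics, no stemming (the
vocabulary is curated; stemming curated terms invites false merges);
accessions survive as single tokens. Multi-token queries intersect;
ranking is total match count with ties broken by id — deliberately simple,
because the required behaviour is a retrieval contract, not a relevance
contract. Facet counts are computed over the current result set, matching
faceted-browsing semantics.

## Exporters and MINSEQE

Experiments export to ISA-TAB (investigation / study / assay
tab-separated tables: one study row per distinct biosample, one assay row
per (replicate, raw file) pair) and to GEO SOFT (one `^SERIES` block per
experiment, one `^SAMPLE` per replicate). File names in exports are the
file's accession plus its format as the extension. Both exporters are pure
functions of the store, so re-export is byte-identical. The exporter
interface is a plain function per format, so further formats can be added
without touching the store.

The MINSEQE guideline is prose; this package operationalizes it as five
concrete checks — assay described (ontology-coded assay term present),
samples described (every replicate resolves to a biosample with a donor),
protocols present (at least one document on a library or biosample), raw
data present (≥ 1 fastq file), processed data present (≥ 1 non-fastq
file) — with compliance their conjunction. The mapping from guideline to
check is ours and is exactly what `check_minseqe()` reports, no more.

## The fixture generator

`generate_consortium()` emulates a small consortium's submission stream so
that every module is testable without downloading anything. The default
spec builds 6 donors (half human, half mouse) with 2 biosamples each drawn
from a fixed term pool (liver, brain, keratinocyte, hepatocyte, HepG2,
K562, lung, heart — so the one-donor-liver-and-brain and keratinocyte
patterns always exist), 10 ChIP-seq experiments with antibody lots and
shared input-control experiments, 10 RNA-seq experiments whose libraries
declare ERCC spike-ins, 2 biological replicates per experiment (the first
two ChIP-seq experiments carry an extra technical replicate, so technical
pairs exist), 2 raw fastqs per replicate (paired-end mates for ChIP-seq,
single-ended for RNA-seq), one bam per replicate derived from its fastqs,
and one pooled bigWig per experiment derived from the bams — roughly 320
records and a provenance graph three layers deep. These sizes are chosen
to be the smallest store in which every audit rule, search expansion and
export path has multiple live targets. All randomness flows from the
single seed and identifiers are minted through the accession registry, so
the same spec is byte-identical on regeneration.

`corrupt()` plants ground-truthed violations by minimal field edits. After
every candidate edit the store is re-audited and the edit is kept only if
it induces exactly the planned flag and nothing else; infeasible plans
error. One case is worth noting: a one-sided `paired_with` plant (R4)
removes the mate link *and* flips the victim's `run_type` to single-ended,
because simply deleting one side would flag both mates and break the
flags-equal-truth contract.

What the generator does **not** emulate: realistic sequence content or
file sizes, quality-metric distributions, organisms beyond human and
mouse, free-text noise, or the long-tailed schema drift of a real
submission stream. Green tests on these fixtures demonstrate the engine's
contracts — validation, integrity, audit recall/precision, search
expansion, export structure — not robustness to arbitrarily messy
real-world submissions.

## Numerical and degenerate-input choices

* Minting uses rejection sampling; exhaustion is detected by comparing the
  issued count against the grammar's capacity, and reduced grammars (one
  digit, one letter: 260 serials) make exhaustion testable.
* `provenance_chain` on a raw file returns an empty vector, not an error;
  unknown ids always error with a classed condition.
* Empty experiment lists export header-only ISA-TAB tables; an experiment
  with replicates but no files exports SOFT with empty
  supplementary-file lines and a warning; an experiment with no replicates
  is an export error naming it.
* Empty queries return no results; facet counts over an empty result set
  are an empty mapping; facets over a field absent from all results are
  empty rather than an error (the unknown-field error fires at
  registration time, when the field names no schema property).
* All report orderings (validation violations, audit flags, provenance
  ties, serialized stores) are explicitly sorted so every artifact is
  byte-deterministic.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run entirely on generated
fixtures: consortium stores of ~23 experiments / ~320 records, random
provenance DAGs of 50 nodes (3 replicates), ontology closures checked on
random DAGs up to 40 terms, and exhaustive enumeration for the dependency
semantics (all presence patterns over 4 fields) and reduced accession
grammars (260 serials). These sizes are the package's own choice: small
enough to enumerate against brute-force oracles, large enough that every
rule and path has multiple live targets.

## Known limitations

* Schema migration machinery is absent; `schema_version` is stored so a
  future migration layer has something to key on.
* Technical-replicate classification implements only the library-level
  definition.
* The store is single-writer; there are no transactions and no relational
  backend.
* Quality metrics (read depth, concordance) are stored as plain fields and
  are not audited numerically — the standard names them as captured
  metadata but supplies no thresholds.
* Whether serial blocks are reserved per lab or epoch is unspecified
  upstream; the accession space is treated as flat.
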