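Package: metaforge
Title: Typed, Accessioned, Linked Metadata Store for Sequencing Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a consortium-grade metadata standard for functional
    genomics assays as a reusable library and command-line tool: per-type
    JSON schema documents with enumerated lists and conditional dependencies,
    a stable accession grammar with minting and file-supersession tracking,
    a linked object store (donors, biosamples, libraries, antibody lots,
    replicates, experiments, files, pipelines) with referential-integrity
    checks, replicate classification and file-provenance chains, a
    declarative post-submission audit engine, ontology-backed controlled
    vocabularies with slim-based search expansion, keyword and faceted
    search, and ISA-TAB / GEO SOFT exporters with a MINSEQE compliance
    check. A deterministic fixture generator emulates a small consortium
    submission stream, clean or with planted, ground-truthed violations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
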