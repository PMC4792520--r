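test_that("records add, resolve, and duplicates are rejected", {
  reg <- load_schema_dir()
  store <- metadata_store(reg)
  store <- add_object(store, metadata_object("donor", "don1",
    list(organism = "human")))
  store <- add_object(store, metadata_object("biosample", "bio-liver",
    list(biosample_term_name = "liver", tissue_term_id = "UBERON:0002107",
         donor = "don1")))
  store <- add_object(store, metadata_object("biosample", "bio-brain",
    list(biosample_term_name = "brain", tissue_term_id = "UBERON:0000955",
         donor = "don1")))
  # both biosamples resolve to the same donor record
  expect_identical(get_object(store, prop(get_object(store, "bio-liver"), "donor"))$id,
                   get_object(store, prop(get_object(store, "bio-brain"), "donor"))$id)
  expect_error(add_object(store, metadata_object("donor", "don1",
    list(organism = "mouse"))), class = "metaforge_duplicate_id")
  # identifying-field uniqueness (software name)
  store <- add_object(store, metadata_object("software", "sw1",
    list(name = "aligner", version = "1.0")))
  expect_error(add_object(store, metadata_object("software", "sw2",
    list(name = "aligner", version = "2.0"))),
    class = "metaforge_duplicate_identifier")
  # an invalid record never enters the store
  expect_error(add_object(store, metadata_object("donor", "don2",
    list(organism = "yeast"))), class = "metaforge_invalid_record")
})

test_that("dangling links are tolerated on load and rejected at finalize", {
  reg <- load_schema_dir()
  store <- metadata_store(reg)
  store <- add_object(store, metadata_object("biosample", "bio1",
    list(biosample_term_name = "liver", donor = "don-missing")))
  findings <- check_referential_integrity(store)
  expect_identical(findings$problem, "dangling-link")
  expect_error(finalize_store(store), class = "metaforge_integrity_error")
  store <- add_object(store, metadata_object("donor", "don-missing",
    list(organism = "human")))
  store <- finalize_store(store)
  expect_true(store$finalized)
  # deleting a referenced donor re-opens the dangling link
  store2 <- delete_object(store, "don-missing")
  expect_identical(check_referential_integrity(store2)$problem, "dangling-link")
})

test_that("mistyped links are reported with the offending field", {
  reg <- load_schema_dir()
  store <- metadata_store(reg)
  store <- add_object(store, metadata_object("donor", "don1",
    list(organism = "human")))
  store <- add_object(store, metadata_object("biosample", "bio1",
    list(biosample_term_name = "liver", donor = "don1")))
  store <- add_object(store, metadata_object("experiment", "exp1",
    list(assay_term_id = "OBI:0000716", assay_term_name = "ChIP-seq")))
  # library whose biosample link points at an experiment
  store <- add_object(store, metadata_object("library", "lib1",
    list(biosample = "exp1", nucleic_acid_term_name = "DNA")))
  findings <- check_referential_integrity(store)
  expect_equal(nrow(findings), 1L)
  expect_identical(findings$problem, "mistyped-link")
  expect_identical(findings$record_id, "lib1")
  expect_identical(findings$field, "biosample")
})

test_that("replicate pairs classify as technical / isogenic / anisogenic", {
  # two libraries from the same biosample
  tech <- mini_experiment_store(n_donors = 1, biosample_of_rep = c(1, 1),
                                donor_of_biosample = 1)
  expect_identical(classify_replicates(tech, "exp1")$class, "technical")
  # distinct biosamples from the same donor
  iso <- mini_experiment_store(n_donors = 1, biosample_of_rep = c(1, 2),
                               donor_of_biosample = c(1, 1))
  expect_identical(classify_replicates(iso, "exp1")$class,
                   "isogenic-biological")
  # distinct biosamples from different donors
  aniso <- mini_experiment_store(n_donors = 2, biosample_of_rep = c(1, 2),
                                 donor_of_biosample = c(1, 2))
  expect_identical(classify_replicates(aniso, "exp1")$class,
                   "anisogenic-biological")
  # symmetric and order-invariant: classification names the sorted pair
  pairs <- classify_replicates(aniso, "exp1")
  expect_true(all(pairs$replicate_a < pairs$replicate_b))
  # broken chain raises
  broken <- aniso
  lib <- broken$objects$lib1
  lib$properties$biosample <- NULL
  broken$objects$lib1 <- lib
  expect_error(classify_replicates(broken, "exp1"),
               class = "metaforge_unresolvable_chain")
})

test_that("provenance chains are topological, nearest first", {
  edges <- data.frame(from = c("bw", "bam"), to = c("bam", "fq"),
                      stringsAsFactors = FALSE)
  store <- dag_store(edges, c("bw", "bam", "fq"))
  expect_identical(provenance_chain(store, "bw"), c("bam", "fq"))
  expect_identical(provenance_chain(store, "fq"), character(0))
  # diamond with a shortcut: the far node must still come after the near ones
  edges2 <- data.frame(from = c("d", "d", "d", "b", "c", "b"),
                       to = c("b", "c", "a", "a", "a", "c"),
                       stringsAsFactors = FALSE)
  store2 <- dag_store(edges2, c("a", "b", "c", "d"))
  chain <- provenance_chain(store2, "d")
  expect_setequal(chain, c("a", "b", "c"))
  expect_true(match("a", chain) > match("b", chain))  # b derives from a
  expect_true(match("c", chain) > match("b", chain))  # b derives from c
})

test_that("provenance cycles are detected and named", {
  store <- metadata_store(toy_registry())
  store <- add_object(store, metadata_object("file", "a",
    list(derived_from = list("b"))))
  store <- add_object(store, metadata_object("file", "b",
    list(derived_from = list("a"))))
  err <- expect_error(provenance_chain(store, "a"),
                      class = "metaforge_provenance_cycle")
  expect_match(conditionMessage(err), "a -> b -> a")
  expect_error(finalize_store(store), class = "metaforge_provenance_cycle")
})

test_that("ancestor sets on random DAGs equal brute-force transitive closure", {
  set.seed(303)
  for (trial in 1:5) {
    n <- 50L
    nodes <- sprintf("f%02d", seq_len(n))
    edges <- random_dag(n, p = 0.08, labels = nodes)
    store <- dag_store(edges, nodes)
    oracle <- brute_closure(edges, nodes)
    for (node in sample(nodes, 10)) {
      expect_setequal(provenance_chain(store, node), oracle[[node]])
    }
  }
})

test_that("embedding expands links to depth, purely and cycle-safely", {
  res <- generate_consortium(fixture_spec(seed = 3, n_chipseq = 2,
                                          n_rnaseq = 1))
  store <- res$store
  exp_id <- sort(names(Filter(function(o) o$type_name == "experiment",
                              store$objects)))[2]
  # depth 0: identity (links stay ids)
  flat <- embed_object(store, exp_id, 0)
  expect_identical(flat[names(flat) != "id" & names(flat) != "type_name"],
                   get_object(store, exp_id)$properties)
  # depth 3: donor fields reachable inline through replicate/library/biosample
  deep <- embed_object(store, exp_id, 3)
  donor <- deep$replicates[[1]]$library$biosample$donor
  expect_true(is.list(donor))
  expect_true(donor$organism %in% c("human", "mouse"))
  # purity: identical on repeated evaluation
  expect_identical(deep, embed_object(store, exp_id, 3))
  # mutually linked records terminate at any depth
  reg <- toy_registry()
  cyc <- metadata_store(reg)
  cyc <- add_object(cyc, metadata_object("file", "a",
    list(derived_from = list("b"))))
  cyc <- add_object(cyc, metadata_object("file", "b",
    list(derived_from = list("a"))))
  doc <- embed_object(cyc, "a", 10)
  expect_identical(doc$derived_from[[1]]$derived_from[[1]], "a")
})

test_that("store serialization round-trips in both dialects, byte-stably", {
  res <- generate_consortium(fixture_spec(seed = 5, n_donors = 2,
                                          n_chipseq = 2, n_rnaseq = 1))
  store <- res$store
  single <- withr::local_tempfile(fileext = ".json")
  write_store(store, single)
  again <- withr::local_tempfile(fileext = ".json")
  write_store(read_store(single, finalize = TRUE), again)
  expect_identical(readLines(single), readLines(again))
  dirpath <- withr::local_tempdir()
  write_store(store, dirpath, dialect = "dir")
  back <- read_store(dirpath, finalize = TRUE)
  expect_setequal(names(back$objects), names(store$objects))
})
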