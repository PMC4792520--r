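# brute-force row-count oracles over a store: (replicate, raw file) pairs
# and distinct biosamples for a set of experiments
brute_assay_rows <- function(store, exp_ids) {
  n <- 0L
  for (e in exp_ids) {
    reps <- Filter(function(o) o$type_name == "replicate" &&
                     identical(prop(o, "experiment"), e), store$objects)
    for (r in reps) {
      n <- n + sum(vapply(store$objects, function(o)
        o$type_name == "file" && identical(prop(o, "replicate"), r$id) &&
          identical(prop(o, "file_format"), "fastq"), logical(1)))
    }
  }
  n
}

brute_study_rows <- function(store, exp_ids) {
  bios <- character(0)
  for (e in exp_ids) {
    reps <- Filter(function(o) o$type_name == "replicate" &&
                     identical(prop(o, "experiment"), e), store$objects)
    for (r in reps) {
      lib <- store$objects[[prop(r, "library")]]
      bios <- c(bios, prop(lib, "biosample"))
    }
  }
  length(unique(bios))
}

test_that("ISA-TAB row counts match brute-force counts on random fixtures", {
  for (seed in c(41, 43)) {
    res <- generate_consortium(fixture_spec(seed = seed))
    store <- res$store
    exps <- sort(names(Filter(function(o) o$type_name == "experiment",
                              store$objects)))
    chosen <- exps[seq(1, length(exps), by = 2)]
    isa <- export_isatab(store, chosen)
    expect_equal(nrow(isa$assay), brute_assay_rows(store, chosen))
    expect_equal(nrow(isa$study), brute_study_rows(store, chosen))
    # file names are accession.format
    expect_true(all(grepl("^ENCFF[0-9]{3}[A-Z]{3}\\.fastq$",
                          isa$assay$`Raw Data File`)))
  }
})

test_that("a biosample shared by two experiments yields one study row", {
  reg <- load_schema_dir()
  store <- metadata_store(reg)
  store <- add_object(store, metadata_object("donor", "don1",
    list(organism = "human")))
  store <- add_object(store, metadata_object("biosample", "bio-liver",
    list(biosample_term_name = "liver", donor = "don1")))
  for (e in c("expA", "expB")) {
    store <- add_object(store, metadata_object("experiment", e,
      list(assay_term_id = "OBI:0001271", assay_term_name = "RNA-seq")))
    store <- add_object(store, metadata_object("library", paste0("lib-", e),
      list(biosample = "bio-liver", nucleic_acid_term_name = "RNA",
           spikeins_used = list("ERCC"))))
    store <- add_object(store, metadata_object("replicate", paste0("rep-", e),
      list(experiment = e, library = paste0("lib-", e),
           biological_replicate_number = 1L,
           technical_replicate_number = 1L)))
  }
  store <- finalize_store(store)
  isa <- export_isatab(store, c("expA", "expB"))
  expect_equal(nrow(isa$study), 1L)
  expect_identical(isa$study$`Sample Name`, "bio-liver")
  # empty experiment list: header-only tables
  empty <- export_isatab(store, character(0))
  expect_equal(nrow(empty$study), 0L)
  expect_equal(nrow(empty$assay), 0L)
  expect_gt(length(names(empty$assay)), 0L)
  # an experiment with no replicates cannot be exported
  store2 <- add_object(store, metadata_object("experiment", "expC",
    list(assay_term_id = "OBI:0001271", assay_term_name = "RNA-seq")))
  err <- expect_error(export_isatab(store2, "expC"),
                      class = "metaforge_export_error")
  expect_match(conditionMessage(err), "expC")
})

test_that("exports are pure: re-export is byte-identical", {
  res <- generate_consortium(fixture_spec(seed = 47, n_chipseq = 3,
                                          n_rnaseq = 2))
  store <- res$store
  exps <- sort(names(Filter(function(o) o$type_name == "experiment",
                            store$objects)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_isatab(export_isatab(store, exps), d1)
  write_isatab(export_isatab(store, exps), d2)
  for (f in c("i_investigation.txt", "s_study.txt", "a_assay.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  soft1 <- export_geo_soft(store, exps[1])
  soft2 <- export_geo_soft(store, exps[1])
  expect_identical(soft1, soft2)
})

test_that("SOFT output has one SERIES and one SAMPLE block per replicate", {
  res <- generate_consortium(fixture_spec(seed = 53, n_chipseq = 1,
                                          n_rnaseq = 0))
  store <- res$store
  # a non-control ChIP-seq experiment with 2 biological replicates
  exps <- names(Filter(function(o) o$type_name == "experiment" &&
                         !has_prop(o, "control_type"), store$objects))
  soft <- export_geo_soft(store, exps[1])
  lines <- strsplit(soft, "\n")[[1]]
  expect_equal(sum(grepl("^\\^SERIES", lines)), 1L)
  n_reps <- length(Filter(function(o) o$type_name == "replicate" &&
                            identical(prop(o, "experiment"), exps[1]),
                          store$objects))
  expect_equal(sum(grepl("^\\^SAMPLE", lines)), n_reps)
  expect_true(any(grepl("^!Sample_supplementary_file = ENCFF", lines)))
  # an experiment with replicates but no files warns and emits empty lines
  bare <- metadata_store(load_schema_dir())
  bare <- add_object(bare, metadata_object("donor", "d",
    list(organism = "human")))
  bare <- add_object(bare, metadata_object("biosample", "b",
    list(biosample_term_name = "liver", donor = "d")))
  bare <- add_object(bare, metadata_object("experiment", "e",
    list(assay_term_id = "OBI:0001271", assay_term_name = "RNA-seq")))
  bare <- add_object(bare, metadata_object("library", "l",
    list(biosample = "b", nucleic_acid_term_name = "RNA")))
  bare <- add_object(bare, metadata_object("replicate", "r",
    list(experiment = "e", biological_replicate_number = 1L,
         technical_replicate_number = 1L, library = "l")))
  bare <- finalize_store(bare)
  expect_warning(soft_bare <- export_geo_soft(bare, "e"), "no raw files")
  expect_true(any(grepl("^!Sample_supplementary_file =$",
                        strsplit(soft_bare, "\n")[[1]])))
})

test_that("MINSEQE verdicts flip exactly with the deleted element", {
  res <- generate_consortium(fixture_spec(seed = 59, n_chipseq = 1,
                                          n_rnaseq = 1))
  store <- res$store
  exps <- names(Filter(function(o) o$type_name == "experiment" &&
                         !has_prop(o, "control_type"), store$objects))
  for (e in exps) {
    expect_true(check_minseqe(store, e)$compliant)
  }
  target <- sort(exps)[1]
  # remove raw fastq files -> only the raw-data check fails
  no_raw <- store
  for (id in names(no_raw$objects)) {
    o <- no_raw$objects[[id]]
    if (o$type_name == "file" && identical(prop(o, "dataset"), target) &&
        identical(prop(o, "file_format"), "fastq")) {
      o$properties$status <- "deleted"
      o$properties$dataset <- NULL
      no_raw$objects[[id]] <- o
    }
  }
  rep_raw <- check_minseqe(no_raw, target)
  expect_false(rep_raw$compliant)
  expect_false(rep_raw$checks[["raw_data_present"]])
  expect_true(rep_raw$checks[["processed_data_present"]])
  expect_true(rep_raw$checks[["protocols_present"]])
  # strip protocol documents -> only the protocols check fails
  no_doc <- store
  for (id in names(no_doc$objects)) {
    o <- no_doc$objects[[id]]
    if (o$type_name %in% c("library", "biosample")) {
      o$properties$documents <- NULL
      no_doc$objects[[id]] <- o
    }
  }
  rep_doc <- check_minseqe(no_doc, target)
  expect_false(rep_doc$compliant)
  expect_false(rep_doc$checks[["protocols_present"]])
  expect_true(rep_doc$checks[["raw_data_present"]])
  # break the biosample chain -> only the samples check fails
  no_bio <- store
  reps <- Filter(function(o) o$type_name == "replicate" &&
                   identical(prop(o, "experiment"), target), no_bio$objects)
  lib <- no_bio$objects[[prop(reps[[1]], "library")]]
  lib$properties$biosample <- NULL
  no_bio$objects[[lib$id]] <- lib
  rep_bio <- check_minseqe(no_bio, target)
  expect_false(rep_bio$compliant)
  expect_false(rep_bio$checks[["samples_described"]])
  expect_true(rep_bio$checks[["assay_described"]])
  expect_error(check_minseqe(store, "ENCSR000XXX"),
               class = "metaforge_unknown_id")
})
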