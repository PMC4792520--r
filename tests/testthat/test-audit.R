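# each rule exercised on a small store built around the planted defect,
# then the full ruleset on generated consortium fixtures

test_that("ChIP-seq replicates without antibodies and experiments without controls flag", {
  store <- mini_experiment_store(assay = "ChIP-seq")
  flags <- run_audits(store)
  expect_setequal(flags$rule_id, c("R1", "R2"))
  expect_identical(sort(flags$record_id[flags$rule_id == "R1"]),
                   c("rep1", "rep2"))
  expect_identical(flags$record_id[flags$rule_id == "R2"], "exp1")
  expect_true(all(flags$severity[flags$rule_id %in% c("R1", "R2")] ==
                    "not-compliant"))
  # an input-control experiment is exempt from both rules
  ctrl <- store
  exp <- ctrl$objects$exp1
  exp$properties$control_type <- "input library"
  ctrl$objects$exp1 <- exp
  expect_equal(nrow(run_audits(ctrl)), 0L)
  # an RNA-seq experiment is not in scope for either rule
  rna <- mini_experiment_store(assay = "RNA-seq")
  expect_false(any(run_audits(rna)$rule_id %in% c("R1", "R2")))
})

test_that("RNA-seq libraries without spike-ins draw a warning-level flag", {
  store <- mini_experiment_store(assay = "RNA-seq")
  flags <- run_audits(store, rules = "R3")
  expect_identical(sort(flags$record_id), c("lib1", "lib2"))
  expect_true(all(flags$severity == "warning"))
  fixed <- store
  for (lib in c("lib1", "lib2")) {
    obj <- fixed$objects[[lib]]
    obj$properties$spikeins_used <- list("ERCC-Mix1")
    fixed$objects[[lib]] <- obj
  }
  expect_equal(nrow(run_audits(fixed, rules = "R3")), 0L)
  # ChIP-seq libraries are exempt
  chip <- mini_experiment_store(assay = "ChIP-seq")
  expect_equal(nrow(run_audits(chip, rules = "R3")), 0L)
})

test_that("paired-end files flag when the mate link is missing or one-sided", {
  reg <- load_schema_dir()
  mk_file <- function(store, id, props) {
    add_object(store, metadata_object("file", id, c(
      list(dataset = "exp1", file_format = "fastq", output_type = "reads",
           md5sum = random_hex(id)), props)))
  }
  random_hex <- function(s) substr(paste(rep(sprintf("%08x", sum(utf8ToInt(s))), 4),
                                         collapse = ""), 1, 32)
  base <- metadata_store(reg)
  base <- add_object(base, metadata_object("experiment", "exp1",
    list(assay_term_id = "OBI:0001271", assay_term_name = "RNA-seq")))
  # reciprocated pair: clean
  ok <- mk_file(base, "f1", list(run_type = "paired-ended", paired_with = "f2"))
  ok <- mk_file(ok, "f2", list(run_type = "paired-ended", paired_with = "f1"))
  expect_equal(nrow(run_audits(ok, rules = "R4")), 0L)
  # paired-ended without a mate (dependency bypassed by direct edit)
  lone <- mk_file(base, "f1", list(run_type = "single-ended"))
  obj <- lone$objects$f1
  obj$properties$run_type <- "paired-ended"
  lone$objects$f1 <- obj
  flags <- run_audits(lone, rules = "R4")
  expect_identical(flags$record_id, "f1")
  # one-sided: f2 names f1 but f1 does not reciprocate
  oneside <- mk_file(lone, "f2", list(run_type = "paired-ended",
                                      paired_with = "f1"))
  obj <- oneside$objects$f1
  obj$properties$run_type <- "single-ended"
  oneside$objects$f1 <- obj
  flags <- run_audits(oneside, rules = "R4")
  expect_identical(flags$record_id, "f2")
})

test_that("technical replicates on different biosamples flag the experiment", {
  # same biological number, different technical numbers, different biosamples
  store <- mini_experiment_store(n_donors = 1, biosample_of_rep = c(1, 2),
                                 donor_of_biosample = c(1, 1))
  for (r in c("rep1", "rep2")) {
    obj <- store$objects[[r]]
    obj$properties$biological_replicate_number <- 1L
    obj$properties$technical_replicate_number <- if (r == "rep1") 1L else 2L
    store$objects[[r]] <- obj
  }
  flags <- run_audits(store, rules = "R5")
  expect_identical(flags$record_id, "exp1")
  # true technical replicates (shared biosample) are clean
  tech <- mini_experiment_store(n_donors = 1, biosample_of_rep = c(1, 1),
                                donor_of_biosample = 1)
  for (r in c("rep1", "rep2")) {
    obj <- tech$objects[[r]]
    obj$properties$biological_replicate_number <- 1L
    obj$properties$technical_replicate_number <- if (r == "rep1") 1L else 2L
    tech$objects[[r]] <- obj
  }
  expect_equal(nrow(run_audits(tech, rules = "R5")), 0L)
})

test_that("files disconnected from their experiment's replicates flag, provenance-aware", {
  res <- generate_consortium(fixture_spec(seed = 11, n_chipseq = 1,
                                          n_rnaseq = 0))
  store <- res$store
  expect_equal(nrow(run_audits(store, rules = "R6")), 0L)
  # a pooled bigWig with no replicate link is fine while its bam ancestry
  # connects; severing derived_from strands it
  bw <- names(Filter(function(o) o$type_name == "file" &&
                       identical(prop(o, "file_format"), "bigWig"),
                     store$objects))[1]
  obj <- store$objects[[bw]]
  obj$properties$derived_from <- NULL
  store$objects[[bw]] <- obj
  flags <- run_audits(store, rules = "R6")
  expect_identical(flags$record_id, bw)
})

test_that("replicates without libraries flag under R7", {
  store <- mini_experiment_store()
  obj <- store$objects$rep1
  obj$properties$library <- NULL
  store$objects$rep1 <- obj
  flags <- run_audits(store, rules = "R7")
  expect_identical(flags$record_id, "rep1")
  expect_identical(flags$severity, "error")
})

test_that("audits are pure, selectable by rule id, and reject unknown ids", {
  res <- generate_consortium(fixture_spec(seed = 13, violation_plan = c(R1 = 1, R4 = 1)))
  f1 <- run_audits(res$store)
  f2 <- run_audits(res$store)
  expect_identical(f1, f2)
  only_r1 <- run_audits(res$store, rules = "R1")
  expect_true(all(only_r1$rule_id == "R1"))
  expect_error(run_audits(res$store, rules = c("R1", "R99")),
               class = "metaforge_unknown_rule")
})

test_that("planted violations are recovered exactly, and a clean store is silent", {
  clean <- generate_consortium(fixture_spec(seed = 17))
  expect_equal(nrow(run_audits(clean$store)), 0L)
  plan <- c(R1 = 2, R2 = 1, R3 = 2, R4 = 1, R5 = 1, R6 = 1, R7 = 1)
  res <- generate_consortium(fixture_spec(seed = 17, violation_plan = plan))
  flags <- run_audits(res$store)
  expect_identical(paste(flags$record_id, flags$rule_id),
                   paste(res$truth$record_id, res$truth$rule_id))
  # per-rule counts match the plan (recall and precision both exact)
  expect_identical(as.integer(table(res$truth$rule_id)[names(sort(plan))]),
                   as.integer(sort(plan)))
})

test_that("repairing the flagged field removes the flag without side effects", {
  res <- generate_consortium(fixture_spec(seed = 19, violation_plan = c(R1 = 1, R3 = 1)))
  store <- res$store
  truth <- res$truth
  r1_target <- truth$record_id[truth$rule_id == "R1"]
  obj <- store$objects[[r1_target]]
  exp <- store$objects[[prop(obj, "experiment")]]
  # repair: restore an antibody link on the flagged replicate
  ab <- names(Filter(function(o) o$type_name == "antibody_lot",
                     store$objects))[1]
  obj$properties$antibody <- ab
  store$objects[[r1_target]] <- obj
  flags <- run_audits(store)
  expect_false(any(flags$record_id == r1_target & flags$rule_id == "R1"))
  expect_equal(nrow(flags), 1L)   # only the R3 plant remains
})

test_that("reports render as parseable TSV and severity-ordered text", {
  flags <- run_audits(mini_experiment_store())
  tsv <- render_report(flags, "tsv")
  parsed <- utils::read.delim(text = tsv, stringsAsFactors = FALSE)
  expect_identical(parsed$record_id, flags$record_id)
  expect_identical(parsed$message, flags$message)
  # empty flag list: header-only
  empty <- run_audits(generate_consortium(fixture_spec(seed = 23,
    n_chipseq = 1, n_rnaseq = 0))$store)
  expect_identical(render_report(empty, "tsv"),
                   "record_id\trule_id\tseverity\tmessage\n")
  # text format groups by severity, most severe first
  mixed <- rbind(
    data.frame(record_id = "x", rule_id = "R3", severity = "warning",
               message = "w", stringsAsFactors = FALSE),
    data.frame(record_id = "y", rule_id = "R4", severity = "error",
               message = "e", stringsAsFactors = FALSE),
    data.frame(record_id = "z", rule_id = "R1", severity = "not-compliant",
               message = "n", stringsAsFactors = FALSE))
  txt <- render_report(mixed, "text")
  pos <- vapply(c("error", "not-compliant", "warning"),
                function(s) regexpr(sprintf("== %s", s), txt, fixed = TRUE)[1],
                numeric(1))
  expect_true(all(diff(pos) > 0))
  expect_error(render_report(flags, "xml"))
})
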