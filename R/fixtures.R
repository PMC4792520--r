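#' Specification for a synthetic consortium store
#'
#' The generator emulates a small consortium's submission stream: human
#' and mouse donors supplying tissue, primary-cell and cell-line
#' biosamples (one donor always supplies both a liver and a brain
#' biosample, and at least one biosample is a keratinocyte), ChIP-seq
#' experiments with antibody lots and input-control experiments, RNA-seq
#' experiments with spike-in-bearing libraries, paired-end fastq pairs,
#' fastq -> bam -> bigWig provenance chains, protocol documents, and
#' pipeline/software records with versions and checksums. All identifiers
#' are minted through the accession registry, and all randomness flows
#' from the single seed, so the same spec always yields a byte-identical
#' store.
#'
#' @param seed integer seed for every random choice.
#' @param n_donors number of donors (human and mouse mixed).
#' @param n_biosamples_per_donor biosamples per donor (>= 2, so the
#'   liver-and-brain-from-one-donor pattern exists).
#' @param n_chipseq,n_rnaseq number of (non-control) ChIP-seq and RNA-seq
#'   experiments.
#' @param replicates_per_experiment biological replicates per experiment.
#' @param files_per_replicate raw fastq files per replicate (ChIP-seq
#'   replicates pair consecutive fastqs as paired-end mates).
#' @param violation_plan named integer vector of planted audit violations,
#'   e.g. `c(R1 = 2, R3 = 1)`; empty for a clean store.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_donors = 6L,
                         n_biosamples_per_donor = 2L,
                         n_chipseq = 10L, n_rnaseq = 10L,
                         replicates_per_experiment = 2L,
                         files_per_replicate = 2L,
                         violation_plan = integer(0)) {
  stopifnot(n_donors >= 1L, n_biosamples_per_donor >= 2L,
            n_chipseq >= 0L, n_rnaseq >= 0L,
            replicates_per_experiment >= 1L, files_per_replicate >= 1L)
  if (length(violation_plan)) {
    known <- vapply(default_audit_ruleset(), `[[`, character(1), "rule_id")
    bad <- setdiff(names(violation_plan), known)
    if (length(bad)) {
      mf_stop("unknown_rule",
              sprintf("violation_plan names unknown rule(s): %s",
                      paste(bad, collapse = ", ")))
    }
    stopifnot(all(violation_plan >= 0))
  }
  structure(list(seed = as.integer(seed), n_donors = as.integer(n_donors),
                 n_biosamples_per_donor = as.integer(n_biosamples_per_donor),
                 n_chipseq = as.integer(n_chipseq),
                 n_rnaseq = as.integer(n_rnaseq),
                 replicates_per_experiment =
                   as.integer(replicates_per_experiment),
                 files_per_replicate = as.integer(files_per_replicate),
                 violation_plan = violation_plan),
            class = "fixture_spec")
}

# biosample term pool: (name, field, term id) cycled over donors
biosample_term_pool <- function() {
  data.frame(
    name = c("liver", "brain", "keratinocyte", "hepatocyte",
             "HepG2", "K562", "lung", "heart"),
    field = c("tissue_term_id", "tissue_term_id", "cell_term_id",
              "cell_term_id", "cell_line_term_id", "cell_line_term_id",
              "tissue_term_id", "tissue_term_id"),
    term = c("UBERON:0002107", "UBERON:0000955", "CL:0000312", "CL:0000182",
             "EFO:0001187", "EFO:0002067", "UBERON:0002048", "UBERON:0000948"),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic consortium store
#'
#' @param spec a [fixture_spec()].
#' @param registry schema registry to validate against.
#' @return a list with `store` (finalized [metadata_store()]), `truth`
#'   (data.frame of planted `(record_id, rule_id)` violations, zero rows
#'   for a clean store) and `accessions` (the accession registry used for
#'   minting). A clean store passes schema validation, referential
#'   integrity and the built-in audits with zero findings.
#' @export
generate_consortium <- function(spec = fixture_spec(),
                                registry = load_schema_dir()) {
  stopifnot(inherits(spec, "fixture_spec"))
  store <- metadata_store(registry)
  areg <- accession_registry()
  mint <- function(code, n) {
    res <- mint_accession(areg, code, seed = spec$seed + match(code,
             c("SR", "BS", "DO", "AB", "LB", "FF")), n = n)
    areg <<- res$registry
    vapply(res$accessions, `[[`, character(1), "text")
  }
  add <- function(type, id, props) {
    store <<- add_object(store, metadata_object(type, id, props))
    id
  }
  with_seed(spec$seed, {
    lab_id <- add("lab", "lab-metaforge",
                  list(name = "metaforge-lab", title = "Metaforge Lab",
                       status = "released"))
    award_id <- add("award", "award-U00HG000001",
                    list(name = "U00HG000001", project = "consortium",
                         status = "released"))
    doc_growth <- add("document", "doc-growth-protocol",
                      list(document_type = "growth protocol",
                           description = "standard growth conditions",
                           status = "released"))
    doc_library <- add("document", "doc-library-protocol",
                       list(document_type = "library protocol",
                            description = "library preparation protocol",
                            status = "released"))
    treat_id <- add("treatment", "treatment-tamoxifen",
                    list(treatment_term_id = "CHEBI:41774",
                         treatment_term_name = "tamoxifen",
                         amount = 100, amount_units = "nM",
                         duration = 4, duration_units = "hour",
                         status = "released"))

    # donors: first ~half human, rest mouse
    donor_ids <- mint("DO", spec$n_donors)
    n_human <- ceiling(spec$n_donors / 2)
    for (i in seq_len(spec$n_donors)) {
      add("donor", donor_ids[i],
          list(organism = if (i <= n_human) "human" else "mouse",
               sex = sample(c("male", "female"), 1L),
               age = as.character(sample(21:70, 1L)),
               life_stage = "adult",
               lab = lab_id, award = award_id, status = "released"))
    }

    # biosamples cycled over the term pool; donor 1 gets liver then brain
    pool <- biosample_term_pool()
    n_bios <- spec$n_donors * spec$n_biosamples_per_donor
    bios_ids <- mint("BS", n_bios)
    bios_meta <- list()
    k <- 0L
    for (d in seq_len(spec$n_donors)) {
      for (b in seq_len(spec$n_biosamples_per_donor)) {
        k <- k + 1L
        row <- pool[(k - 1L) %% nrow(pool) + 1L, ]
        props <- list(biosample_term_name = row$name,
                      donor = donor_ids[d],
                      source = "metaforge consortium",
                      starting_amount = 1e6, starting_amount_units = "cells",
                      documents = list(doc_growth),
                      lab = lab_id, award = award_id, status = "released")
        props[[row$field]] <- row$term
        if (k == 4L) props$treatments <- list(treat_id)
        add("biosample", bios_ids[k], props)
        bios_meta[[k]] <- list(id = bios_ids[k], donor = donor_ids[d],
                               name = row$name)
      }
    }

    # antibody lots for ChIP targets
    ab_targets <- c("H3K4me3", "H3K27ac", "CTCF", "POLR2A")
    n_ab <- max(1L, min(length(ab_targets), ceiling(spec$n_chipseq / 3)))
    ab_ids <- if (spec$n_chipseq > 0L) mint("AB", n_ab) else character(0)
    for (i in seq_along(ab_ids)) {
      add("antibody_lot", ab_ids[i],
          list(source = "metaforge reagents",
               product_id = sprintf("mab-%03d", i),
               lot_id = sprintf("lot-%04d", sample(1000:9999, 1L)),
               targets = list(paste0(ab_targets[i], " (human)")),
               host_organism = "rabbit", status = "released"))
    }

    # software and pipelines
    sw_align <- add("software", "software-aligner",
                    list(name = "metaforge-aligner", version = "2.4.1",
                         md5sum = random_md5(), status = "released"))
    sw_quant <- add("software", "software-quantifier",
                    list(name = "metaforge-quantifier", version = "1.3.0",
                         md5sum = random_md5(), status = "released"))
    pipe_chip <- add("pipeline", "pipeline-chip",
                     list(title = "ChIP-seq processing pipeline",
                          software = list(sw_align), status = "released"))
    pipe_rna <- add("pipeline", "pipeline-rna",
                    list(title = "RNA-seq processing pipeline",
                         software = list(sw_align, sw_quant),
                         status = "released"))

    # experiment plan: controls first (so ChIP-seq experiments can link
    # them), then ChIP-seq, then RNA-seq
    n_controls <- if (spec$n_chipseq > 0L) max(1L, ceiling(spec$n_chipseq / 4))
      else 0L
    n_exp <- n_controls + spec$n_chipseq + spec$n_rnaseq
    exp_ids <- if (n_exp > 0L) mint("SR", n_exp) else character(0)
    ctrl_ids <- utils::head(exp_ids, n_controls)
    chip_ids <- exp_ids[seq_len(spec$n_chipseq) + n_controls]
    rna_ids <- utils::tail(exp_ids, spec$n_rnaseq)

    # technical pairs: the first (up to) two ChIP-seq experiments carry an
    # extra technical replicate on biological replicate 1
    tech_pair_exps <- utils::head(chip_ids, 2L)

    rpe <- spec$replicates_per_experiment
    bio_cursor <- 0L
    next_biosamples <- function(n) {
      idx <- ((bio_cursor + seq_len(n) - 1L) %% n_bios) + 1L
      bio_cursor <<- bio_cursor + n
      idx
    }

    plan <- list()
    build_exp <- function(exp_id, kind) {
      # kind: "control", "chip", "rna"
      assay_id <- if (kind == "rna") "OBI:0001271" else "OBI:0000716"
      assay_name <- if (kind == "rna") "RNA-seq" else "ChIP-seq"
      props <- list(assay_term_id = assay_id, assay_term_name = assay_name,
                    description = sprintf("%s assay %s", assay_name, exp_id),
                    lab = lab_id, award = award_id, status = "released")
      if (kind == "control") {
        props$control_type <- "input library"
        props$description <- sprintf("input control %s", exp_id)
      }
      if (kind == "chip") {
        props$target <- ab_targets[(match(exp_id, chip_ids) - 1L) %%
                                     length(ab_targets) + 1L]
        props$possible_controls <-
          list(ctrl_ids[(match(exp_id, chip_ids) - 1L) %% n_controls + 1L])
      }
      add("experiment", exp_id, props)
      bios_idx <- next_biosamples(rpe)
      reps <- data.frame(bio = seq_len(rpe), tech = 1L,
                         biosample = bios_idx)
      if (kind == "chip" && exp_id %in% tech_pair_exps) {
        reps <- rbind(reps, data.frame(bio = 1L, tech = 2L,
                                       biosample = bios_idx[1]))
      }
      list(exp_id = exp_id, kind = kind, reps = reps)
    }
    for (id in ctrl_ids) plan[[length(plan) + 1L]] <- build_exp(id, "control")
    for (id in chip_ids) plan[[length(plan) + 1L]] <- build_exp(id, "chip")
    for (id in rna_ids) plan[[length(plan) + 1L]] <- build_exp(id, "rna")

    n_libs <- sum(vapply(plan, function(p) nrow(p$reps), integer(1)))
    lib_ids <- if (n_libs > 0L) mint("LB", n_libs) else character(0)
    n_raw <- n_libs * spec$files_per_replicate
    n_bam <- n_libs
    n_bw <- length(plan)
    file_ids <- if (n_raw + n_bam + n_bw > 0L)
      mint("FF", n_raw + n_bam + n_bw) else character(0)
    lib_cursor <- 0L
    file_cursor <- 0L
    next_lib <- function() { lib_cursor <<- lib_cursor + 1L; lib_ids[lib_cursor] }
    next_file <- function() { file_cursor <<- file_cursor + 1L; file_ids[file_cursor] }

    for (p in plan) {
      exp_bams <- character(0)
      for (r in seq_len(nrow(p$reps))) {
        row <- p$reps[r, ]
        lib_id <- next_lib()
        lib_props <- list(
          biosample = bios_meta[[row$biosample]]$id,
          nucleic_acid_term_name = if (p$kind == "rna")
            "polyadenylated mRNA" else "DNA",
          documents = list(doc_library), status = "released")
        if (p$kind == "rna") lib_props$spikeins_used <- list("ERCC-Mix1")
        add("library", lib_id, lib_props)
        rep_id <- sprintf("rep-%s-%d-%d", p$exp_id, row$bio, row$tech)
        rep_props <- list(experiment = p$exp_id, library = lib_id,
                          biological_replicate_number = row$bio,
                          technical_replicate_number = row$tech,
                          status = "released")
        if (p$kind == "chip") {
          rep_props$antibody <- ab_ids[(match(p$exp_id, chip_ids) - 1L) %%
                                         length(ab_ids) + 1L]
        }
        add("replicate", rep_id, rep_props)
        # raw fastqs: ChIP-seq (and its controls) pair consecutive files
        fastqs <- character(spec$files_per_replicate)
        for (f in seq_len(spec$files_per_replicate)) fastqs[f] <- next_file()
        paired <- p$kind != "rna"
        for (f in seq_len(spec$files_per_replicate)) {
          fprops <- list(dataset = p$exp_id, file_format = "fastq",
                         output_type = "reads", md5sum = random_md5(),
                         replicate = rep_id, status = "released")
          if (paired && f %% 2L == 0L) {
            fprops$run_type <- "paired-ended"
            fprops$paired_with <- fastqs[f - 1L]
          } else if (paired && f < spec$files_per_replicate) {
            fprops$run_type <- "paired-ended"
            fprops$paired_with <- fastqs[f + 1L]
          } else {
            fprops$run_type <- "single-ended"
          }
          add("file", fastqs[f], fprops)
        }
        bam_id <- next_file()
        add("file", bam_id,
            list(dataset = p$exp_id, file_format = "bam",
                 output_type = "alignments", md5sum = random_md5(),
                 derived_from = as.list(fastqs), replicate = rep_id,
                 pipeline = if (p$kind == "rna") pipe_rna else pipe_chip,
                 status = "released"))
        exp_bams <- c(exp_bams, bam_id)
      }
      bw_id <- next_file()
      add("file", bw_id,
          list(dataset = p$exp_id, file_format = "bigWig",
               output_type = "signal", md5sum = random_md5(),
               derived_from = as.list(exp_bams),
               pipeline = if (p$kind == "rna") pipe_rna else pipe_chip,
               status = "released"))
    }
  })
  store <- finalize_store(store)
  truth <- data.frame(record_id = character(0), rule_id = character(0),
                      stringsAsFactors = FALSE)
  if (length(spec$violation_plan) && sum(spec$violation_plan) > 0L) {
    res <- corrupt(store, spec$violation_plan, seed = spec$seed + 1000L)
    store <- res$store
    truth <- res$truth
  }
  list(store = store, truth = truth, accessions = areg)
}

#' Plant ground-truthed violations in a clean store
#'
#' Applies minimal field edits, each inducing exactly one planned audit
#' flag and no others; the edit set is verified by re-auditing after every
#' edit, so the returned ground truth equals the flag set by construction.
#'
#' @param store a clean, finalized [metadata_store()] (zero audit flags).
#' @param violation_plan named integer vector, e.g. `c(R4 = 1)`.
#' @param seed seed for target selection.
#' @return list with the corrupted `store` and `truth` (data.frame of
#'   `record_id`, `rule_id`). An infeasible plan (more violations
#'   requested than eligible targets) is an error.
#' @export
corrupt <- function(store, violation_plan, seed = 1L) {
  stopifnot(inherits(store, "metadata_store"))
  if (!length(violation_plan) || sum(violation_plan) == 0L) {
    return(list(store = store,
                truth = data.frame(record_id = character(0),
                                   rule_id = character(0),
                                   stringsAsFactors = FALSE)))
  }
  baseline <- run_audits(store)
  if (nrow(baseline)) {
    mf_stop("corrupt_error", "store is not clean: it already carries audit flags")
  }
  objs <- store$objects
  chip_term <- default_audit_context()$chipseq_terms
  is_type <- function(o, t) o$type_name == t
  candidates_for <- function(rule_id) {
    switch(rule_id,
      R1 = names(Filter(function(o) {
        if (!is_type(o, "replicate") || !has_prop(o, "antibody")) return(FALSE)
        e <- objs[[prop(o, "experiment") %||% ""]]
        !is.null(e) && !is_control_experiment(e) &&
          identical(prop(e, "assay_term_id"), chip_term)
      }, objs)),
      R2 = names(Filter(function(o) {
        is_type(o, "experiment") && !is_control_experiment(o) &&
          identical(prop(o, "assay_term_id"), chip_term) &&
          has_prop(o, "possible_controls")
      }, objs)),
      R3 = names(Filter(function(o) {
        is_type(o, "library") && has_prop(o, "spikeins_used")
      }, objs)),
      R4 = names(Filter(function(o) {
        is_type(o, "file") && identical(prop(o, "run_type"), "paired-ended") &&
          has_prop(o, "paired_with")
      }, objs)),
      R5 = names(Filter(function(o) {
        if (!is_type(o, "experiment")) return(FALSE)
        reps <- replicates_of(store, o$id)
        bionum <- vapply(reps, function(r)
          as.integer(prop(r, "biological_replicate_number")), integer(1))
        any(table(bionum) >= 2L)
      }, objs)),
      R6 = names(Filter(function(o) {
        is_type(o, "file") && has_prop(o, "replicate") &&
          !has_prop(o, "derived_from")
      }, objs)),
      R7 = names(Filter(function(o) {
        is_type(o, "replicate") && has_prop(o, "library")
      }, objs)),
      mf_stop("unknown_rule", sprintf("unknown rule id '%s'", rule_id)))
  }
  apply_edit <- function(store, rule_id, target) {
    # returns list(store, flagged_id) or NULL if the edit is not possible
    obj <- store$objects[[target]]
    switch(rule_id,
      R1 = { obj$properties$antibody <- NULL
             store$objects[[target]] <- obj
             list(store = store, flagged = target) },
      R2 = { obj$properties$possible_controls <- NULL
             store$objects[[target]] <- obj
             list(store = store, flagged = target) },
      R3 = { obj$properties$spikeins_used <- NULL
             store$objects[[target]] <- obj
             list(store = store, flagged = target) },
      R4 = { mate <- prop(obj, "paired_with")
             obj$properties$paired_with <- NULL
             obj$properties$run_type <- "single-ended"
             store$objects[[target]] <- obj
             list(store = store, flagged = mate) },
      R5 = { reps <- replicates_of(store, target)
             bionum <- vapply(reps, function(r)
               as.integer(prop(r, "biological_replicate_number")), integer(1))
             dupnum <- as.integer(names(which(table(bionum) >= 2L))[1])
             pair <- reps[bionum == dupnum]
             victim <- store$objects[[prop(pair[[1]], "library")]]
             cur_bio <- prop(victim, "biosample")
             other <- setdiff(names(Filter(function(o)
               o$type_name == "biosample", store$objects)), cur_bio)
             if (!length(other)) return(NULL)
             victim$properties$biosample <- sort(other)[1]
             store$objects[[victim$id]] <- victim
             list(store = store, flagged = target) },
      R6 = { obj$properties$replicate <- NULL
             store$objects[[target]] <- obj
             list(store = store, flagged = target) },
      R7 = { obj$properties$library <- NULL
             store$objects[[target]] <- obj
             list(store = store, flagged = target) })
  }
  truth_rows <- list()
  with_seed(seed, {
    for (rule_id in sort(names(violation_plan))) {
      n_wanted <- violation_plan[[rule_id]]
      if (n_wanted == 0L) next
      cands <- sort(candidates_for(rule_id))
      cands <- if (length(cands) > 1L) sample(cands) else cands
      planted <- 0L
      for (target in cands) {
        if (planted >= n_wanted) break
        trial <- apply_edit(store, rule_id, target)
        if (is.null(trial)) next
        expected <- rbind(do.call(rbind, c(truth_rows, list(data.frame(
          record_id = trial$flagged, rule_id = rule_id,
          stringsAsFactors = FALSE)))))
        flags <- run_audits(trial$store)
        if (setequal(paste(flags$record_id, flags$rule_id),
                     paste(expected$record_id, expected$rule_id)) &&
            nrow(flags) == nrow(expected)) {
          store <- trial$store
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            record_id = trial$flagged, rule_id = rule_id,
            stringsAsFactors = FALSE)
          planted <- planted + 1L
        }
        # otherwise: edit had side effects; discard the trial store
      }
      if (planted < n_wanted) {
        mf_stop("infeasible_plan",
                sprintf("cannot plant %d violation(s) of %s: only %d target(s) usable",
                        n_wanted, rule_id, planted))
      }
    }
  })
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(record_id = character(0), rule_id = character(0),
               stringsAsFactors = FALSE)
  truth <- truth[order(truth$record_id, truth$rule_id), , drop = FALSE]
  rownames(truth) <- NULL
  list(store = store, truth = truth)
}
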