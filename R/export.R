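#' Export experiments as ISA-TAB tables
#'
#' Produces the three ISA-TAB tables as data.frames: an investigation
#' table, a study table with one row per distinct biosample used by the
#' requested experiments (a biosample shared by several experiments
#' appears once), and an assay table with one row per (replicate, raw
#' file) pair. File names in exports follow the accession-as-filename
#' convention: accession plus the file format as extension.
#'
#' @param store a finalized [metadata_store()].
#' @param experiment_ids experiment accessions to export.
#' @return list of class `isatab_export` with elements `investigation`,
#'   `study`, `assay` (data.frames). An experiment with no replicates is
#'   an error naming it.
#' @export
export_isatab <- function(store, experiment_ids) {
  stopifnot(inherits(store, "metadata_store"))
  study_rows <- list()
  assay_rows <- list()
  seen_biosamples <- character(0)
  for (exp_id in sort(experiment_ids)) {
    exp <- get_object(store, exp_id)
    reps <- replicates_of(store, exp_id)
    if (!length(reps)) {
      mf_stop("export_error",
              sprintf("experiment '%s' has no replicates", exp_id))
    }
    reps <- reps[order(names(reps))]
    for (rep in reps) {
      lib <- store$objects[[prop(rep, "library") %||% ""]]
      bio <- if (!is.null(lib))
        store$objects[[prop(lib, "biosample") %||% ""]] else NULL
      donor_id <- if (!is.null(bio)) prop(bio, "donor") else NA_character_
      bio_id <- if (!is.null(bio)) bio$id else NA_character_
      if (!is.na(bio_id) && !bio_id %in% seen_biosamples) {
        seen_biosamples <- c(seen_biosamples, bio_id)
        donor <- store$objects[[donor_id %||% ""]]
        study_rows[[length(study_rows) + 1L]] <- data.frame(
          `Source Name` = donor_id %||% "",
          `Characteristics[organism]` =
            if (!is.null(donor)) prop(donor, "organism") %||% "" else "",
          `Sample Name` = bio_id,
          `Characteristics[biosample term]` =
            if (!is.null(bio)) prop(bio, "biosample_term_name") %||% "" else "",
          check.names = FALSE, stringsAsFactors = FALSE)
      }
      raw_files <- Filter(function(o) {
        o$type_name == "file" &&
          identical(prop(o, "replicate"), rep$id) &&
          identical(prop(o, "file_format"), "fastq")
      }, store$objects)
      raw_files <- raw_files[order(names(raw_files))]
      for (f in raw_files) {
        assay_rows[[length(assay_rows) + 1L]] <- data.frame(
          `Sample Name` = bio_id %||% "",
          `Assay Name` = exp_id,
          `Parameter Value[assay term]` = prop(exp, "assay_term_name") %||% "",
          `Parameter Value[biological replicate]` =
            as.integer(prop(rep, "biological_replicate_number") %||% NA),
          `Parameter Value[technical replicate]` =
            as.integer(prop(rep, "technical_replicate_number") %||% NA),
          `Raw Data File` = paste0(f$id, ".", prop(f, "file_format")),
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  empty_df <- function(cols) {
    as.data.frame(stats::setNames(replicate(length(cols), character(0),
                                            simplify = FALSE), cols),
                  check.names = FALSE)
  }
  study <- if (length(study_rows)) do.call(rbind, study_rows) else
    empty_df(c("Source Name", "Characteristics[organism]", "Sample Name",
               "Characteristics[biosample term]"))
  study <- study[order(study$`Sample Name`), , drop = FALSE]
  rownames(study) <- NULL
  assay <- if (length(assay_rows)) do.call(rbind, assay_rows) else
    empty_df(c("Sample Name", "Assay Name", "Parameter Value[assay term]",
               "Parameter Value[biological replicate]",
               "Parameter Value[technical replicate]", "Raw Data File"))
  rownames(assay) <- NULL
  investigation <- data.frame(
    Field = c("Investigation Identifier", "Investigation Title",
              "Study Count", "Assay Row Count"),
    Value = c("metaforge-export",
              "Functional genomics assay metadata export",
              as.character(nrow(study)), as.character(nrow(assay))),
    stringsAsFactors = FALSE)
  structure(list(investigation = investigation, study = study, assay = assay),
            class = "isatab_export")
}

#' Write ISA-TAB tables to a directory
#'
#' Writes `i_investigation.txt`, `s_study.txt` and `a_assay.txt` as
#' tab-separated text. Export is a pure function of the store, so
#' re-export is byte-identical.
#'
#' @param export an [export_isatab()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_isatab <- function(export, dir) {
  stopifnot(inherits(export, "isatab_export"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
  }
  write_tsv(export$investigation, file.path(dir, "i_investigation.txt"))
  write_tsv(export$study, file.path(dir, "s_study.txt"))
  write_tsv(export$assay, file.path(dir, "a_assay.txt"))
  invisible(dir)
}

#' Export an experiment in GEO SOFT format
#'
#' One `^SERIES` block for the experiment and one `^SAMPLE` block per
#' replicate, each carrying organism, biosample characteristics, library
#' strategy (the assay name) and the replicate's raw file names. An
#' experiment whose replicates have no files still exports, with empty
#' supplementary-file lines and a warning.
#'
#' @param store a finalized [metadata_store()].
#' @param experiment_id experiment accession.
#' @return SOFT text (single string).
#' @export
export_geo_soft <- function(store, experiment_id) {
  exp <- get_object(store, experiment_id)
  reps <- replicates_of(store, experiment_id)
  if (!length(reps)) {
    mf_stop("export_error",
            sprintf("experiment '%s' has no replicates", experiment_id))
  }
  reps <- reps[order(names(reps))]
  lines <- c(
    sprintf("^SERIES = %s", experiment_id),
    sprintf("!Series_title = %s",
            prop(exp, "description") %||% prop(exp, "assay_term_name") %||% ""),
    sprintf("!Series_type = %s", prop(exp, "assay_term_name") %||% ""))
  n_files_total <- 0L
  for (rep in reps) {
    lib <- store$objects[[prop(rep, "library") %||% ""]]
    bio <- if (!is.null(lib))
      store$objects[[prop(lib, "biosample") %||% ""]] else NULL
    donor <- if (!is.null(bio))
      store$objects[[prop(bio, "donor") %||% ""]] else NULL
    raw_files <- Filter(function(o) {
      o$type_name == "file" && identical(prop(o, "replicate"), rep$id) &&
        identical(prop(o, "file_format"), "fastq")
    }, store$objects)
    raw_files <- raw_files[order(names(raw_files))]
    n_files_total <- n_files_total + length(raw_files)
    file_lines <- if (length(raw_files)) {
      sprintf("!Sample_supplementary_file = %s.%s",
              names(raw_files),
              vapply(raw_files, function(f) prop(f, "file_format"),
                     character(1)))
    } else {
      "!Sample_supplementary_file ="
    }
    lines <- c(lines,
      sprintf("^SAMPLE = %s_%s", experiment_id, rep$id),
      sprintf("!Sample_organism_ch1 = %s",
              if (!is.null(donor)) prop(donor, "organism") %||% "" else ""),
      sprintf("!Sample_characteristics_ch1 = biosample: %s",
              if (!is.null(bio)) prop(bio, "biosample_term_name") %||% "" else ""),
      sprintf("!Sample_characteristics_ch1 = biosample accession: %s",
              if (!is.null(bio)) bio$id else ""),
      sprintf("!Sample_library_strategy = %s",
              prop(exp, "assay_term_name") %||% ""),
      file_lines)
  }
  if (n_files_total == 0L) {
    warning(sprintf("experiment '%s' has no raw files; SOFT export has empty supplementary-file lines",
                    experiment_id))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' MINSEQE compliance report
#'
#' Operationalizes the minimum-information guideline for high-throughput
#' sequencing experiments as five checks: the assay is described (an
#' ontology-coded assay term is present); the samples are described (every
#' replicate resolves through its library to a biosample with a donor or
#' strain); protocols are present (at least one document attached to a
#' library or biosample of the experiment); raw data are present (at
#' least one fastq file); processed data are present (at least one
#' non-fastq file). The experiment is compliant iff all five hold.
#'
#' @param store a finalized [metadata_store()].
#' @param experiment_id experiment accession.
#' @return object of class `minseqe_report`: the per-check booleans and
#'   `compliant`, their conjunction.
#' @export
check_minseqe <- function(store, experiment_id) {
  exp <- get_object(store, experiment_id)
  reps <- replicates_of(store, experiment_id)
  assay_described <- has_prop(exp, "assay_term_id")
  samples_described <- length(reps) > 0L && all(vapply(reps, function(r) {
    lib <- store$objects[[prop(r, "library") %||% ""]]
    bio <- if (!is.null(lib))
      store$objects[[prop(lib, "biosample") %||% ""]] else NULL
    !is.null(bio) && has_prop(bio, "donor")
  }, logical(1)))
  protocols_present <- any(vapply(reps, function(r) {
    lib <- store$objects[[prop(r, "library") %||% ""]]
    bio <- if (!is.null(lib))
      store$objects[[prop(lib, "biosample") %||% ""]] else NULL
    (!is.null(lib) && has_prop(lib, "documents")) ||
      (!is.null(bio) && has_prop(bio, "documents"))
  }, logical(1)))
  files <- Filter(function(o) o$type_name == "file" &&
                    identical(prop(o, "dataset"), experiment_id),
                  store$objects)
  formats <- vapply(files, function(f) prop(f, "file_format") %||% "",
                    character(1))
  raw_present <- any(formats == "fastq")
  processed_present <- any(formats != "fastq" & nzchar(formats))
  checks <- c(assay_described = assay_described,
              samples_described = samples_described,
              protocols_present = protocols_present,
              raw_data_present = raw_present,
              processed_data_present = processed_present)
  structure(list(experiment_id = experiment_id, checks = checks,
                 compliant = all(checks)),
            class = "minseqe_report")
}

#' @export
print.minseqe_report <- function(x, ...) {
  cat(sprintf("<minseqe_report> %s: %s\n", x$experiment_id,
              if (x$compliant) "compliant" else "NOT compliant"))
  for (nm in names(x$checks)) {
    cat(sprintf("  [%s] %s\n", if (x$checks[[nm]]) "x" else " ", nm))
  }
  invisible(x)
}
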