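#' Audit rules and the built-in ruleset
#'
#' Audits are post-submission consistency checks over the finalized object
#' graph — the complement of per-record schema validation. Each rule is
#' data: an id, the record type it applies to, a severity, a description
#' and a pure predicate, so downstream users can register new rules
#' without touching the engine. Rule applicability keys off the
#' experiment's ontology-coded assay term (OBI CURIEs), not free text.
#'
#' The built-in ruleset:
#' \describe{
#'   \item{R1 (not-compliant)}{a ChIP-seq replicate must link an antibody
#'     lot (input-control experiments, marked by `control_type`, are
#'     exempt — their libraries are immunoprecipitation-free).}
#'   \item{R2 (not-compliant)}{a ChIP-seq experiment must list at least one
#'     control experiment in `possible_controls` (control experiments
#'     themselves are exempt).}
#'   \item{R3 (warning)}{a library sequenced in an RNA-seq experiment must
#'     declare its spike-in reference.}
#'   \item{R4 (error)}{a paired-ended file must name its mate, and
#'     `paired_with` must be reciprocated.}
#'   \item{R5 (error)}{technical replicates (same biological number,
#'     different technical number) must share a biosample.}
#'   \item{R6 (error)}{a file must be connected to a replicate of its
#'     experiment, directly or through its `derived_from` ancestry
#'     (pooled processed files are connected through their inputs).}
#'   \item{R7 (error)}{a replicate must link a library.}
#' }
#'
#' @param rule_id,applies_to,severity,description,predicate rule fields;
#'   `predicate(record, store, ctx)` returns a character vector of
#'   messages (empty = no flag). `ctx` carries the assay-term
#'   configuration.
#' @return `audit_rule` returns an `audit_rule`; `default_audit_ruleset`
#'   the built-in list of rules.
#' @export
audit_rule <- function(rule_id, applies_to, severity, description, predicate) {
  stopifnot(is_scalar_chr(rule_id), is_scalar_chr(applies_to),
            severity %in% c("error", "not-compliant", "warning", "internal"),
            is.function(predicate))
  structure(list(rule_id = rule_id, applies_to = applies_to,
                 severity = severity, description = description,
                 predicate = predicate),
            class = "audit_rule")
}

# assay CURIEs used for rule applicability; overridable through the ctx
default_audit_context <- function() {
  list(chipseq_terms = "OBI:0000716",
       rnaseq_terms = "OBI:0001271",
       controls_required_terms = "OBI:0000716")
}

experiment_of_replicate <- function(store, rep) {
  exp_id <- prop(rep, "experiment")
  if (is.null(exp_id)) NULL else store$objects[[exp_id]]
}

assay_of <- function(exp) if (is.null(exp)) NULL else prop(exp, "assay_term_id")

is_control_experiment <- function(exp) has_prop(exp, "control_type")

replicates_of <- function(store, exp_id) {
  Filter(function(o) o$type_name == "replicate" &&
           identical(prop(o, "experiment"), exp_id), store$objects)
}

#' @rdname audit_rule
#' @export
default_audit_ruleset <- function() {
  list(
    audit_rule("R1", "replicate", "not-compliant",
      "ChIP-seq replicate lacks an antibody lot",
      function(record, store, ctx) {
        exp <- experiment_of_replicate(store, record)
        if (is.null(exp) || is_control_experiment(exp)) return(character(0))
        assay <- assay_of(exp)
        if (is.null(assay) || !assay %in% ctx$chipseq_terms) return(character(0))
        if (has_prop(record, "antibody")) return(character(0))
        sprintf("replicate '%s' of ChIP-seq experiment '%s' has no 'antibody' link",
                record$id, exp$id)
      }),
    audit_rule("R2", "experiment", "not-compliant",
      "ChIP-seq experiment lacks a control experiment",
      function(record, store, ctx) {
        assay <- assay_of(record)
        if (is.null(assay) || !assay %in% ctx$controls_required_terms ||
            is_control_experiment(record)) return(character(0))
        controls <- unlist(prop(record, "possible_controls"), use.names = FALSE)
        if (length(controls)) return(character(0))
        sprintf("experiment '%s' lists no control in 'possible_controls'",
                record$id)
      }),
    audit_rule("R3", "library", "warning",
      "RNA-seq library lacks a spike-in reference",
      function(record, store, ctx) {
        reps <- Filter(function(o) o$type_name == "replicate" &&
                         identical(prop(o, "library"), record$id),
                       store$objects)
        assays <- unlist(lapply(reps, function(r)
          assay_of(experiment_of_replicate(store, r))), use.names = FALSE)
        if (!any(assays %in% ctx$rnaseq_terms)) return(character(0))
        if (has_prop(record, "spikeins_used")) return(character(0))
        sprintf("RNA-seq library '%s' declares no 'spikeins_used'", record$id)
      }),
    audit_rule("R4", "file", "error",
      "paired-ended file lacking or one-sided paired_with",
      function(record, store, ctx) {
        msgs <- character(0)
        if (identical(prop(record, "run_type"), "paired-ended") &&
            !has_prop(record, "paired_with")) {
          msgs <- c(msgs, sprintf("paired-ended file '%s' has no 'paired_with'",
                                  record$id))
        }
        if (has_prop(record, "paired_with")) {
          mate <- store$objects[[prop(record, "paired_with")]]
          if (is.null(mate) ||
              !identical(prop(mate, "paired_with"), record$id)) {
            msgs <- c(msgs,
                      sprintf("file '%s' names mate '%s' but 'paired_with' is not reciprocated",
                              record$id, prop(record, "paired_with")))
          }
        }
        msgs
      }),
    audit_rule("R5", "experiment", "error",
      "technical replicates do not share a biosample",
      function(record, store, ctx) {
        reps <- replicates_of(store, record$id)
        if (length(reps) < 2L) return(character(0))
        bio_of <- function(r) {
          lib <- store$objects[[prop(r, "library") %||% ""]]
          if (is.null(lib)) NA_character_ else
            prop(lib, "biosample") %||% NA_character_
        }
        msgs <- character(0)
        bionum <- vapply(reps, function(r)
          as.integer(prop(r, "biological_replicate_number") %||% NA_integer_),
          integer(1))
        for (bn in unique(bionum[!is.na(bionum)])) {
          group <- reps[which(bionum == bn)]
          if (length(group) < 2L) next
          samples <- vapply(group, bio_of, character(1))
          samples <- samples[!is.na(samples)]
          if (length(unique(samples)) > 1L) {
            msgs <- c(msgs,
                      sprintf("technical replicates (biological number %d) of '%s' use different biosamples: %s",
                              bn, record$id,
                              paste(sort(unique(samples)), collapse = ", ")))
          }
        }
        msgs
      }),
    audit_rule("R6", "file", "error",
      "file connected to no replicate of its experiment",
      function(record, store, ctx) {
        exp_id <- prop(record, "dataset")
        if (is.null(exp_id)) return(character(0))
        connects <- function(fid, visited = character(0)) {
          if (fid %in% visited) return(FALSE)
          obj <- store$objects[[fid]]
          if (is.null(obj)) return(FALSE)
          rep_id <- prop(obj, "replicate")
          if (!is.null(rep_id)) {
            rep <- store$objects[[rep_id]]
            if (!is.null(rep) &&
                identical(prop(rep, "experiment"), exp_id)) return(TRUE)
          }
          parents <- unlist(prop(obj, "derived_from"), use.names = FALSE)
          for (p in parents) {
            if (connects(p, c(visited, fid))) return(TRUE)
          }
          FALSE
        }
        if (connects(record$id)) return(character(0))
        sprintf("file '%s' is linked to no replicate of experiment '%s' (field 'replicate')",
                record$id, exp_id)
      }),
    audit_rule("R7", "replicate", "error",
      "replicate lacks a library",
      function(record, store, ctx) {
        if (has_prop(record, "library")) return(character(0))
        sprintf("replicate '%s' has no 'library' link", record$id)
      })
  )
}

#' Run audits over a finalized store
#'
#' Applies each rule's predicate to every record of its type and returns
#' the flags, sorted by (record id, rule id). Auditing is pure: running
#' twice on the same store yields identical output.
#'
#' @param store a finalized [metadata_store()].
#' @param ruleset list of [audit_rule()]s, default [default_audit_ruleset()].
#' @param rules optionally, rule ids to restrict to; unknown ids error.
#' @param ctx assay-term configuration, see [audit_rule()].
#' @return data.frame of class `audit_flags` with columns `record_id`,
#'   `rule_id`, `severity`, `message`.
#' @export
run_audits <- function(store, ruleset = default_audit_ruleset(), rules = NULL,
                       ctx = default_audit_context()) {
  stopifnot(inherits(store, "metadata_store"))
  ids <- vapply(ruleset, `[[`, character(1), "rule_id")
  if (anyDuplicated(ids)) mf_stop("ruleset_error", "duplicate rule ids")
  if (!is.null(rules)) {
    unknown <- setdiff(rules, ids)
    if (length(unknown)) {
      mf_stop("unknown_rule",
              sprintf("unknown rule id(s): %s", paste(unknown, collapse = ", ")))
    }
    ruleset <- ruleset[ids %in% rules]
  }
  rows <- list()
  for (rule in ruleset) {
    targets <- Filter(function(o) o$type_name == rule$applies_to,
                      store$objects)
    for (obj in targets) {
      msgs <- rule$predicate(obj, store, ctx)
      for (m in msgs) {
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = obj$id, rule_id = rule$rule_id,
          severity = rule$severity, message = m, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(0), rule_id = character(0),
               severity = character(0), message = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$record_id, out$rule_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("audit_flags", "data.frame")
  out
}

severity_order <- c("error", "not-compliant", "warning", "internal")

#' Render an audit report
#'
#' @param flags an `audit_flags` data.frame from [run_audits()].
#' @param format `"tsv"` (one line per flag, header first, machine
#'   parseable) or `"text"` (grouped by severity, most severe first).
#' @return report text (single string).
#' @export
render_report <- function(flags, format = c("tsv", "text")) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- c(paste(c("record_id", "rule_id", "severity", "message"),
                     collapse = "\t"),
               if (nrow(flags)) {
                 paste(flags$record_id, flags$rule_id, flags$severity,
                       flags$message, sep = "\t")
               })
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  lines <- character(0)
  for (sev in severity_order) {
    sub <- flags[flags$severity == sev, , drop = FALSE]
    if (!nrow(sub)) next
    lines <- c(lines, sprintf("== %s (%d) ==", sev, nrow(sub)),
               sprintf("  %s  %s: %s", sub$record_id, sub$rule_id, sub$message))
  }
  if (!length(lines)) lines <- "no audit flags"
  paste0(paste(lines, collapse = "\n"), "\n")
}
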