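#' Schema documents
#'
#' Each record type (donor, biosample, file, ...) is defined by a schema
#' document: a JSON object naming the type, its properties, which of them
#' are required, conditional dependencies between them, and which fields
#' identify a record uniquely within a store. Only a fixed subset of schema
#' keywords is implemented — `type_name`, `schema_version`, `properties`,
#' `required`, `dependencies`, `identifying_fields` at the top level and
#' `kind`, `enum`, `pattern`, `link_to`, `description` per property —
#' and any unknown keyword is rejected loudly: for a metadata standard a
#' silently ignored constraint is worse than a hard failure.
#'
#' Property kinds are `text`, `integer`, `number`, `boolean`, `list`,
#' `link` and `document-ref`. `enum` and `pattern` apply to text
#' properties; patterns are anchored (full-match), so a partial match can
#' never let a malformed identifier slip through. `link_to` names the
#' target record type and is required for `link`/`document-ref` kinds; on a
#' `list` property it declares a list of links.
#'
#' Dependencies support both forms seen in submission practice: presence of
#' a trigger field, or specific trigger values, requiring further fields
#' and/or forbidding others. The canonical example ships in the `file`
#' schema: a file with `run_type` `"paired-ended"` must name its mate via
#' `paired_with`, so paired files are never separated at submission.
#'
#' @param schema_text schema document as JSON text (or a parsed list).
#' @return an object of class `schema_doc`.
#' @export
load_schema <- function(schema_text) {
  doc <- if (is.character(schema_text)) {
    tryCatch(jsonlite::fromJSON(schema_text, simplifyVector = FALSE),
             error = function(e) mf_stop("schema_parse",
               sprintf("schema does not parse as JSON: %s", conditionMessage(e))))
  } else schema_text
  allowed_top <- c("type_name", "schema_version", "properties", "required",
                   "dependencies", "identifying_fields", "contained_fields")
  unknown <- setdiff(names(doc), allowed_top)
  if (length(unknown)) {
    mf_stop("schema_error",
            sprintf("unknown schema keyword(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  if (!is_scalar_chr(doc$type_name)) {
    mf_stop("schema_error", "schema must carry a scalar 'type_name'")
  }
  props <- doc$properties
  if (is.null(props) || !length(props)) {
    mf_stop("schema_error",
            sprintf("schema '%s' defines no properties", doc$type_name))
  }
  allowed_prop <- c("kind", "enum", "pattern", "link_to", "description")
  kinds <- c("text", "integer", "number", "boolean", "list", "link",
             "document-ref")
  for (nm in names(props)) {
    p <- props[[nm]]
    bad <- setdiff(names(p), allowed_prop)
    if (length(bad)) {
      mf_stop("schema_error",
              sprintf("property '%s' of '%s' has unknown keyword(s): %s",
                      nm, doc$type_name, paste(bad, collapse = ", ")))
    }
    if (is.null(p$kind) || !p$kind %in% kinds) {
      mf_stop("schema_error",
              sprintf("property '%s' of '%s' has missing or unknown kind",
                      nm, doc$type_name))
    }
    if (!is.null(p$enum)) {
      p$enum <- unlist(p$enum, use.names = FALSE)
      if (p$kind != "text") {
        mf_stop("schema_error",
                sprintf("property '%s': enum is only valid for text kind", nm))
      }
      if (!length(p$enum) || anyDuplicated(p$enum)) {
        mf_stop("schema_error",
                sprintf("property '%s': enumerated list must be non-empty and duplicate-free",
                        nm))
      }
    }
    if (!is.null(p$pattern) && p$kind != "text") {
      mf_stop("schema_error",
              sprintf("property '%s': pattern is only valid for text kind", nm))
    }
    if (p$kind %in% c("link", "document-ref")) {
      if (p$kind == "document-ref" && is.null(p$link_to)) p$link_to <- "document"
      if (is.null(p$link_to)) {
        mf_stop("schema_error",
                sprintf("property '%s': link kind requires link_to", nm))
      }
    } else if (!is.null(p$link_to) && p$kind != "list") {
      mf_stop("schema_error",
              sprintf("property '%s': link_to is only valid for link, document-ref or list kinds",
                      nm))
    }
    props[[nm]] <- p
  }
  required <- unlist(doc$required, use.names = FALSE)
  identifying <- unlist(doc$identifying_fields, use.names = FALSE)
  contained <- unlist(doc$contained_fields, use.names = FALSE)
  deps <- doc$dependencies %||% list()
  for (fld in c(required, identifying, contained, names(deps))) {
    if (!fld %in% names(props)) {
      mf_stop("schema_error",
              sprintf("schema '%s' references unknown field '%s'",
                      doc$type_name, fld))
    }
  }
  for (trigger in names(deps)) {
    d <- deps[[trigger]]
    d$trigger_values <- unlist(d$trigger_values, use.names = FALSE)
    d$required_fields <- unlist(d$required_fields, use.names = FALSE)
    d$forbidden_fields <- unlist(d$forbidden_fields, use.names = FALSE)
    bad <- setdiff(names(d), c("trigger_values", "required_fields",
                               "forbidden_fields"))
    if (length(bad)) {
      mf_stop("schema_error",
              sprintf("dependency on '%s' has unknown keyword(s): %s",
                      trigger, paste(bad, collapse = ", ")))
    }
    for (fld in c(d$required_fields, d$forbidden_fields)) {
      if (!fld %in% names(props)) {
        mf_stop("schema_error",
                sprintf("dependency on '%s' names unknown field '%s'",
                        trigger, fld))
      }
    }
    if (length(intersect(d$required_fields, d$forbidden_fields))) {
      mf_stop("schema_error",
              sprintf("dependency on '%s': required and forbidden fields overlap",
                      trigger))
    }
    deps[[trigger]] <- d
  }
  for (fld in contained) {
    if (is.null(props[[fld]]$link_to)) {
      mf_stop("schema_error",
              sprintf("contained field '%s' must be link-valued", fld))
    }
  }
  structure(list(type_name = doc$type_name,
                 schema_version = doc$schema_version %||% 1L,
                 properties = props,
                 required = required %||% character(0),
                 dependencies = deps,
                 identifying_fields = identifying %||% character(0),
                 contained_fields = contained %||% character(0)),
            class = "schema_doc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.schema_doc <- function(x, ...) {
  cat(sprintf("<schema_doc> %s (v%s): %d properties, %d required, %d dependencies\n",
              x$type_name, x$schema_version, length(x$properties),
              length(x$required), length(x$dependencies)))
  invisible(x)
}

#' Schema registry
#'
#' A registry holds one schema per record type. Duplicate type names are
#' rejected, and link targets must resolve to a type registered in the same
#' registry (checked by [check_schema_registry()], since schemas may link
#' mutually, e.g. file to file).
#'
#' @return an empty object of class `schema_registry`.
#' @export
schema_registry <- function() {
  structure(list(schemas = list()), class = "schema_registry")
}

#' @rdname schema_registry
#' @param registry a `schema_registry`.
#' @param schema a [load_schema()] document.
#' @export
register_schema <- function(registry, schema) {
  stopifnot(inherits(registry, "schema_registry"), inherits(schema, "schema_doc"))
  if (schema$type_name %in% names(registry$schemas)) {
    mf_stop("schema_error",
            sprintf("type '%s' is already registered", schema$type_name))
  }
  registry$schemas[[schema$type_name]] <- schema
  registry
}

#' @rdname schema_registry
#' @export
check_schema_registry <- function(registry) {
  for (schema in registry$schemas) {
    for (nm in names(schema$properties)) {
      target <- schema$properties[[nm]]$link_to
      if (!is.null(target) && !target %in% names(registry$schemas)) {
        mf_stop("schema_error",
                sprintf("property '%s' of '%s' links to unregistered type '%s'",
                        nm, schema$type_name, target))
      }
    }
  }
  invisible(registry)
}

#' Load a directory of schema documents
#'
#' One record type per `.json` file. After loading, cross-type link targets
#' are verified. The schema set shipped with the package
#' (`system.file("extdata/schemas", package = "metaforge")`) covers donor,
#' biosample, library, antibody_lot, experiment, replicate, file, pipeline,
#' software, document, treatment, lab and award.
#'
#' @param dir directory of schema JSON files.
#' @return a validated `schema_registry`.
#' @export
load_schema_dir <- function(dir = system.file("extdata/schemas",
                                              package = "metaforge")) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(files)) mf_stop("schema_error", sprintf("no schemas in '%s'", dir))
  registry <- schema_registry()
  for (f in files) {
    registry <- register_schema(registry,
                                load_schema(paste(readLines(f, warn = FALSE),
                                                  collapse = "\n")))
  }
  check_schema_registry(registry)
}

#' Construct a metadata record
#'
#' @param type_name registered record type.
#' @param id accession or local identifier.
#' @param properties named list of field values.
#' @return an object of class `metadata_object`.
#' @export
metadata_object <- function(type_name, id, properties = list()) {
  stopifnot(is_scalar_chr(type_name), is_scalar_chr(id), is.list(properties))
  structure(list(id = id, type_name = type_name, properties = properties),
            class = "metadata_object")
}

#' @export
print.metadata_object <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$type_name, x$id))
  for (nm in names(x$properties)) {
    v <- x$properties[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(utils::head(unlist(v, use.names = FALSE), 6),
                      collapse = ", ")))
  }
  invisible(x)
}

kind_ok <- function(value, kind) {
  switch(kind,
    "text" = is_scalar_chr(value),
    "integer" = (is.numeric(value) && length(value) == 1L &&
                   !is.na(value) && value == as.integer(value)),
    "number" = is.numeric(value) && length(value) == 1L && !is.na(value),
    "boolean" = is.logical(value) && length(value) == 1L && !is.na(value),
    "list" = is.list(value) || (is.vector(value) && is.null(dim(value))),
    "link" = is_scalar_chr(value),
    "document-ref" = is_scalar_chr(value),
    FALSE)
}

#' Validate a record against its schema
#'
#' Every problem is reported, none raised: the returned report carries one
#' row per violation with the offending field, the rule kind (one of
#' `missing-required`, `enum`, `pattern`, `type`, `dependency-required`,
#' `dependency-forbidden`, `bad-link-type`, `unknown-field`) and a message.
#' Partial records are supported — only required fields and fired
#' dependencies force presence. Validation is pure and order-independent:
#' permuting the record's fields yields an identical report.
#'
#' Unknown fields are violations by default (curated strictness);
#' `strict_unknown = FALSE` downgrades them to warnings, which are listed
#' in the report with `level = "warning"` and do not affect validity.
#' Link-target typing (`bad-link-type`) is only checkable against a store;
#' when `store` is `NULL` it is deferred to [check_referential_integrity()].
#'
#' @param schema the record type's `schema_doc`.
#' @param record a [metadata_object()].
#' @param store optionally, a [metadata_store()] used to resolve link
#'   targets.
#' @param strict_unknown treat unknown fields as violations (default) or
#'   warnings.
#' @return an object of class `validation_report`.
#' @export
validate_record <- function(schema, record, store = NULL,
                            strict_unknown = TRUE) {
  stopifnot(inherits(schema, "schema_doc"), inherits(record, "metadata_object"))
  if (schema$type_name != record$type_name) {
    mf_stop("type_mismatch",
            sprintf("record '%s' has type '%s' but schema defines '%s'",
                    record$id, record$type_name, schema$type_name))
  }
  rows <- list()
  add <- function(field, rule, message, level = "violation") {
    rows[[length(rows) + 1L]] <<- data.frame(
      field = field, rule = rule, message = message, level = level,
      stringsAsFactors = FALSE)
  }
  props <- record$properties
  present <- names(props)[!vapply(props, is.null, logical(1))]
  for (fld in schema$required) {
    if (!fld %in% present) {
      add(fld, "missing-required",
          sprintf("required field '%s' is missing", fld))
    }
  }
  for (fld in sort(present)) {
    spec <- schema$properties[[fld]]
    if (is.null(spec)) {
      add(fld, "unknown-field",
          sprintf("field '%s' is not defined by the '%s' schema",
                  fld, schema$type_name),
          level = if (strict_unknown) "violation" else "warning")
      next
    }
    value <- props[[fld]]
    if (!kind_ok(value, spec$kind)) {
      add(fld, "type",
          sprintf("field '%s' must be of kind %s", fld, spec$kind))
      next
    }
    if (!is.null(spec$enum) && !value %in% spec$enum) {
      add(fld, "enum",
          sprintf("value '%s' for '%s' is not in the enumerated list [%s]",
                  value, fld, paste(spec$enum, collapse = ", ")))
    }
    if (!is.null(spec$pattern) &&
        !grepl(paste0("^(?:", spec$pattern, ")$"), value, perl = TRUE)) {
      add(fld, "pattern",
          sprintf("value '%s' for '%s' does not match pattern '%s'",
                  value, fld, spec$pattern))
    }
    if (!is.null(store) && !is.null(spec$link_to)) {
      targets <- unlist(value, use.names = FALSE)
      for (tid in targets) {
        tgt <- store$objects[[tid]]
        if (!is.null(tgt) && tgt$type_name != spec$link_to) {
          add(fld, "bad-link-type",
              sprintf("field '%s' links '%s' of type '%s'; expected '%s'",
                      fld, tid, tgt$type_name, spec$link_to))
        }
      }
    }
  }
  for (trigger in sort(names(schema$dependencies))) {
    d <- schema$dependencies[[trigger]]
    if (!trigger %in% present) next
    if (length(d$trigger_values) &&
        !props[[trigger]] %in% d$trigger_values) next
    for (fld in d$required_fields) {
      if (!fld %in% present) {
        add(fld, "dependency-required",
            sprintf("'%s'='%s' requires field '%s'",
                    trigger, paste(props[[trigger]], collapse = ","), fld))
      }
    }
    for (fld in d$forbidden_fields) {
      if (fld %in% present) {
        add(fld, "dependency-forbidden",
            sprintf("'%s'='%s' forbids field '%s'",
                    trigger, paste(props[[trigger]], collapse = ","), fld))
      }
    }
  }
  violations <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field = character(0), rule = character(0),
               message = character(0), level = character(0),
               stringsAsFactors = FALSE)
  violations <- violations[order(violations$field, violations$rule), ,
                           drop = FALSE]
  rownames(violations) <- NULL
  structure(list(record_id = record$id, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  n <- sum(x$violations$level == "violation")
  cat(sprintf("<validation_report> %s: %s\n", x$record_id,
              if (n == 0L) "valid" else sprintf("%d violation(s)", n)))
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}

#' Is a validation report clean?
#' @param report a `validation_report`.
#' @return `TRUE` iff the report lists no violations (warnings do not count).
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  !any(report$violations$level == "violation")
}
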