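#' Create a metadata store
#'
#' The store holds the linked object graph of a submission stream: donors,
#' biosamples, libraries, antibody lots, replicates, experiments, files,
#' pipelines and their supporting records. Links between records are plain
#' ids; referential integrity is tolerated as incomplete while records are
#' being loaded (partial submissions are a requirement — one biological
#' replicate may arrive before the second is ready) and enforced at
#' [finalize_store()].
#'
#' @param registry a `schema_registry`, typically [load_schema_dir()].
#' @return an object of class `metadata_store`.
#' @export
metadata_store <- function(registry = load_schema_dir()) {
  stopifnot(inherits(registry, "schema_registry"))
  structure(list(schemas = registry, objects = list(), finalized = FALSE),
            class = "metadata_store")
}

#' @export
print.metadata_store <- function(x, ...) {
  types <- vapply(x$objects, `[[`, character(1), "type_name")
  tab <- table(types)
  cat(sprintf("<metadata_store> %d records%s\n", length(x$objects),
              if (x$finalized) " (finalized)" else ""))
  if (length(tab)) {
    cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Add a record to the store
#'
#' The record is validated against its type's schema before insertion
#' (dangling links are allowed at this stage). Duplicate ids and duplicate
#' values of a type's identifying fields are rejected.
#'
#' @param store a [metadata_store()].
#' @param record a [metadata_object()].
#' @param strict_unknown passed to [validate_record()].
#' @return the updated store.
#' @export
add_object <- function(store, record, strict_unknown = TRUE) {
  stopifnot(inherits(store, "metadata_store"),
            inherits(record, "metadata_object"))
  schema <- store$schemas$schemas[[record$type_name]]
  if (is.null(schema)) {
    mf_stop("unknown_type",
            sprintf("no schema registered for type '%s'", record$type_name))
  }
  if (record$id %in% names(store$objects)) {
    mf_stop("duplicate_id", sprintf("id '%s' already present", record$id))
  }
  report <- validate_record(schema, record, strict_unknown = strict_unknown)
  if (!is_valid(report)) {
    mf_stop("invalid_record",
            sprintf("record '%s' fails validation: %s", record$id,
                    paste(report$violations$message[
                      report$violations$level == "violation"],
                      collapse = "; ")),
            report = report)
  }
  for (fld in schema$identifying_fields) {
    if (!has_prop(record, fld)) next
    v <- prop(record, fld)
    for (other in store$objects) {
      if (other$type_name == record$type_name &&
          identical(other$properties[[fld]], v)) {
        mf_stop("duplicate_identifier",
                sprintf("value '%s' of identifying field '%s' already used by '%s'",
                        v, fld, other$id))
      }
    }
  }
  store$objects[[record$id]] <- record
  store$finalized <- FALSE
  store
}

#' Fetch a record by id
#' @param store a [metadata_store()].
#' @param id record id.
#' @return the `metadata_object`, or an error if unknown.
#' @export
get_object <- function(store, id) {
  obj <- store$objects[[id]]
  if (is.null(obj)) mf_stop("unknown_id", sprintf("no record with id '%s'", id))
  obj
}

#' Mark a record deleted
#'
#' Deletion is a status change, never physical removal: accession stability
#' requires that an id stays resolvable (and is never re-issued) once
#' created. Links pointing at a deleted record are reported by
#' [check_referential_integrity()].
#'
#' @param store a [metadata_store()].
#' @param id record id.
#' @return the updated store.
#' @export
delete_object <- function(store, id) {
  obj <- get_object(store, id)
  obj$properties$status <- "deleted"
  store$objects[[id]] <- obj
  store
}

# fields of a schema that hold links, with their targets
link_fields <- function(schema) {
  out <- list()
  for (nm in names(schema$properties)) {
    tgt <- schema$properties[[nm]]$link_to
    if (!is.null(tgt)) out[[nm]] <- tgt
  }
  out
}

#' Check referential integrity
#'
#' Every link-valued property must resolve to an existing, non-deleted
#' record of the schema-declared target type. Findings are reported, not
#' raised.
#'
#' @param store a [metadata_store()].
#' @return data.frame with columns `record_id`, `field`, `target`,
#'   `problem` (`dangling-link` or `mistyped-link`); zero rows iff the
#'   graph is consistent.
#' @export
check_referential_integrity <- function(store) {
  rows <- list()
  for (obj in store$objects) {
    schema <- store$schemas$schemas[[obj$type_name]]
    for (fld in names(link_fields(schema))) {
      if (!has_prop(obj, fld)) next
      targets <- unlist(prop(obj, fld), use.names = FALSE)
      want <- link_fields(schema)[[fld]]
      for (tid in targets) {
        tgt <- store$objects[[tid]]
        if (is.null(tgt) ||
            identical(tgt$properties$status, "deleted")) {
          rows[[length(rows) + 1L]] <- data.frame(
            record_id = obj$id, field = fld, target = tid,
            problem = "dangling-link", stringsAsFactors = FALSE)
        } else if (tgt$type_name != want) {
          rows[[length(rows) + 1L]] <- data.frame(
            record_id = obj$id, field = fld, target = tid,
            problem = "mistyped-link", stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(0), field = character(0),
               target = character(0), problem = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$record_id, out$field, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Finalize a store
#'
#' Finalization turns a load-in-progress into a consistent released graph:
#' one-sided `paired_with` declarations are auto-completed (if file a
#' names b, b gains the back-reference), referential integrity is
#' enforced, replicate (biological, technical) number pairs must be unique
#' within each experiment, and the `derived_from` graph must be acyclic.
#'
#' @param store a [metadata_store()].
#' @return the finalized store.
#' @export
finalize_store <- function(store) {
  # complete paired_with symmetry before integrity is enforced
  for (id in names(store$objects)) {
    obj <- store$objects[[id]]
    if (obj$type_name != "file" || !has_prop(obj, "paired_with")) next
    mate_id <- prop(obj, "paired_with")
    mate <- store$objects[[mate_id]]
    if (!is.null(mate) && !has_prop(mate, "paired_with")) {
      mate$properties$paired_with <- id
      store$objects[[mate_id]] <- mate
    }
  }
  # materialize reverse links: an experiment accession refers to its
  # replicates as a group, so experiments carry a `replicates` list kept in
  # step with the replicate -> experiment links (single source of truth)
  rep_by_exp <- list()
  for (obj in store$objects) {
    if (obj$type_name != "replicate") next
    exp_id <- prop(obj, "experiment")
    if (!is.null(exp_id)) {
      rep_by_exp[[exp_id]] <- c(rep_by_exp[[exp_id]], obj$id)
    }
  }
  for (id in names(store$objects)) {
    obj <- store$objects[[id]]
    if (obj$type_name != "experiment") next
    reps <- sort(rep_by_exp[[id]] %||% character(0))
    if (length(reps)) obj$properties$replicates <- as.list(reps)
    else obj$properties$replicates <- NULL
    store$objects[[id]] <- obj
  }
  findings <- check_referential_integrity(store)
  if (nrow(findings)) {
    mf_stop("integrity_error",
            sprintf("store has %d unresolved link(s), e.g. %s.%s -> %s",
                    nrow(findings), findings$record_id[1], findings$field[1],
                    findings$target[1]),
            findings = findings)
  }
  # replicate number uniqueness per experiment
  reps <- Filter(function(o) o$type_name == "replicate", store$objects)
  key <- vapply(reps, function(r) {
    paste(prop(r, "experiment"),
          prop(r, "biological_replicate_number"),
          prop(r, "technical_replicate_number"), sep = "/")
  }, character(1))
  if (anyDuplicated(key)) {
    mf_stop("replicate_clash",
            sprintf("duplicate (biological, technical) replicate numbers: %s",
                    key[duplicated(key)][1]))
  }
  # derived_from must form a DAG
  edges <- derived_from_edges(store)
  if (nrow(edges)) {
    verts <- sort(unique(c(edges$child, edges$parent)))
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = verts)
    if (!igraph::is_dag(g)) {
      mf_stop("provenance_cycle", "derived_from relationships contain a cycle")
    }
  }
  store$finalized <- TRUE
  store
}

derived_from_edges <- function(store) {
  rows <- list()
  for (obj in store$objects) {
    if (obj$type_name != "file" || !has_prop(obj, "derived_from")) next
    parents <- unlist(prop(obj, "derived_from"), use.names = FALSE)
    if (length(parents)) {
      rows[[length(rows) + 1L]] <- data.frame(
        child = obj$id, parent = parents, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(child = character(0), parent = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify the replicate pairs of an experiment
#'
#' Technical replicates are different libraries prepared from the same
#' biosample; biological replicates use distinct biosamples, and are
#' isogenic when those biosamples come from the same donor (or strain) and
#' anisogenic when the donors differ. Every unordered replicate pair of
#' the experiment is classified; the classification is symmetric and
#' independent of replicate ordering.
#'
#' @param store a [metadata_store()].
#' @param experiment_id experiment accession.
#' @return data.frame with columns `replicate_a`, `replicate_b`, `class`
#'   (`technical`, `isogenic-biological` or `anisogenic-biological`).
#' @export
classify_replicates <- function(store, experiment_id) {
  get_object(store, experiment_id)
  reps <- Filter(function(o) o$type_name == "replicate" &&
                   identical(prop(o, "experiment"), experiment_id),
                 store$objects)
  reps <- reps[order(names(reps))]
  chain <- lapply(reps, function(r) {
    lib_id <- prop(r, "library")
    if (is.null(lib_id)) {
      mf_stop("unresolvable_chain",
              sprintf("replicate '%s' has no library", r$id))
    }
    lib <- store$objects[[lib_id]]
    if (is.null(lib)) {
      mf_stop("unresolvable_chain",
              sprintf("library '%s' not in store", lib_id))
    }
    bio_id <- prop(lib, "biosample")
    bio <- if (!is.null(bio_id)) store$objects[[bio_id]] else NULL
    if (is.null(bio)) {
      mf_stop("unresolvable_chain",
              sprintf("library '%s' has no resolvable biosample", lib_id))
    }
    donor <- prop(bio, "donor")
    if (is.null(donor)) {
      mf_stop("unresolvable_chain",
              sprintf("biosample '%s' has no donor", bio_id))
    }
    list(biosample = bio_id, donor = donor)
  })
  ids <- names(reps)
  rows <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        a <- chain[[i]]; b <- chain[[j]]
        cls <- if (a$biosample == b$biosample) "technical"
          else if (a$donor == b$donor) "isogenic-biological"
          else "anisogenic-biological"
        rows[[length(rows) + 1L]] <- data.frame(
          replicate_a = ids[i], replicate_b = ids[j], class = cls,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicate_a = character(0), replicate_b = character(0),
               class = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' File provenance chain
#'
#' All transitive `derived_from` ancestors of a file, nearest first, in a
#' topological order (a file always precedes its own inputs). Ordering is
#' by longest-path distance from the query file — which is topological on
#' a DAG — with ties broken by id. Raw files (empty `derived_from`) return
#' an empty chain. A cycle anywhere on the ancestor paths raises a
#' provenance-cycle error naming the cycle.
#'
#' @param store a [metadata_store()].
#' @param file_id file accession.
#' @return character vector of ancestor file ids.
#' @export
provenance_chain <- function(store, file_id) {
  get_object(store, file_id)
  seen <- new.env(parent = emptyenv())
  on_stack <- character(0)
  walk <- function(id) {
    if (!is.null(seen[[id]])) return(invisible())
    if (id %in% on_stack) {
      cyc <- c(on_stack[seq(match(id, on_stack), length(on_stack))], id)
      mf_stop("provenance_cycle",
              sprintf("derived_from cycle: %s", paste(cyc, collapse = " -> ")))
    }
    on_stack <<- c(on_stack, id)
    obj <- store$objects[[id]]
    parents <- if (!is.null(obj) && has_prop(obj, "derived_from"))
      unlist(prop(obj, "derived_from"), use.names = FALSE) else character(0)
    for (p in parents) walk(p)
    on_stack <<- utils::head(on_stack, -1L)
    seen[[id]] <- TRUE
    invisible()
  }
  walk(file_id)
  ancestors <- setdiff(ls(seen), file_id)
  if (!length(ancestors)) return(character(0))
  # rank = longest-path distance from the query file; ordering by rank is
  # topological on a DAG (an edge always increases rank by at least 1)
  ranks <- stats::setNames(rep(-Inf, length(ancestors) + 1L),
                           c(file_id, ancestors))
  ranks[file_id] <- 0
  # relax edges repeatedly; |V| passes suffice on a DAG
  for (pass in seq_len(length(ranks))) {
    changed <- FALSE
    for (id in names(ranks)) {
      obj <- store$objects[[id]]
      parents <- if (!is.null(obj) && has_prop(obj, "derived_from"))
        unlist(prop(obj, "derived_from"), use.names = FALSE) else character(0)
      for (p in parents) {
        cand <- ranks[id] + 1
        if (cand > ranks[p]) { ranks[p] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  ord <- ranks[ancestors]
  ancestors[order(ord, ancestors)]
}

#' Embed a record's links as nested documents
#'
#' Link fields are replaced by embedded copies of their targets up to
#' `depth` (default 3 — enough to reach the donor from an experiment
#' through replicate, library and biosample); beyond the depth, links stay
#' ids. Cyclic back-references terminate: a record already visited on the
#' current path embeds as its bare id. Embedding is a pure function of
#' (store, id, depth): a record reached twice through different paths
#' embeds identically.
#'
#' @param store a [metadata_store()].
#' @param id record id.
#' @param depth non-negative embedding depth.
#' @return a named list: the record's properties plus `id` and
#'   `type_name`, with links expanded.
#' @export
embed_object <- function(store, id, depth = 3L) {
  embed_walk(store, id, depth, visited = character(0))
}

embed_walk <- function(store, id, depth, visited) {
  obj <- get_object(store, id)
  out <- c(list(id = obj$id, type_name = obj$type_name), obj$properties)
  if (depth <= 0L) return(out)
  schema <- store$schemas$schemas[[obj$type_name]]
  lf <- link_fields(schema)
  for (fld in names(lf)) {
    if (!has_prop(obj, fld)) next
    value <- obj$properties[[fld]]
    is_list_kind <- schema$properties[[fld]]$kind == "list"
    # contained fields (e.g. an experiment's replicates) are structural
    # parts of the record, not independent hops: they embed at the same
    # depth, so depth 3 reaches the donor from an experiment through
    # replicate -> library -> biosample -> donor
    child_depth <- if (fld %in% schema$contained_fields) depth else depth - 1L
    targets <- unlist(value, use.names = FALSE)
    embedded <- lapply(targets, function(tid) {
      if (tid %in% c(visited, id) || is.null(store$objects[[tid]])) {
        tid                      # cycle guard / dangling: keep bare id
      } else {
        embed_walk(store, tid, child_depth, c(visited, id))
      }
    })
    out[[fld]] <- if (is_list_kind) embedded else embedded[[1]]
  }
  out
}

#' Serialize / load a store
#'
#' Two on-disk dialects are supported: a single JSON document mapping each
#' type name to its list of records, or a directory with one JSON file per
#' type. Records are written sorted by type then id so serialization is
#' byte-stable.
#'
#' @param store a [metadata_store()].
#' @param path output `.json` file, or a directory (created) for the
#'   per-type dialect.
#' @param dialect `"single"` or `"dir"`.
#' @return `write_store` returns `path` invisibly.
#' @export
write_store <- function(store, path, dialect = c("single", "dir")) {
  dialect <- match.arg(dialect)
  types <- sort(unique(vapply(store$objects, `[[`, character(1), "type_name")))
  by_type <- lapply(types, function(tp) {
    objs <- Filter(function(o) o$type_name == tp, store$objects)
    objs <- objs[order(names(objs))]
    unname(lapply(objs, function(o) c(list(id = o$id), o$properties)))
  })
  names(by_type) <- types
  if (dialect == "single") {
    jsonlite::write_json(by_type, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (tp in types) {
      jsonlite::write_json(by_type[[tp]], file.path(path, paste0(tp, ".json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }
  invisible(path)
}

#' @rdname write_store
#' @param registry schema registry used to type records on load.
#' @param finalize finalize after loading.
#' @export
read_store <- function(path, registry = load_schema_dir(), finalize = FALSE) {
  store <- metadata_store(registry)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    docs <- lapply(files, jsonlite::read_json)
    names(docs) <- sub("\\.json$", "", basename(files))
  } else {
    docs <- jsonlite::read_json(path)
  }
  for (tp in names(docs)) {
    for (rec in docs[[tp]]) {
      id <- rec$id
      rec$id <- NULL
      store <- add_object(store, metadata_object(tp, id, rec))
    }
  }
  if (finalize) store <- finalize_store(store)
  store
}
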