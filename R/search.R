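#' Tokenize text for indexing and querying
#'
#' Lowercase, split on non-alphanumerics, drop empties. Accessions survive
#' as single tokens because they are purely alphanumeric. No stemming: the
#' vocabulary is curated, and stemming curated terms invites false merges.
#'
#' @param x character vector.
#' @return character vector of tokens.
#' @export
tokenize <- function(x) {
  toks <- unlist(strsplit(tolower(x), "[^a-z0-9]+"), use.names = FALSE)
  toks[nzchar(toks)]
}

# all character leaves of a nested (embedded) document
text_leaves <- function(doc) {
  if (is.character(doc)) return(doc)
  if (is.list(doc)) {
    return(unlist(lapply(doc, text_leaves), use.names = FALSE))
  }
  character(0)
}

# values at a field path inside an embedded document. A dotted path is an
# exact descent (through list-of-documents nodes); a bare field name is
# gathered recursively anywhere in the document, matching how faceted
# metadata is drawn from the flattened embedded record.
path_values <- function(doc, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    vals <- gather_by_key(doc, parts)
    return(unique(vals))
  }
  cur <- list(doc)
  for (p in parts) {
    nxt <- list()
    for (node in cur) {
      if (!is.list(node)) next
      if (!is.null(names(node)) && p %in% names(node)) {
        nxt[[length(nxt) + 1L]] <- node[[p]]
      } else if (is.null(names(node))) {
        for (el in node) {
          if (is.list(el) && p %in% names(el)) {
            nxt[[length(nxt) + 1L]] <- el[[p]]
          }
        }
      }
    }
    cur <- nxt
  }
  vals <- unlist(lapply(cur, function(v)
    if (is.atomic(v)) as.character(v) else
      unlist(Filter(is.character, v), use.names = FALSE)),
    use.names = FALSE)
  unique(vals)
}

gather_by_key <- function(doc, key) {
  if (!is.list(doc)) return(character(0))
  out <- character(0)
  if (!is.null(names(doc)) && key %in% names(doc)) {
    v <- doc[[key]]
    if (is.atomic(v)) out <- c(out, as.character(v))
    else out <- c(out, unlist(Filter(function(e) is.atomic(e), v),
                              use.names = FALSE))
  }
  for (el in doc) {
    if (is.list(el)) out <- c(out, gather_by_key(el, key))
  }
  out
}

# term CURIEs found at the slim-config fields of an embedded document
annotated_terms <- function(doc, term_fields) {
  unique(unlist(lapply(term_fields, function(f) path_values(doc, f)),
                use.names = FALSE))
}

#' Build a keyword index with ontology expansion
#'
#' Each record of the indexed types is embedded to `embed_depth` and every
#' text field of the embedded document is tokenized into the postings. When
#' a slim configuration is given, the names of the slim terms matched by
#' the record's annotated ontology terms — plus those terms' synonyms —
#' are indexed too: that is how a query for "skin" reaches experiments
#' whose biosample is a keratinocyte even though no stored field contains
#' the string "skin". Facet values are captured per record for
#' [facet_counts()].
#'
#' @param store a finalized [metadata_store()].
#' @param embed_depth embedding depth for indexing (default 3).
#' @param facet_fields character vector of dotted field paths registered
#'   as facets; each must exist as a property somewhere in the schema set.
#' @param slim_config `NULL`, or a list with `ontology` (an [load_ontology()]
#'   bundle), `term_fields` (dotted paths holding CURIEs) and `slims`
#'   (character vector of slim term ids).
#' @param types record types to index (default experiments).
#' @return an object of class `search_index`.
#' @export
build_index <- function(store, embed_depth = 3L,
                        facet_fields = character(0), slim_config = NULL,
                        types = "experiment") {
  stopifnot(inherits(store, "metadata_store"))
  all_props <- unique(unlist(lapply(store$schemas$schemas,
                                    function(s) names(s$properties))))
  for (ff in facet_fields) {
    leaf <- utils::tail(strsplit(ff, ".", fixed = TRUE)[[1]], 1L)
    if (!leaf %in% all_props) {
      mf_stop("unknown_facet_field",
              sprintf("facet field path '%s' names no schema property", ff))
    }
  }
  ids <- sort(names(store$objects)[
    vapply(store$objects, function(o) o$type_name %in% types, logical(1))])
  postings <- new.env(parent = emptyenv())
  facet_values <- lapply(facet_fields, function(...) list())
  names(facet_values) <- facet_fields
  slim_annotations <- list()
  for (id in ids) {
    doc <- embed_object(store, id, depth = embed_depth)
    toks <- tokenize(text_leaves(doc))
    if (!is.null(slim_config)) {
      terms <- annotated_terms(doc, slim_config$term_fields)
      terms <- intersect(terms, names(slim_config$ontology))
      slims <- unique(unlist(lapply(terms, function(t)
        slim_terms(slim_config$ontology, t, slim_config$slims)),
        use.names = FALSE))
      slim_names <- vapply(slims, function(t)
        slim_config$ontology[[t]]$name, character(1))
      syns <- unlist(lapply(terms, function(t)
        slim_config$ontology[[t]]$synonyms), use.names = FALSE)
      slim_annotations[[id]] <- unname(slim_names)
      toks <- c(toks, tokenize(c(slim_names, syns)))
    }
    counts <- table(toks)
    for (tok in names(counts)) {
      cur <- postings[[tok]]
      if (is.null(cur)) cur <- integer(0)
      cur[id] <- as.integer(counts[[tok]])
      postings[[tok]] <- cur
    }
    for (ff in facet_fields) {
      facet_values[[ff]][[id]] <- path_values(doc, ff)
    }
  }
  structure(list(postings = postings, record_ids = ids,
                 facet_fields = facet_fields, facet_values = facet_values,
                 slim_annotations = slim_annotations),
            class = "search_index")
}

#' @export
print.search_index <- function(x, ...) {
  cat(sprintf("<search_index> %d records, %d tokens, %d facet field(s)\n",
              length(x$record_ids), length(ls(x$postings)),
              length(x$facet_fields)))
  invisible(x)
}

#' Keyword search
#'
#' Multi-token queries use intersection semantics: a record must match
#' every query token. Results are ranked by total match count (summed
#' token frequencies), ties broken by record id, so ranking is stable.
#'
#' @param index a [build_index()] result.
#' @param query_text free-text query.
#' @return character vector of matching record ids, ranked; empty query
#'   yields no results.
#' @export
keyword_search <- function(index, query_text) {
  stopifnot(inherits(index, "search_index"))
  toks <- unique(tokenize(query_text))
  if (!length(toks)) return(character(0))
  per_token <- lapply(toks, function(tok) {
    p <- index$postings[[tok]]
    if (is.null(p)) integer(0) else p
  })
  hit_ids <- Reduce(intersect, lapply(per_token, names))
  if (!length(hit_ids)) return(character(0))
  score <- vapply(hit_ids, function(id)
    sum(vapply(per_token, function(p) p[[id]], integer(1))), integer(1))
  hit_ids[order(-score, hit_ids)]
}

#' Facet counts over a result set
#'
#' Counts field values over the given results only — the semantics of
#' faceted browsing, where filters narrow the current result set. For a
#' single-valued field the counts sum to the number of results carrying
#' the field; multi-valued fields contribute one count per value.
#'
#' @param index a [build_index()] result.
#' @param result_ids record ids (e.g. from [keyword_search()]).
#' @param facet_field a facet field registered at [build_index()] time.
#' @return named integer vector (value -> count), decreasing count then
#'   value order; empty for an empty result set.
#' @export
facet_counts <- function(index, result_ids, facet_field) {
  stopifnot(inherits(index, "search_index"))
  if (!facet_field %in% index$facet_fields) {
    mf_stop("unknown_facet_field",
            sprintf("facet field '%s' is not registered on this index",
                    facet_field))
  }
  vals <- unlist(lapply(result_ids, function(id)
    unique(index$facet_values[[facet_field]][[id]])), use.names = FALSE)
  if (!length(vals)) return(stats::setNames(integer(0), character(0)))
  tab <- table(vals)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts[order(-counts, names(counts))]
}
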