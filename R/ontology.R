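#' Load an ontology slice in OBO subset syntax
#'
#' Controlled vocabularies come from small slices of the standard
#' ontologies: UBERON for tissues, CL for primary cell types, EFO for
#' immortalized cell lines, OBI for assay names and ChEBI for biosample
#' treatments. Only a subset of OBO is parsed — `[Term]` stanzas with
#' `id`, `name`, `is_a`, `relationship: part_of` and `synonym` lines —
#' which is all the term graph needs for validation and search expansion.
#' Edge labels (`is_a` vs `part_of`) are preserved so traversal can be
#' restricted later. The parent graph must be acyclic and all parents must
#' resolve within the loaded bundle.
#'
#' @param text OBO text (single string or character vector of lines).
#' @return an object of class `ontology`: a named list of terms, each with
#'   `id`, `name`, `namespace` (the CURIE prefix), `parents`
#'   (data.frame of `parent`, `rel`) and `synonyms`.
#' @export
load_ontology <- function(text) {
  ont <- structure(parse_obo(text), class = "ontology")
  check_ontology(ont)
  ont
}

# stanza parser; graph checks happen separately so bundle files with
# cross-file parents can be merged before resolution is enforced
parse_obo <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (is.null(cur)) return(terms)
    if (is.null(cur$id)) mf_stop("obo_parse", "[Term] stanza without an id")
    if (cur$id %in% names(terms)) {
      mf_stop("duplicate_term",
              sprintf("duplicate term id '%s'", cur$id))
    }
    cur$namespace <- sub(":.*$", "", cur$id)
    cur$parents <- if (length(cur$parent_ids)) {
      data.frame(parent = cur$parent_ids, rel = cur$parent_rels,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(parent = character(0), rel = character(0),
                 stringsAsFactors = FALSE)
    }
    terms[[cur$id]] <- cur[c("id", "name", "namespace", "parents", "synonyms")]
    terms
  }
  in_term <- FALSE
  for (line in lines) {
    line <- trimws(line)
    if (line == "" || startsWith(line, "!")) next
    if (line == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NULL, name = NA_character_,
                  parent_ids = character(0), parent_rels = character(0),
                  synonyms = character(0))
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", line)) {          # [Typedef] etc: skip stanza
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term) next
    strip_cmt <- function(x) trimws(sub(" *!.*$", "", x))
    if (startsWith(line, "id:")) {
      cur$id <- strip_cmt(sub("^id: *", "", line))
    } else if (startsWith(line, "name:")) {
      cur$name <- trimws(sub("^name: *", "", line))
    } else if (startsWith(line, "is_a:")) {
      cur$parent_ids <- c(cur$parent_ids, strip_cmt(sub("^is_a: *", "", line)))
      cur$parent_rels <- c(cur$parent_rels, "is_a")
    } else if (grepl("^relationship: *part_of ", line)) {
      cur$parent_ids <- c(cur$parent_ids,
                          strip_cmt(sub("^relationship: *part_of *", "", line)))
      cur$parent_rels <- c(cur$parent_rels, "part_of")
    } else if (startsWith(line, "synonym:")) {
      m <- regmatches(line, regexpr('"[^"]*"', line))
      if (length(m)) {
        cur$synonyms <- c(cur$synonyms, gsub('"', "", m))
      }
    }
    # other tag lines (def:, xref:, ...) are ignored: not part of the subset
  }
  flush(cur, terms)
}

check_ontology <- function(ont) {
  ids <- names(ont)
  edges <- ontology_edges(ont)
  dangling <- setdiff(edges$parent, ids)
  if (length(dangling)) {
    mf_stop("dangling_parent",
            sprintf("parent term(s) not in bundle: %s",
                    paste(sort(dangling), collapse = ", ")))
  }
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE,
                                       vertices = sort(ids))
    if (!igraph::is_dag(g)) {
      mf_stop("ontology_cycle", "ontology parent graph contains a cycle")
    }
  }
  invisible(ont)
}

ontology_edges <- function(ont) {
  rows <- lapply(ont, function(t) {
    if (!nrow(t$parents)) return(NULL)
    data.frame(child = t$id, parent = t$parents$parent, rel = t$parents$rel,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(child = character(0), parent = character(0),
                      rel = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @export
print.ontology <- function(x, ...) {
  ns <- table(vapply(x, `[[`, character(1), "namespace"))
  cat(sprintf("<ontology> %d terms (%s)\n", length(x),
              paste(sprintf("%s: %d", names(ns), ns), collapse = ", ")))
  invisible(x)
}

#' Load an ontology bundle directory
#'
#' One `.obo` file per namespace; all files are merged into a single term
#' graph before acyclicity and parent resolution are checked, since terms
#' may have cross-namespace parents (a CL cell type can be `part_of` an
#' UBERON structure).
#'
#' @param dir bundle directory; defaults to the toy slices shipped with the
#'   package.
#' @return an `ontology`.
#' @export
load_ontology_dir <- function(dir = system.file("extdata/ontology",
                                                package = "metaforge")) {
  files <- sort(list.files(dir, pattern = "\\.obo$", full.names = TRUE))
  if (!length(files)) mf_stop("obo_parse", sprintf("no .obo files in '%s'", dir))
  terms <- list()
  for (f in files) {
    part <- parse_obo(readLines(f, warn = FALSE))
    dup <- intersect(names(part), names(terms))
    if (length(dup)) {
      mf_stop("duplicate_term",
              sprintf("duplicate term id(s) across bundle: %s",
                      paste(dup, collapse = ", ")))
    }
    terms <- c(terms, part)
  }
  ont <- structure(terms, class = "ontology")
  check_ontology(ont)
  ont
}

#' Ancestors of a term
#'
#' Transitive closure over the labelled parent edges, excluding the term
#' itself. By default both `is_a` and `part_of` edges are traversed — that
#' is what lets an anatomical search term group cell types located in that
#' structure (keratinocyte, part of the skin epidermis, part of the skin
#' of body, is reached from "skin of body").
#'
#' @param ont an `ontology`.
#' @param term_id CURIE of the start term.
#' @param rels edge labels to traverse.
#' @return character vector of ancestor term ids (sorted).
#' @export
ancestors <- function(ont, term_id, rels = c("is_a", "part_of")) {
  if (!term_id %in% names(ont)) {
    mf_stop("unknown_term", sprintf("unknown term '%s'", term_id))
  }
  seen <- character(0)
  frontier <- term_id
  while (length(frontier)) {
    parents <- unlist(lapply(frontier, function(id) {
      p <- ont[[id]]$parents
      p$parent[p$rel %in% rels]
    }), use.names = FALSE)
    frontier <- setdiff(parents, c(seen, term_id))
    seen <- union(seen, frontier)
  }
  sort(seen)
}

#' Slim assignment for a term
#'
#' A slim is a small curated set of high-level terms; a record annotated
#' with a term is assigned the slims among the term's ancestors (and the
#' term itself, when the term is in the slim set). This is what lets a
#' "skin" facet group keratinocyte assays.
#'
#' @param ont an `ontology`.
#' @param term_id annotated term.
#' @param slim_set character vector of slim term ids (must be loaded).
#' @param rels edge labels to traverse.
#' @return the matched slim ids (sorted).
#' @export
slim_terms <- function(ont, term_id, slim_set, rels = c("is_a", "part_of")) {
  missing <- setdiff(slim_set, names(ont))
  if (length(missing)) {
    mf_stop("unknown_term",
            sprintf("slim term(s) not loaded: %s", paste(missing, collapse = ", ")))
  }
  sort(intersect(c(term_id, ancestors(ont, term_id, rels)), slim_set))
}

#' Term-usage constraints
#'
#' Maps (record type, field) to the ontology namespaces allowed there:
#' tissues are UBERON terms, primary cell types CL, immortalized cell
#' lines EFO, assay names OBI and treatments ChEBI.
#'
#' @return data.frame with columns `type_name`, `field`, `namespaces`
#'   (comma-separated).
#' @export
default_term_constraints <- function() {
  data.frame(
    type_name = c("biosample", "biosample", "biosample", "experiment",
                  "treatment"),
    field = c("tissue_term_id", "cell_term_id", "cell_line_term_id",
              "assay_term_id", "treatment_term_id"),
    namespaces = c("UBERON", "CL", "EFO", "OBI", "CHEBI"),
    stringsAsFactors = FALSE)
}

#' Validate a term id against field constraints
#'
#' @param constraints a constraint table, see [default_term_constraints()].
#' @param ont loaded `ontology` bundle.
#' @param type_name,field where the term is used.
#' @param term_id the CURIE to check.
#' @return a list with `ok` (logical) and, when not ok, `violation`
#'   (`"unknown-term"` or `"namespace"`) and `message`.
#' @export
validate_term <- function(constraints, ont, type_name, field, term_id) {
  row <- constraints[constraints$type_name == type_name &
                       constraints$field == field, , drop = FALSE]
  if (!nrow(row)) {
    mf_stop("unknown_constraint",
            sprintf("no term constraint registered for %s.%s", type_name, field))
  }
  if (!term_id %in% names(ont)) {
    return(list(ok = FALSE, violation = "unknown-term",
                message = sprintf("term '%s' is not in the loaded bundle",
                                  term_id)))
  }
  allowed <- strsplit(row$namespaces[1], ",", fixed = TRUE)[[1]]
  ns <- ont[[term_id]]$namespace
  if (!ns %in% allowed) {
    return(list(ok = FALSE, violation = "namespace",
                message = sprintf("%s.%s requires namespace(s) %s; '%s' is %s",
                                  type_name, field, row$namespaces[1],
                                  term_id, ns)))
  }
  list(ok = TRUE)
}
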