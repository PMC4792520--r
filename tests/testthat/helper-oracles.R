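# Independent brute-force oracles used across the suite. They are kept
# deliberately naive (repeated edge expansion, exhaustive enumeration) and
# share no code with the package internals they check.

# reflexive-free transitive closure by repeated edge relaxation:
# edges is a data.frame(from, to); returns a named list node -> reachable set
brute_closure <- function(edges, nodes) {
  reach <- lapply(stats::setNames(nodes, nodes), function(n)
    unique(edges$to[edges$from == n]))
  repeat {
    changed <- FALSE
    for (n in nodes) {
      expanded <- unique(c(reach[[n]],
                           unlist(reach[reach[[n]]], use.names = FALSE)))
      if (length(expanded) > length(reach[[n]])) {
        reach[[n]] <- expanded
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(reach, function(r) sort(setdiff(r, character(0))))
}

# random DAG on n nodes: edges only from higher to lower topological index,
# so acyclicity holds by construction
random_dag <- function(n, p = 0.15, labels = sprintf("n%02d", seq_len(n))) {
  from <- character(0); to <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (stats::runif(1) < p) {
        from <- c(from, labels[i]); to <- c(to, labels[j])
      }
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

# brute-force dependency semantics: given presence/values of fields, does
# the rule (trigger, trigger_values, required, forbidden) flag?
brute_dependency_flags <- function(record_fields, trigger, trigger_values,
                                   required_fields, forbidden_fields) {
  present <- names(record_fields)
  if (!trigger %in% present) return(character(0))
  if (length(trigger_values) &&
      !record_fields[[trigger]] %in% trigger_values) return(character(0))
  c(setdiff(required_fields, present),
    intersect(forbidden_fields, present))
}

# minimal schema registry with only a "file"-like type, for store tests
# that should not depend on the shipped schema set
toy_registry <- function() {
  reg <- schema_registry()
  reg <- register_schema(reg, load_schema('{
    "type_name": "file",
    "properties": {
      "derived_from": {"kind": "list", "link_to": "file"},
      "label": {"kind": "text"},
      "status": {"kind": "text"}
    }
  }'))
  check_schema_registry(reg)
}

# store holding an arbitrary derived_from DAG over "file" records
dag_store <- function(edges, nodes) {
  store <- metadata_store(toy_registry())
  for (n in sort(nodes)) {
    parents <- edges$to[edges$from == n]
    props <- list(label = n)
    if (length(parents)) props$derived_from <- as.list(sort(parents))
    store <- add_object(store, metadata_object("file", n, props))
  }
  store
}

# small hand-built consortium around one experiment; biosample/donor layout
# is configurable so replicate classification cases are easy to express
mini_experiment_store <- function(n_donors = 2, biosample_of_rep = c(1, 2),
                                  donor_of_biosample = c(1, 2),
                                  assay = "ChIP-seq") {
  reg <- load_schema_dir()
  store <- metadata_store(reg)
  assay_id <- if (assay == "ChIP-seq") "OBI:0000716" else "OBI:0001271"
  for (d in seq_len(n_donors)) {
    store <- add_object(store, metadata_object("donor", sprintf("don%d", d),
      list(organism = "human")))
  }
  n_bios <- max(biosample_of_rep)
  for (b in seq_len(n_bios)) {
    store <- add_object(store, metadata_object("biosample", sprintf("bio%d", b),
      list(biosample_term_name = "keratinocyte",
           cell_term_id = "CL:0000312",
           donor = sprintf("don%d", donor_of_biosample[b]))))
  }
  store <- add_object(store, metadata_object("experiment", "exp1",
    list(assay_term_id = assay_id, assay_term_name = assay)))
  for (r in seq_along(biosample_of_rep)) {
    store <- add_object(store, metadata_object("library", sprintf("lib%d", r),
      list(biosample = sprintf("bio%d", biosample_of_rep[r]),
           nucleic_acid_term_name = "DNA")))
    store <- add_object(store, metadata_object("replicate", sprintf("rep%d", r),
      list(experiment = "exp1", library = sprintf("lib%d", r),
           biological_replicate_number = r,
           technical_replicate_number = 1L)))
  }
  finalize_store(store)
}
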