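#' @keywords internal
"_PACKAGE"

# Classed condition constructor so callers can test errors by class
# (e.g. "metaforge_malformed_accession") rather than by message text.
mf_error <- function(class, message, ...) {
  structure(
    class = c(paste0("metaforge_", class), "metaforge_error", "error", "condition"),
    list(message = message, ...)
  )
}

mf_stop <- function(class, message, ...) stop(mf_error(class, message, ...))

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Pull a property off a record; NULL when absent.
prop <- function(record, name) record$properties[[name]]

has_prop <- function(record, name) {
  v <- record$properties[[name]]
  !is.null(v) && !(length(v) == 0L)
}

# Evaluate an expression with the global RNG seeded, restoring prior state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic 32-char lowercase hex string from the current RNG stream.
random_md5 <- function() {
  paste(sprintf("%x", sample(0:15, 32L, replace = TRUE)), collapse = "")
}
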