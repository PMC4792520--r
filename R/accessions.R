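#' Accession grammar
#'
#' Accessions follow a fixed grammar: a constant prefix, a two-letter entity
#' type code, a run of decimal digits and a run of uppercase letters. The
#' production grammar is `ENC(SR|BS|DO|AB|LB|FF)[0-9]{3}[A-Z]{3}` — eleven
#' uppercase characters — giving 10^3 x 26^3 = 17,576,000 distinct serials
#' per entity type. Reduced grammars (fewer digit/letter positions) are
#' supported so that properties such as exhaustion can be exercised on an
#' enumerable space.
#'
#' @param prefix constant prefix, default `"ENC"`.
#' @param type_codes named character vector mapping type code to entity
#'   category. The default carries the fixed mapping: SR = experiment,
#'   BS = biosample, DO = donor/strain, AB = antibody lot, LB = library,
#'   FF = file.
#' @param n_digits,n_letters number of decimal-digit and uppercase-letter
#'   positions in the serial.
#' @return an object of class `accession_grammar`.
#' @export
#' @examples
#' g <- accession_grammar()
#' accession_capacity("SR", g)
accession_grammar <- function(prefix = "ENC",
                              type_codes = c(SR = "experiment",
                                             BS = "biosample",
                                             DO = "donor",
                                             AB = "antibody lot",
                                             LB = "library",
                                             FF = "file"),
                              n_digits = 3L, n_letters = 3L) {
  stopifnot(is_scalar_chr(prefix), length(type_codes) >= 1L,
            n_digits >= 1L, n_letters >= 1L)
  structure(list(prefix = prefix, type_codes = type_codes,
                 n_digits = as.integer(n_digits),
                 n_letters = as.integer(n_letters)),
            class = "accession_grammar")
}

#' Number of distinct accessions available per entity type
#'
#' For the production grammar this is 10^3 x 26^3 = 17,576,000 — comfortably
#' more than seventeen million identifiers per entity type.
#'
#' @param type_code a valid two-letter type code.
#' @param grammar an [accession_grammar()].
#' @return the count of distinct serials, as a double.
#' @export
accession_capacity <- function(type_code, grammar = accession_grammar()) {
  if (!type_code %in% names(grammar$type_codes)) {
    mf_stop("unknown_type_code",
            sprintf("unknown accession type code '%s'", type_code))
  }
  10^grammar$n_digits * 26^grammar$n_letters
}

# serial index (0-based) -> serial text under a grammar
serial_text <- function(index, grammar) {
  n_let <- 26^grammar$n_letters
  digits <- index %/% n_let
  rest <- index %% n_let
  letters_out <- character(grammar$n_letters)
  for (i in seq_len(grammar$n_letters)) {
    letters_out[grammar$n_letters - i + 1L] <- LETTERS[rest %% 26 + 1L]
    rest <- rest %/% 26
  }
  paste0(formatC(digits, width = grammar$n_digits, flag = "0"),
         paste(letters_out, collapse = ""))
}

#' Parse and validate an accession
#'
#' Decomposes an identifier into its type code and serial, rejecting any
#' text that does not match the grammar exactly. Matching is case-sensitive:
#' accessions are uppercase-only, and lowercase input is rejected rather
#' than folded, so that identifiers stay byte-stable across systems.
#'
#' @param text the candidate identifier.
#' @param grammar an [accession_grammar()].
#' @return an object of class `accession` with elements `text`, `type_code`,
#'   `serial` and `entity` (the entity category for the type code).
#' @export
#' @examples
#' parse_accession("ENCSR000DVI")$entity   # "experiment"
#' parse_accession("ENCBS046RNA")$entity   # "biosample"
parse_accession <- function(text, grammar = accession_grammar()) {
  if (!is_scalar_chr(text)) {
    mf_stop("malformed_accession", "accession must be a single character string")
  }
  fail <- function(what, detail) {
    mf_stop("malformed_accession",
            sprintf("malformed accession '%s': %s (%s)", text, what, detail),
            constraint = what)
  }
  if (text != toupper(text)) {
    fail("case", "accessions are uppercase-only")
  }
  expected_len <- nchar(grammar$prefix) + 2L + grammar$n_digits + grammar$n_letters
  if (nchar(text) != expected_len) {
    fail("length", sprintf("expected %d characters, got %d",
                           expected_len, nchar(text)))
  }
  if (substr(text, 1L, nchar(grammar$prefix)) != grammar$prefix) {
    fail("prefix", sprintf("expected prefix '%s'", grammar$prefix))
  }
  code_start <- nchar(grammar$prefix) + 1L
  code <- substr(text, code_start, code_start + 1L)
  if (!code %in% names(grammar$type_codes)) {
    fail("type code", sprintf("unknown type code '%s'", code))
  }
  dig_start <- code_start + 2L
  digits <- substr(text, dig_start, dig_start + grammar$n_digits - 1L)
  if (!grepl(sprintf("^[0-9]{%d}$", grammar$n_digits), digits)) {
    fail("digits", sprintf("expected %d decimal digits", grammar$n_digits))
  }
  let_start <- dig_start + grammar$n_digits
  lets <- substr(text, let_start, let_start + grammar$n_letters - 1L)
  if (!grepl(sprintf("^[A-Z]{%d}$", grammar$n_letters), lets)) {
    fail("letters", sprintf("expected %d uppercase letters", grammar$n_letters))
  }
  structure(list(text = text, type_code = code,
                 serial = paste0(digits, lets),
                 entity = unname(grammar$type_codes[code])),
            class = "accession")
}

#' @export
format.accession <- function(x, ...) x$text

#' @export
print.accession <- function(x, ...) {
  cat(sprintf("<accession> %s  [%s: %s]\n", x$text, x$type_code, x$entity))
  invisible(x)
}

#' Create an empty accession registry
#'
#' The registry tracks every serial ever issued per type code (the issued
#' sets are append-only: an accession is stable once created and is never
#' re-issued, even after the record it names is deleted) and the
#' supersession relation between file accessions.
#'
#' @param grammar an [accession_grammar()].
#' @return an object of class `accession_registry`.
#' @export
accession_registry <- function(grammar = accession_grammar()) {
  issued <- stats::setNames(
    replicate(length(grammar$type_codes), character(0), simplify = FALSE),
    names(grammar$type_codes))
  structure(list(grammar = grammar, issued = issued,
                 supersessions = character(0)),
            class = "accession_registry")
}

#' @export
print.accession_registry <- function(x, ...) {
  counts <- vapply(x$issued, length, integer(1))
  cat("<accession_registry>\n  issued:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = " "),
      sprintf("\n  supersessions: %d\n", length(x$supersessions)))
  invisible(x)
}

#' Mint new accessions
#'
#' Serials are drawn by seeded pseudo-random rejection sampling over the
#' serial space, never sequentially, so the text of an accession leaks
#' nothing about submission order. Minting is reproducible: the same
#' registry state and seed always yield the same accession. Previously
#' issued serials are never re-issued.
#'
#' @param registry an [accession_registry()].
#' @param type_code a valid type code.
#' @param seed integer seed controlling the draw.
#' @param n how many accessions to mint.
#' @return a list with `accessions` (list of `accession` objects) and the
#'   updated `registry`. Raises an exhaustion error when the serial space
#'   for the type code is used up.
#' @export
mint_accession <- function(registry, type_code, seed, n = 1L) {
  stopifnot(inherits(registry, "accession_registry"))
  grammar <- registry$grammar
  if (!type_code %in% names(grammar$type_codes)) {
    mf_stop("unknown_type_code",
            sprintf("unknown accession type code '%s'", type_code))
  }
  capacity <- accession_capacity(type_code, grammar)
  out <- vector("list", n)
  issued <- registry$issued[[type_code]]
  with_seed(seed, {
    for (i in seq_len(n)) {
      if (length(issued) >= capacity) {
        mf_stop("accession_exhausted",
                sprintf("serial space for type code '%s' is exhausted (%d issued)",
                        type_code, length(issued)))
      }
      repeat {
        idx <- sample.int(capacity, 1L) - 1L
        serial <- serial_text(idx, grammar)
        if (!serial %in% issued) break
      }
      issued <- c(issued, serial)
      out[[i]] <- parse_accession(
        paste0(grammar$prefix, type_code, serial), grammar)
    }
  })
  registry$issued[[type_code]] <- issued
  list(accessions = out, registry = registry)
}

#' Record that one file supersedes another
#'
#' When a file is replaced, the replacement receives a fresh accession and
#' is related to the file it supersedes; chains may be walked back through
#' successive replacements. Only file (`FF`) accessions participate.
#'
#' @param registry an [accession_registry()].
#' @param old,new accession text or `accession` objects; `new` supersedes
#'   `old`.
#' @return the updated registry.
#' @export
supersede_file <- function(registry, old, new) {
  stopifnot(inherits(registry, "accession_registry"))
  as_txt <- function(x) if (inherits(x, "accession")) x$text else x
  old_a <- parse_accession(as_txt(old), registry$grammar)
  new_a <- parse_accession(as_txt(new), registry$grammar)
  file_code <- names(registry$grammar$type_codes)[
    registry$grammar$type_codes == "file"]
  if (old_a$type_code != file_code || new_a$type_code != file_code) {
    mf_stop("non_file_supersession",
            "only file accessions can participate in supersession")
  }
  if (old_a$text == new_a$text) {
    mf_stop("self_supersession",
            sprintf("'%s' cannot supersede itself", old_a$text))
  }
  if (old_a$text %in% unname(registry$supersessions)) {
    mf_stop("already_superseded",
            sprintf("'%s' is already superseded by another file", old_a$text))
  }
  # walking old -> older ... must never reach new (no cycles)
  cur <- old_a$text
  while (!is.na(cur)) {
    if (cur == new_a$text) {
      mf_stop("supersession_cycle",
              sprintf("superseding '%s' by '%s' would create a cycle",
                      old_a$text, new_a$text))
    }
    cur <- if (cur %in% names(registry$supersessions))
      registry$supersessions[[cur]] else NA_character_
  }
  registry$supersessions[[new_a$text]] <- old_a$text
  registry
}

#' Walk a file's supersession chain
#'
#' @param registry an [accession_registry()].
#' @param accession file accession text or object.
#' @return character vector of accessions from the given file back through
#'   everything it (transitively) supersedes, newest first.
#' @export
supersession_chain <- function(registry, accession) {
  cur <- if (inherits(accession, "accession")) accession$text else accession
  chain <- cur
  while (cur %in% names(registry$supersessions)) {
    cur <- registry$supersessions[[cur]]
    chain <- c(chain, cur)
  }
  chain
}

#' Write / read an accession ledger
#'
#' The ledger is the registry's persistence format: plain text, one issued
#' accession per line, `#` comments, with supersession relations recorded
#' as `#supersedes <new> <old>` directive lines. Because the ledger is
#' append-only, accession stability survives restarts.
#'
#' @param registry an [accession_registry()].
#' @param path file path.
#' @return `write_accession_ledger` returns `path` invisibly;
#'   `read_accession_ledger` returns a rebuilt `accession_registry`.
#' @export
write_accession_ledger <- function(registry, path) {
  lines <- c("# metaforge accession ledger")
  for (code in names(registry$issued)) {
    serials <- registry$issued[[code]]
    if (length(serials)) {
      lines <- c(lines, paste0(registry$grammar$prefix, code, serials))
    }
  }
  for (new in names(registry$supersessions)) {
    lines <- c(lines, sprintf("#supersedes %s %s",
                              new, registry$supersessions[[new]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_accession_ledger
#' @param grammar an [accession_grammar()].
#' @export
read_accession_ledger <- function(path, grammar = accession_grammar()) {
  registry <- accession_registry(grammar)
  for (line in readLines(path)) {
    line <- trimws(line)
    if (line == "") next
    if (startsWith(line, "#supersedes ")) {
      parts <- strsplit(sub("^#supersedes +", "", line), " +")[[1]]
      registry <- supersede_file(registry, parts[2], parts[1])
      next
    }
    if (startsWith(line, "#")) next
    acc <- parse_accession(line, grammar)
    registry$issued[[acc$type_code]] <-
      union(registry$issued[[acc$type_code]], acc$serial)
  }
  registry
}
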