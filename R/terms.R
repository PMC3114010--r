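#' RDF terms
#'
#' Terms are encoded as N-Triples-style strings: IRIs as `<iri>`, literals as
#' `"lexical"^^<datatype-iri>` (every literal carries a datatype; plain
#' literals get `xsd:string`), blank nodes as `_:label`. This flat encoding
#' makes a graph a plain character matrix with set semantics, which keeps
#' matching and equality cheap.
#'
#' @param x IRI string (absolute, unencoded).
#' @return An encoded term (character scalar).
#' @export
iri <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  paste0("<", x, ">")
}

#' @rdname iri
#' @param value literal value (character, integer/numeric, or logical).
#' @param datatype datatype IRI; inferred from `value`'s type when `NULL`.
#' @export
lit <- function(value, datatype = NULL) {
  if (is.null(datatype)) {
    datatype <- if (is.character(value)) XSD$string
    else if (is.logical(value)) XSD$boolean
    else if (is.integer(value)) XSD$int
    else XSD$double
  }
  lex <- if (is.logical(value)) tolower(as.character(value))
  else if (is.double(value)) format(value, digits = 15, scientific = FALSE, trim = TRUE)
  else as.character(value)
  lex <- gsub("\\", "\\\\", lex, fixed = TRUE)
  lex <- gsub("\"", "\\\"", lex, fixed = TRUE)
  paste0("\"", lex, "\"^^<", datatype, ">")
}

#' @rdname iri
#' @param label blank-node label.
#' @export
bnode <- function(label) paste0("_:", label)

term_kind <- function(t) {
  ifelse(startsWith(t, "<"), "iri",
         ifelse(startsWith(t, "\""), "literal",
                ifelse(startsWith(t, "_:"), "bnode", "invalid")))
}

is_iri_term <- function(t) startsWith(t, "<")
is_literal_term <- function(t) startsWith(t, "\"")
is_bnode_term <- function(t) startsWith(t, "_:")

#' @rdname iri
#' @param t an encoded term.
#' @export
iri_value <- function(t) {
  stopifnot(is_iri_term(t))
  substr(t, 2L, nchar(t) - 1L)
}

lit_parts <- function(t) {
  stopifnot(is_literal_term(t))
  # lexical form ends at the last unescaped quote before ^^
  m <- regmatches(t, regexec('^"((?:[^"\\\\]|\\\\.)*)"\\^\\^<([^>]*)>$', t))[[1]]
  if (length(m) != 3L) stop("malformed literal term: ", t)
  lex <- gsub("\\\\\"", "\"", m[2], fixed = FALSE)
  lex <- gsub("\\\\", "\\", lex, fixed = TRUE)
  list(lexical = lex, datatype = m[3])
}

#' @rdname iri
#' @export
lit_lexical <- function(t) lit_parts(t)$lexical

#' @rdname iri
#' @export
lit_datatype <- function(t) lit_parts(t)$datatype

#' Decode a literal term to an R value using its datatype
#' @param t an encoded literal term.
#' @return numeric, logical or character scalar.
#' @export
lit_value <- function(t) {
  p <- lit_parts(t)
  dt <- p$datatype
  if (dt %in% c(XSD$int, XSD$integer, XSD$long)) {
    v <- suppressWarnings(as.integer(p$lexical))
    if (is.na(v)) suppressWarnings(as.numeric(p$lexical)) else v
  } else if (dt %in% c(XSD$double, XSD$float, XSD$decimal)) {
    suppressWarnings(as.numeric(p$lexical))
  } else if (dt == XSD$boolean) {
    p$lexical == "true"
  } else p$lexical
}

lit_is_numeric <- function(t) {
  if (!is_literal_term(t)) return(FALSE)
  p <- lit_parts(t)
  if (p$datatype %in% c(XSD$int, XSD$integer, XSD$long, XSD$double,
                        XSD$float, XSD$decimal)) return(TRUE)
  # untyped-looking strings that happen to be numerals are not numbers
  FALSE
}

local_name <- function(iri_string) {
  sub("^.*[#/]", "", iri_string)
}
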