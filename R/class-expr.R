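#' Restricted OWL class expressions
#'
#' The fragment used by service descriptions: named classes, conjunctions
#' (`and`, with `that` as a synonym), existential restrictions
#' (`'property' some Filler`) and datatype restrictions with facets
#' (`double[< = 500.0]`, `int[< 5]`, `double[< 5.0, > -5.0]`). Expressions
#' are S3 lists with a `kind` of `named`, `and`, `some`, or `data_some`.
#'
#' @param text expression text; quoted names (`'has attribute'`) and bare
#'   names are resolved to IRIs through `labels`.
#' @param labels named character vector mapping names to IRIs (e.g. from
#'   [load_ontology()]); unmapped names are minted in the service-ontology
#'   namespace.
#' @return a `class_expr` object.
#' @export
parse_class_expression <- function(text, labels = character(0)) {
  toks <- ce_tokens(text)
  state <- new.env(parent = emptyenv())
  state$pos <- 1L
  state$toks <- toks
  expr <- ce_parse_conj(state, labels)
  if (state$pos <= length(state$toks$type))
    ce_fail(state, "trailing input")
  expr
}

ce_fail <- function(state, msg) {
  at <- if (state$pos <= length(state$toks$type))
    state$toks$col[state$pos] else nchar(state$toks$src) + 1L
  stop(sprintf("class expression parse error at column %d: %s", at, msg),
       call. = FALSE)
}
ce_peek <- function(state) {
  if (state$pos <= length(state$toks$type)) state$toks$type[state$pos] else "eof"
}
ce_peek_val <- function(state) {
  if (state$pos <= length(state$toks$type)) state$toks$value[state$pos] else NA
}
ce_next <- function(state) {
  v <- state$toks$value[state$pos]
  state$pos <- state$pos + 1L
  v
}

DATATYPE_NAMES <- c(string = "string", int = "int", integer = "int",
                    double = "double", float = "double", decimal = "double")

ce_parse_conj <- function(state, labels) {
  parts <- list(ce_parse_prim(state, labels))
  while (ce_peek(state) == "word" && ce_peek_val(state) %in% c("and", "that")) {
    ce_next(state)
    parts[[length(parts) + 1L]] <- ce_parse_prim(state, labels)
  }
  if (length(parts) == 1L) parts[[1]] else ce_and(parts)
}

ce_parse_prim <- function(state, labels) {
  ty <- ce_peek(state)
  if (ty == "lparen") {
    ce_next(state)
    e <- ce_parse_conj(state, labels)
    if (ce_peek(state) != "rparen") ce_fail(state, "expected ')'")
    ce_next(state)
    return(e)
  }
  if (ty %in% c("word", "qname")) {
    name <- ce_next(state)
    if (name %in% names(DATATYPE_NAMES)) {
      facets <- if (ce_peek(state) == "lbracket") ce_parse_facets(state) else list()
      return(ce_data(DATATYPE_NAMES[[name]], facets))
    }
    if (ce_peek(state) == "word" && identical(ce_peek_val(state), "some")) {
      ce_next(state)
      filler <- ce_parse_prim(state, labels)
      prop <- ce_resolve(name, labels)
      if (filler$kind == "data")
        return(ce_data_some(prop, filler$base, filler$facets))
      return(ce_some(prop, filler))
    }
    return(ce_named(ce_resolve(name, labels)))
  }
  ce_fail(state, paste0("unexpected token '", ce_peek_val(state), "'"))
}

ce_parse_facets <- function(state) {
  ce_next(state)  # [
  facets <- list()
  repeat {
    if (ce_peek(state) != "op") ce_fail(state, "expected facet operator")
    op <- ce_next(state)
    if (ce_peek(state) == "op" && identical(ce_peek_val(state), "=")) {
      ce_next(state)
      op <- paste0(op, "=")
    }
    if (ce_peek(state) != "number") ce_fail(state, "expected facet bound")
    bound <- as.numeric(ce_next(state))
    kind <- switch(op,
                   "<" = "maxExclusive", "<=" = "maxInclusive",
                   ">" = "minExclusive", ">=" = "minInclusive",
                   ce_fail(state, paste0("unknown facet operator '", op, "'")))
    facets[[length(facets) + 1L]] <- list(kind = kind, bound = bound)
    if (ce_peek(state) == "comma") { ce_next(state); next }
    break
  }
  if (ce_peek(state) != "rbracket") ce_fail(state, "expected ']'")
  ce_next(state)
  facets
}

ce_resolve <- function(name, labels) {
  if (grepl("^https?://", name)) return(name)
  if (name %in% names(labels)) return(labels[[name]])
  paste0(NS$lso, gsub("\\s+", "_", name))
}

ce_tokens <- function(text) {
  types <- character(0); values <- character(0); cols <- integer(0)
  push <- function(ty, v, col) {
    types[[length(types) + 1L]] <<- ty
    values[[length(values) + 1L]] <<- v
    cols[[length(cols) + 1L]] <<- col
  }
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    rest <- substr(text, i, n)
    if (ch == "'") {
      m <- regexpr("^'[^']*'", rest)
      if (m < 0) stop(sprintf("class expression parse error at column %d: unterminated quoted name", i), call. = FALSE)
      l <- attr(m, "match.length")
      push("word", substr(rest, 2L, l - 1L), i); i <- i + l; next
    }
    if (ch == "(") { push("lparen", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ")", i); i <- i + 1L; next }
    if (ch == "[") { push("lbracket", "[", i); i <- i + 1L; next }
    if (ch == "]") { push("rbracket", "]", i); i <- i + 1L; next }
    if (ch == ",") { push("comma", ",", i); i <- i + 1L; next }
    if (ch %in% c("<", ">", "=")) { push("op", ch, i); i <- i + 1L; next }
    m <- regexpr("^-?[0-9]+(\\.[0-9]+)?", rest)
    if (m > 0) {
      l <- attr(m, "match.length")
      push("number", substr(rest, 1L, l), i); i <- i + l; next
    }
    m <- regexpr("^https?://[^\\s)\\],]+", rest, perl = TRUE)
    if (m > 0) {
      l <- attr(m, "match.length")
      push("qname", substr(rest, 1L, l), i); i <- i + l; next
    }
    m <- regexpr("^[A-Za-z_][A-Za-z0-9_:-]*", rest)
    if (m > 0) {
      l <- attr(m, "match.length")
      push("word", substr(rest, 1L, l), i); i <- i + l; next
    }
    stop(sprintf("class expression parse error at column %d: unexpected character '%s'",
                 i, ch), call. = FALSE)
  }
  list(type = types, value = values, col = cols, src = text)
}

ce_named <- function(iri) structure(list(kind = "named", iri = iri),
                                    class = "class_expr")
ce_and <- function(parts) {
  flat <- list()
  for (p in parts) {
    if (p$kind == "and") flat <- c(flat, p$parts) else flat[[length(flat) + 1L]] <- p
  }
  structure(list(kind = "and", parts = flat), class = "class_expr")
}
ce_some <- function(property, filler)
  structure(list(kind = "some", property = property, filler = filler),
            class = "class_expr")
ce_data_some <- function(property, base, facets)
  structure(list(kind = "data_some", property = property, base = base,
                 facets = facets), class = "class_expr")
ce_data <- function(base, facets)
  structure(list(kind = "data", base = base, facets = facets),
            class = "class_expr")

#' @export
format.class_expr <- function(x, ...) {
  fmt <- function(e) {
    switch(e$kind,
           named = local_name(e$iri),
           and = paste(vapply(e$parts, fmt, ""), collapse = " and "),
           some = sprintf("'%s' some (%s)", local_name(e$property), fmt(e$filler)),
           data_some = sprintf("'%s' some %s%s", local_name(e$property), e$base,
                               fmt_facets(e$facets)),
           data = paste0(e$base, fmt_facets(e$facets)))
  }
  fmt_facets <- function(fs) {
    if (length(fs) == 0L) return("")
    ops <- c(maxExclusive = "<", maxInclusive = "<=",
             minExclusive = ">", minInclusive = ">=")
    paste0("[", paste(vapply(fs, function(f)
      paste(ops[[f$kind]], f$bound), ""), collapse = ", "), "]")
  }
  fmt(x)
}

#' @export
print.class_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Evaluate datatype facets against a value
#'
#' @param value a numeric (or string, which fails numeric facets) value.
#' @param facets list of `list(kind =, bound =)` facets.
#' @return `TRUE` iff every facet holds.
#' @export
facet_satisfied <- function(value, facets) {
  if (length(facets) == 0L) return(TRUE)
  if (!is.numeric(value)) return(FALSE)
  for (f in facets) {
    ok <- switch(f$kind,
                 maxInclusive = value <= f$bound,
                 maxExclusive = value < f$bound,
                 minInclusive = value >= f$bound,
                 minExclusive = value > f$bound,
                 stop("unknown facet kind: ", f$kind, call. = FALSE))
    if (!ok) return(FALSE)
  }
  TRUE
}
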