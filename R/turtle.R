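#' Parse Turtle / N3 text into an RDF graph
#'
#' Supports the subset this framework emits: `@prefix` directives, prefixed
#' names, absolute IRIs in angle brackets, the `a` keyword, literal objects
#' with optional `^^` datatype, object lists (`,`), predicate-object lists
#' (`;`), blank node labels (`_:x`) and comments. In `lenient` mode it also
#' accepts the loose N3 of the bundled listing fixtures: prefix IRIs and
#' datatype IRIs printed without angle brackets, and `prefix`/`PREFIX`
#' directives without the leading `@`.
#'
#' @param text Turtle document (single string or character vector of lines).
#' @param lenient accept the loose listing-style N3 (default `FALSE`).
#' @return an [rdf_graph()].
#' @export
parse_turtle <- function(text, lenient = FALSE) {
  text <- paste(text, collapse = "\n")
  toks <- turtle_tokens(text, lenient = lenient)
  g <- rdf_graph(prefixes = character(0))
  pos <- 1L
  n <- length(toks$value)
  peek <- function() if (pos <= n) toks$value[pos] else NA_character_
  peek_type <- function() if (pos <= n) toks$type[pos] else "eof"
  advance <- function() {
    v <- toks$value[pos]; pos <<- pos + 1L; v
  }
  fail <- function(msg) {
    ln <- if (pos <= n) toks$line[pos] else toks$line[n]
    stop(sprintf("turtle syntax error (line %d): %s", ln, msg), call. = FALSE)
  }
  expand_pname <- function(tok) {
    m <- regexec("^([A-Za-z][A-Za-z0-9_.-]*)?:(.*)$", tok)[[1]]
    parts <- regmatches(tok, regexec("^([A-Za-z][A-Za-z0-9_.-]*)?:(.*)$", tok))[[1]]
    if (length(parts) == 0L) fail(paste0("not a prefixed name: ", tok))
    pfx <- parts[2]; local <- parts[3]
    key <- if (nzchar(pfx)) pfx else ""
    ns <- if (key %in% names(g$prefixes)) g$prefixes[[key]] else NULL
    if (is.null(ns) && lenient && pfx %in% names(default_prefixes()))
      ns <- default_prefixes()[[pfx]]  # listings use rdf: without declaring it
    if (is.null(ns)) fail(paste0("undeclared prefix: '", pfx, "'"))
    iri(paste0(ns, local))
  }
  parse_term <- function(role) {
    ty <- peek_type()
    v <- advance()
    if (ty == "iriref") return(iri(substr(v, 2L, nchar(v) - 1L)))
    if (ty == "bnode") return(v)
    if (ty == "keyword_a") return(iri(paste0(NS$rdf, "type")))
    if (ty == "string") {
      lex <- turtle_unescape(substr(v, 2L, nchar(v) - 1L))
      dt <- XSD$string
      if (identical(peek_type(), "dtsep")) {
        advance()
        dty <- peek_type()
        dtv <- advance()
        dt <- if (dty == "iriref") substr(dtv, 2L, nchar(dtv) - 1L)
        else if (dty == "bareiri") dtv
        else iri_value(expand_pname(dtv))
      }
      return(lit(lex, dt))
    }
    if (ty == "number") {
      if (grepl("[.eE]", v)) return(lit(as.numeric(v), XSD$double))
      return(lit(as.integer(v), XSD$integer))
    }
    if (ty == "pname") return(expand_pname(v))
    if (ty == "bareiri" && lenient) return(iri(v))
    fail(paste0("unexpected token '", v, "' as ", role))
  }
  while (pos <= n) {
    if (peek_type() == "prefix_directive") {
      advance()
      pn <- peek()
      if (peek_type() != "pname_ns") fail("expected prefix name after @prefix")
      advance()
      pfx <- sub(":$", "", pn)
      ty <- peek_type()
      v <- advance()
      ns_iri <- if (ty == "iriref") substr(v, 2L, nchar(v) - 1L)
      else if (ty == "bareiri" && lenient) v
      else fail("expected namespace IRI in @prefix")
      g$prefixes[[pfx]] <- ns_iri
      if (identical(peek(), ".")) advance()
      next
    }
    s <- parse_term("subject")
    repeat {
      p <- parse_term("predicate")
      repeat {
        o <- parse_term("object")
        g <- rdf_add(g, s, p, o)
        if (identical(peek(), ",")) { advance(); next }
        break
      }
      if (identical(peek(), ";")) {
        advance()
        if (identical(peek(), ".")) break  # trailing ; before .
        next
      }
      break
    }
    if (!identical(peek(), ".")) fail("expected '.' at end of statement")
    advance()
  }
  if (length(g$prefixes) == 0L) g$prefixes <- default_prefixes()
  g
}

turtle_unescape <- function(x) {
  x <- gsub("\\\\n", "\n", x)
  x <- gsub("\\\\t", "\t", x)
  x <- gsub("\\\\\"", "\"", x)
  gsub("\\\\\\\\", "\\\\", x)
}
turtle_escape <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  gsub("\t", "\\\\t", x)
}

turtle_tokens <- function(text, lenient = FALSE) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  types <- character(0); values <- character(0); linenos <- integer(0)
  push <- function(ty, v, ln) {
    types[[length(types) + 1L]] <<- ty
    values[[length(values) + 1L]] <<- v
    linenos[[length(linenos) + 1L]] <<- ln
  }
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]
    i <- 1L; len <- nchar(s)
    while (i <= len) {
      ch <- substr(s, i, i)
      if (grepl("^\\s$", ch)) { i <- i + 1L; next }
      if (ch == "#") break  # comment to end of line
      rest <- substr(s, i, len)
      if (ch == "<") {
        j <- regexpr(">", rest, fixed = TRUE)
        if (j < 0) stop(sprintf("turtle syntax error (line %d): unterminated IRI", ln), call. = FALSE)
        push("iriref", substr(rest, 1L, j), ln); i <- i + j; next
      }
      if (ch == "\"") {
        m <- regexpr('^"(?:[^"\\\\]|\\\\.)*"', rest)
        if (m < 0) stop(sprintf("turtle syntax error (line %d): unterminated string", ln), call. = FALSE)
        l <- attr(m, "match.length")
        push("string", substr(rest, 1L, l), ln); i <- i + l; next
      }
      if (startsWith(rest, "^^")) { push("dtsep", "^^", ln); i <- i + 2L
        # lenient: bare IRI datatype as printed in the listings
        rest2 <- substr(s, i, len)
        if (lenient && grepl("^https?://", rest2)) {
          m <- regexpr("^[^\\s;,]+", rest2, perl = TRUE)
          l <- attr(m, "match.length")
          v <- substr(rest2, 1L, l)
          # a trailing '.' is the statement terminator, not part of the IRI
          if (endsWith(v, ".")) { v <- sub("\\.$", "", v); l <- l - 1L }
          push("bareiri", v, ln); i <- i + l
        }
        next
      }
      if (lenient && grepl("^a:[A-Za-z0-9_]", rest)) {
        # listings glue the 'a' keyword to an empty-prefix name: "a:classname"
        push("keyword_a", "a", ln); i <- i + 1L; next
      }
      if (startsWith(rest, "@prefix")) { push("prefix_directive", "@prefix", ln); i <- i + 7L; next }
      if (lenient && grepl("^(prefix|PREFIX)\\s", rest)) {
        push("prefix_directive", "prefix", ln); i <- i + 6L; next
      }
      if (ch %in% c(".", ";", ",")) { push("punct", ch, ln); i <- i + 1L; next }
      if (startsWith(rest, "_:")) {
        m <- regexpr("^_:[A-Za-z0-9_]+", rest)
        l <- attr(m, "match.length")
        push("bnode", substr(rest, 1L, l), ln); i <- i + l; next
      }
      if (grepl("^-?[0-9]", rest) || grepl("^[+-]\\.?[0-9]", rest)) {
        m <- regexpr("^[+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", rest)
        l <- attr(m, "match.length")
        push("number", substr(rest, 1L, l), ln); i <- i + l; next
      }
      if (grepl("^a[\\s(<]", paste0(rest, " "), perl = TRUE) &&
          (i == 1L || TRUE) && grepl("^a\\b", rest)) {
        push("keyword_a", "a", ln); i <- i + 1L; next
      }
      # prefixed name, possibly namespace-only (for @prefix) or lenient bare IRI
      if (lenient && grepl("^[A-Za-z][A-Za-z0-9_.-]*:https?://", rest)) {
        # listing style "@prefix ss:http://..." glued together
        m <- regexpr("^[A-Za-z][A-Za-z0-9_.-]*:", rest)
        l <- attr(m, "match.length")
        push("pname_ns", substr(rest, 1L, l), ln); i <- i + l
        rest2 <- substr(s, i, len)
        m2 <- regexpr("^[^\\s;,]+", rest2, perl = TRUE)
        l2 <- attr(m2, "match.length")
        v <- substr(rest2, 1L, l2)
        if (grepl("\\.$", v)) { v <- sub("\\.$", "", v); l2 <- l2 - 1L }
        push("bareiri", v, ln); i <- i + l2; next
      }
      if (lenient && grepl("^:https?://", rest)) {
        push("pname_ns", ":", ln); i <- i + 1L
        rest2 <- substr(s, i, len)
        m2 <- regexpr("^[^\\s;,]+", rest2, perl = TRUE)
        l2 <- attr(m2, "match.length")
        v <- substr(rest2, 1L, l2)
        if (grepl("\\.$", v)) { v <- sub("\\.$", "", v); l2 <- l2 - 1L }
        push("bareiri", v, ln); i <- i + l2; next
      }
      if (lenient && grepl("^https?://", rest)) {
        m <- regexpr("^[^\\s;,]+", rest, perl = TRUE)
        l <- attr(m, "match.length")
        v <- substr(rest, 1L, l)
        if (grepl("\\.$", v)) { v <- sub("\\.$", "", v); l <- l - 1L }
        push("bareiri", v, ln); i <- i + l; next
      }
      m <- regexpr("^[A-Za-z][A-Za-z0-9_.-]*:|^:", rest)
      if (m > 0) {
        l <- attr(m, "match.length")
        after <- substr(rest, l + 1L, len)
        m2 <- regexpr("^[A-Za-z0-9_][A-Za-z0-9_.-]*", after)
        if (m2 > 0) {
          l2 <- attr(m2, "match.length")
          v <- substr(rest, 1L, l + l2)
          # a trailing '.' inside the local-name regexp is a terminator
          while (endsWith(v, ".")) { v <- sub("\\.$", "", v) }
          push("pname", v, ln); i <- i + nchar(v); next
        }
        push("pname_ns", substr(rest, 1L, l), ln); i <- i + l; next
      }
      stop(sprintf("turtle syntax error (line %d): unexpected character '%s'", ln, ch),
           call. = FALSE)
    }
  }
  list(type = types, value = values, line = linenos)
}

#' Serialize a graph
#'
#' @param g an [rdf_graph()].
#' @param format `"turtle"` or `"rdfxml"`.
#' @return a single string; reparsing it yields an equal triple set.
#' @export
serialize_graph <- function(g, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  if (format == "rdfxml") return(serialize_rdfxml(g))
  pfx <- g$prefixes
  compact <- function(term) {
    if (is_iri_term(term)) {
      v <- iri_value(term)
      for (p in names(pfx)) {
        ns <- pfx[[p]]
        if (startsWith(v, ns)) {
          local <- substr(v, nchar(ns) + 1L, nchar(v))
          if (grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", local) && !endsWith(local, "."))
            return(paste0(p, ":", local))
        }
      }
      return(paste0("<", v, ">"))
    }
    if (is_literal_term(term)) {
      parts <- lit_parts(term)
      lex <- paste0("\"", turtle_escape(parts$lexical), "\"")
      if (parts$datatype == XSD$string) return(lex)
      return(paste0(lex, "^^<", parts$datatype, ">"))
    }
    term  # blank node
  }
  df <- split_triples(g)
  header <- vapply(names(pfx), function(p)
    sprintf("@prefix %s: <%s> .", p, pfx[[p]]), "")
  if (nrow(df) == 0L) return(paste(c(header, ""), collapse = "\n"))
  df <- df[order(df$s, df$p, df$o), , drop = FALSE]
  body <- sprintf("%s %s %s .",
                  vapply(df$s, compact, ""),
                  vapply(df$p, compact, ""),
                  vapply(df$o, compact, ""))
  paste(c(header, "", body, ""), collapse = "\n")
}
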