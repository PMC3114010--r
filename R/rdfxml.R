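#' Parse RDF/XML into an RDF graph
#'
#' Handles the constructs used by annotation graphs: `rdf:Description` and
#' typed node elements, `rdf:about`, `rdf:ID`, `rdf:nodeID`, property
#' elements with `rdf:resource`/`rdf:nodeID` references, literal content with
#' optional `rdf:datatype`, and nested node elements.
#'
#' @param text RDF/XML document as a string.
#' @return an [rdf_graph()].
#' @export
parse_rdfxml <- function(text) {
  doc <- xml2::read_xml(text)
  rdf_ns <- NS$rdf
  g <- rdf_graph(prefixes = character(0))
  ns_map <- xml2::xml_ns(doc)
  pfx <- stats::setNames(as.character(ns_map), names(ns_map))
  # xml2 names namespaces d1, d2... for defaults; keep only sane prefixes
  keep <- !grepl("^d[0-9]+$", names(pfx))
  g$prefixes <- pfx[keep]
  if (length(g$prefixes) == 0L) g$prefixes <- default_prefixes()

  qname_iri <- function(node) {
    ns <- xml2::xml_ns(node)
    nm <- xml2::xml_name(node, ns = ns)  # "prefix:local" against doc ns map
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      nsuri <- as.character(ns[parts[1]])
      paste0(nsuri, parts[2])
    } else {
      stop("rdfxml: element without namespace: ", nm)
    }
  }
  bn_counter <- 0L
  rdf_attr <- function(el, local) {
    at <- xml2::xml_attrs(el)
    hit <- which(names(at) == local | endsWith(names(at), paste0(":", local)))
    if (length(hit) > 0L) unname(at[hit[1]]) else NA_character_
  }
  node_term <- function(el) {
    about <- rdf_attr(el, "about")
    if (!is.na(about)) return(iri(about))
    nid <- rdf_attr(el, "nodeID")
    if (!is.na(nid)) return(bnode(nid))
    id <- rdf_attr(el, "ID")
    if (!is.na(id)) return(iri(paste0("#", id)))
    bn_counter <<- bn_counter + 1L
    bnode(paste0("g", bn_counter))
  }
  process_node <- function(el) {
    subj <- node_term(el)
    el_iri <- qname_iri(el)
    if (el_iri != paste0(rdf_ns, "Description"))
      g <<- rdf_add(g, subj, iri(paste0(rdf_ns, "type")), iri(el_iri))
    for (prop in xml2::xml_children(el)) {
      p <- iri(qname_iri(prop))
      res <- rdf_attr(prop, "resource")
      if (!is.na(res)) { g <<- rdf_add(g, subj, p, iri(res)); next }
      nid <- rdf_attr(prop, "nodeID")
      if (!is.na(nid)) { g <<- rdf_add(g, subj, p, bnode(nid)); next }
      kids <- xml2::xml_children(prop)
      if (length(kids) > 0L) {
        for (kid in kids) {
          obj <- process_node(kid)
          g <<- rdf_add(g, subj, p, obj)
        }
        next
      }
      dt <- rdf_attr(prop, "datatype")
      if (is.na(dt)) dt <- XSD$string
      g <<- rdf_add(g, subj, p, lit(xml2::xml_text(prop), dt))
    }
    subj
  }
  for (el in xml2::xml_children(doc)) process_node(el)
  g
}

serialize_rdfxml <- function(g) {
  df <- split_triples(g)
  rdf_type <- iri(paste0(NS$rdf, "type"))
  pfx <- g$prefixes
  # every predicate / type IRI must be expressible as a QName
  ns_of <- function(v) sub("[^#/]*$", "", v)
  needed <- unique(vapply(c(df$p, df$o[df$p == rdf_type & startsWith(df$o, "<")]),
                          function(t) ns_of(iri_value(t)), ""))
  extra <- setdiff(needed, as.character(pfx))
  if (length(extra) > 0L) {
    nm <- paste0("ns", seq_along(extra))
    pfx <- c(pfx, stats::setNames(extra, nm))
  }
  qname <- function(v) {
    ns <- ns_of(v)
    p <- names(pfx)[match(ns, as.character(pfx))][1]
    local <- substr(v, nchar(ns) + 1L, nchar(v))
    if (is.na(p) || !grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local))
      stop("rdfxml: cannot form QName for ", v)
    c(p, local)
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  used <- character(0)
  note_used <- function(p) used <<- unique(c(used, p))
  subj_attr <- function(s) {
    if (startsWith(s, "_:")) sprintf(' rdf:nodeID="%s"', substr(s, 3L, nchar(s)))
    else sprintf(' rdf:about="%s"', esc(iri_value(s)))
  }
  body <- character(0)
  for (s in unique(df$s)) {
    rows <- df[df$s == s, , drop = FALSE]
    lines <- sprintf("  <rdf:Description%s>", subj_attr(s))
    for (k in seq_len(nrow(rows))) {
      p <- rows$p[k]; o <- rows$o[k]
      q <- qname(iri_value(p)); note_used(q[1])
      tag <- paste0(q[1], ":", q[2])
      if (startsWith(o, "<")) {
        lines <- c(lines, sprintf('    <%s rdf:resource="%s"/>', tag, esc(iri_value(o))))
      } else if (startsWith(o, "_:")) {
        lines <- c(lines, sprintf('    <%s rdf:nodeID="%s"/>', tag, substr(o, 3L, nchar(o))))
      } else {
        parts <- lit_parts(o)
        dt_attr <- if (parts$datatype == XSD$string) ""
        else sprintf(' rdf:datatype="%s"', esc(parts$datatype))
        lines <- c(lines, sprintf("    <%s%s>%s</%s>", tag, dt_attr,
                                  esc(parts$lexical), tag))
      }
    }
    lines <- c(lines, "  </rdf:Description>")
    body <- c(body, lines)
  }
  note_used("rdf")
  pfx_keep <- pfx[names(pfx) %in% used]
  if (!"rdf" %in% names(pfx_keep)) pfx_keep <- c(pfx_keep, rdf = NS$rdf)
  ns_decl <- paste(sprintf('xmlns:%s="%s"', names(pfx_keep),
                           as.character(pfx_keep)), collapse = "\n         ")
  paste(c('<?xml version="1.0" encoding="UTF-8"?>',
          sprintf("<rdf:RDF %s>", ns_decl),
          body,
          "</rdf:RDF>", ""), collapse = "\n")
}
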