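#' Load an ontology context from a Turtle file
#'
#' The bundled service ontology (`inst/extdata/lso.ttl`) declares, in plain
#' Turtle: `rdfs:label` bindings that map class-expression names to IRIs,
#' class definitions carried as class-expression text under `lso:definition`,
#' and the property hierarchy as `rdfs:subPropertyOf` /
#' `owl:equivalentProperty` triples. This keeps the ontology both
#' human-readable and within the structural fragment the reasoner supports.
#'
#' @param path Turtle file; default is the bundled Lipinski service ontology.
#' @return an `ontology_context`.
#' @export
load_ontology <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lso.ttl", package = "semdesc",
                        mustWork = TRUE)
  g <- parse_turtle(readLines(path, warn = FALSE))
  v <- vocab()
  lab <- rdf_match(g, p = iri(v$rdfs_label))
  labels <- stats::setNames(vapply(lab$s, iri_value, ""),
                            vapply(lab$o, lit_lexical, ""))
  sub <- rdf_match(g, p = iri(v$rdfs_subprop))
  subproperties <- data.frame(sub = vapply(sub$s, iri_value, ""),
                              super = vapply(sub$o, iri_value, ""),
                              stringsAsFactors = FALSE)
  eq <- rdf_match(g, p = iri(v$owl_equivprop))
  equivalents <- data.frame(a = vapply(eq$s, iri_value, ""),
                            b = vapply(eq$o, iri_value, ""),
                            stringsAsFactors = FALSE)
  defs_raw <- rdf_match(g, p = iri(v$definition))
  definitions <- list()
  for (k in seq_len(nrow(defs_raw))) {
    definitions[[iri_value(defs_raw$s[k])]] <-
      parse_class_expression(lit_lexical(defs_raw$o[k]), labels)
  }
  ontology_context(definitions = definitions, subproperties = subproperties,
                   equivalents = equivalents, labels = labels)
}

# upward closure: the property itself plus all declared super- and
# equivalent properties; materialized on write so that data annotated through
# a subproperty also answers queries phrased with the superproperty
property_superclosure <- function(property, ctx) {
  if (is.null(ctx)) return(property)
  out <- property
  repeat {
    more <- c(ctx$subproperties$super[ctx$subproperties$sub %in% out],
              ctx$equivalents$a[ctx$equivalents$b %in% out],
              ctx$equivalents$b[ctx$equivalents$a %in% out])
    new <- setdiff(more, out)
    if (length(new) == 0L) break
    out <- c(out, new)
  }
  out
}
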