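#' The entity-attribute-value annotation pattern
#'
#' Every annotative service decorates a molecule with exactly three triples:
#' `(entity, has-attribute, attr)`, `(attr, rdf:type, type)`,
#' `(attr, has-value, value)`. The attribute node IRI is minted
#' deterministically from the entity IRI, the local name of the attribute
#' type and a content hash of the value, so repeating an annotation is a
#' no-op and references stay stable across service chains.
#'
#' @param g an [rdf_graph()].
#' @param entity encoded IRI term of the annotated entity.
#' @param type attribute type IRI (plain string).
#' @param value encoded literal term (see [lit()]).
#' @param property attachment property IRI; default SIO `has attribute`.
#' @return list with the updated `graph` and the `attribute` node term.
#' @export
add_attribute <- function(g, entity, type, value,
                          property = vocab()$has_attribute) {
  stopifnot(is_iri_term(entity), is_literal_term(value))
  attr_iri <- paste0(iri_value(entity), "#", local_name(type), "-",
                     content_hash(value))
  attr_term <- iri(attr_iri)
  v <- vocab()
  g <- rdf_add(g, entity, iri(property), attr_term)
  g <- rdf_add(g, attr_term, iri(v$rdf_type), iri(type))
  g <- rdf_add(g, attr_term, iri(v$has_value), value)
  list(graph = g, attribute = attr_term)
}

#' Read attribute instances back from a graph
#'
#' Attributes reachable from `entity` through `property` *or any declared
#' sub/equivalent property* (per `closure`) whose `rdf:type` is `type` are
#' returned together with their values.
#'
#' @param g an [rdf_graph()].
#' @param entity encoded IRI term.
#' @param type attribute type IRI (plain string), or `NULL` for all types.
#' @param closure character vector of predicate IRIs to traverse; defaults to
#'   just `has attribute`. Use [property_closure()] to include declared
#'   subproperties.
#' @return list of attribute instances: each has `entity`, `attribute`,
#'   `type`, `value` (encoded literal term).
#' @export
get_attributes <- function(g, entity, type = NULL,
                           closure = vocab()$has_attribute) {
  v <- vocab()
  hits <- rdf_match(g, s = entity, p = paste0("<", closure, ">"))
  out <- list()
  for (attr in unique(hits$o)) {
    if (is_literal_term(attr)) next
    types <- rdf_match(g, s = attr, p = iri(v$rdf_type))$o
    types <- vapply(types[startsWith(types, "<")], iri_value, "")
    if (!is.null(type) && !(type %in% types)) next
    vals <- rdf_match(g, s = attr, p = iri(v$has_value))$o
    vals <- vals[startsWith(vals, "\"")]
    for (val in vals) {
      out[[length(out) + 1L]] <- list(entity = entity, attribute = attr,
                                      type = if (is.null(type)) types else type,
                                      value = val)
    }
  }
  out
}
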