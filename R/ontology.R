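#' Ontology context
#'
#' Holds named-class definitions (IRI -> class expression), the declared
#' property hierarchy (subproperty and equivalent-property pairs) and a
#' name -> IRI label map used when parsing class-expression text.
#'
#' @param definitions named list: class IRI -> `class_expr`.
#' @param subproperties data.frame with columns `sub`, `super` (IRIs).
#' @param equivalents data.frame with columns `a`, `b` (IRIs).
#' @param labels named character vector: display name -> IRI.
#' @return an `ontology_context`.
#' @export
ontology_context <- function(definitions = list(),
                             subproperties = data.frame(sub = character(0),
                                                        super = character(0)),
                             equivalents = data.frame(a = character(0),
                                                      b = character(0)),
                             labels = character(0)) {
  ctx <- structure(list(definitions = definitions,
                        subproperties = subproperties,
                        equivalents = equivalents,
                        labels = labels),
                   class = "ontology_context")
  check_definition_cycles(ctx)
  ctx
}

check_definition_cycles <- function(ctx) {
  visiting <- character(0)
  seen <- character(0)
  refs <- function(e) {
    switch(e$kind,
           named = e$iri,
           and = unlist(lapply(e$parts, refs)),
           some = refs(e$filler),
           character(0))
  }
  visit <- function(iri) {
    if (iri %in% visiting)
      stop("definitional cycle among named classes at ", iri, call. = FALSE)
    if (iri %in% seen || is.null(ctx$definitions[[iri]])) return(invisible())
    visiting <<- c(visiting, iri)
    for (r in refs(ctx$definitions[[iri]])) visit(r)
    visiting <<- setdiff(visiting, iri)
    seen <<- c(seen, iri)
  }
  for (iri in names(ctx$definitions)) visit(iri)
}

#' Downward closure of a property under declared sub/equivalent properties
#'
#' Returns every property that entails `property`: itself, declared
#' equivalents, and (transitively) declared subproperties and their
#' equivalents. Data linked through any returned property counts as linked
#' through `property`.
#'
#' @param property property IRI.
#' @param ctx an `ontology_context`.
#' @return character vector of property IRIs.
#' @export
property_closure <- function(property, ctx = NULL) {
  if (is.null(ctx)) return(property)
  out <- property
  repeat {
    more <- c(ctx$subproperties$sub[ctx$subproperties$super %in% out],
              ctx$equivalents$a[ctx$equivalents$b %in% out],
              ctx$equivalents$b[ctx$equivalents$a %in% out])
    new <- setdiff(more, out)
    if (length(new) == 0L) break
    out <- c(out, new)
  }
  out
}

# does prop_specific entail prop_general (sub or equivalent)?
property_entails <- function(prop_specific, prop_general, ctx) {
  prop_specific %in% property_closure(prop_general, ctx)
}

xsd_for_base <- function(base) {
  switch(base,
         string = c(XSD$string),
         int = c(XSD$int, XSD$integer, XSD$long),
         double = c(XSD$double, XSD$float, XSD$decimal,
                    XSD$int, XSD$integer, XSD$long),  # ints are numbers
         character(0))
}

#' Closed-world instance check
#'
#' Evaluates a class expression against a node of an RDF graph. A named class
#' holds if asserted by `rdf:type` or if its definition in `ctx` holds; an
#' existential restriction holds if some object reachable through the
#' property (or any declared sub/equivalent property) satisfies the filler; a
#' datatype restriction holds if some literal with a compatible datatype
#' satisfies every facet. Absent triples make restrictions fail (the planner
#' materializes service outputs before classification).
#'
#' @param g an [rdf_graph()].
#' @param node encoded IRI term.
#' @param expr a `class_expr` (or expression text, parsed with `ctx` labels).
#' @param ctx an `ontology_context`.
#' @return logical.
#' @export
is_instance <- function(g, node, expr, ctx = ontology_context()) {
  if (is.character(expr)) expr <- parse_class_expression(expr, ctx$labels)
  eval_expr(g, node, expr, ctx, active = character(0))
}

eval_expr <- function(g, node, expr, ctx, active) {
  v <- vocab()
  switch(expr$kind,
    named = {
      if (rdf_contains(g, node, iri(v$rdf_type), iri(expr$iri))) return(TRUE)
      def <- ctx$definitions[[expr$iri]]
      if (is.null(def) || expr$iri %in% active) return(FALSE)
      eval_expr(g, node, def, ctx, active = c(active, expr$iri))
    },
    and = all(vapply(expr$parts, function(p)
      eval_expr(g, node, p, ctx, active), TRUE)),
    some = {
      preds <- property_closure(expr$property, ctx)
      objs <- rdf_match(g, s = node, p = paste0("<", preds, ">"))$o
      objs <- objs[!startsWith(objs, "\"")]
      any(vapply(objs, function(o)
        eval_expr(g, o, expr$filler, ctx, active), TRUE))
    },
    data_some = {
      preds <- property_closure(expr$property, ctx)
      objs <- rdf_match(g, s = node, p = paste0("<", preds, ">"))$o
      lits <- objs[startsWith(objs, "\"")]
      ok_types <- xsd_for_base(expr$base)
      any(vapply(lits, function(l) {
        if (!(lit_datatype(l) %in% ok_types)) return(FALSE)
        val <- lit_value(l)
        if (length(expr$facets) == 0L) return(TRUE)
        facet_satisfied(val, expr$facets)
      }, TRUE))
    },
    data = stop("bare datatype expression cannot classify a node", call. = FALSE),
    stop("unknown expression kind: ", expr$kind, call. = FALSE)
  )
}

#' Structural subsumption between class expressions
#'
#' `subsumes(general, specific)` is `TRUE` when every conjunct of the general
#' expression (after expanding named-class definitions) is matched by a
#' conjunct of the specific expression: named classes by equality,
#' existential restrictions by a restriction on an entailing (sub/equivalent)
#' property whose filler is subsumed, and datatype restrictions when the
#' specific facets imply the general ones. Sound but incomplete for the full
#' OWL semantics; exact for the conjunctive-existential fragment services use.
#'
#' @param general,specific `class_expr` objects or expression text.
#' @param ctx an `ontology_context`.
#' @return logical.
#' @export
subsumes <- function(general, specific, ctx = ontology_context()) {
  if (is.character(general)) general <- parse_class_expression(general, ctx$labels)
  if (is.character(specific)) specific <- parse_class_expression(specific, ctx$labels)
  gen <- expand_conjuncts(general, ctx, character(0))
  spec <- expand_conjuncts(specific, ctx, character(0))
  all(vapply(gen, function(gc)
    any(vapply(spec, function(sc) conjunct_covers(gc, sc, ctx), TRUE)), TRUE))
}

# flatten an expression to a list of primitive conjuncts, expanding defined
# named classes (the named conjunct itself is kept too, so asserted types match)
expand_conjuncts <- function(expr, ctx, active) {
  switch(expr$kind,
         and = do.call(c, lapply(expr$parts, expand_conjuncts, ctx, active)),
         named = {
           def <- ctx$definitions[[expr$iri]]
           if (is.null(def) || expr$iri %in% active) list(expr)
           else c(list(expr),
                  expand_conjuncts(def, ctx, c(active, expr$iri)))
         },
         list(expr))
}

conjunct_covers <- function(gen, spec, ctx) {
  if (gen$kind == "named") {
    if (spec$kind != "named") return(FALSE)
    if (identical(gen$iri, spec$iri)) return(TRUE)
    # a defined specific class covers the general named class when the
    # general name appears among its expanded conjuncts
    def <- ctx$definitions[[spec$iri]]
    if (is.null(def)) return(FALSE)
    any(vapply(expand_conjuncts(def, ctx, spec$iri), function(c2)
      conjunct_covers(gen, c2, ctx), TRUE))
  } else if (gen$kind == "some") {
    if (spec$kind != "some") return(FALSE)
    property_entails(spec$property, gen$property, ctx) &&
      subsumes(gen$filler, spec$filler, ctx)
  } else if (gen$kind == "data_some") {
    if (spec$kind != "data_some") return(FALSE)
    property_entails(spec$property, gen$property, ctx) &&
      base_subsumes(gen$base, spec$base) &&
      facets_imply(spec$facets, gen$facets)
  } else FALSE
}

base_subsumes <- function(gen, spec) {
  gen == spec || (gen == "double" && spec == "int")
}

# do the specific facets imply every general facet?
facets_imply <- function(spec, gen) {
  all(vapply(gen, function(gf) {
    any(vapply(spec, function(sf) facet_implies(sf, gf), TRUE))
  }, TRUE))
}

facet_implies <- function(sf, gf) {
  upper <- c("maxInclusive", "maxExclusive")
  if (gf$kind %in% upper) {
    if (!(sf$kind %in% upper)) return(FALSE)
    if (sf$bound < gf$bound) return(TRUE)
    if (sf$bound == gf$bound)
      return(gf$kind == "maxInclusive" || sf$kind == "maxExclusive")
    return(FALSE)
  }
  lower <- c("minInclusive", "minExclusive")
  if (!(sf$kind %in% lower)) return(FALSE)
  if (sf$bound > gf$bound) return(TRUE)
  if (sf$bound == gf$bound)
    return(gf$kind == "minInclusive" || sf$kind == "minExclusive")
  FALSE
}
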