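#' Annotative services
#'
#' A service is the unit of matchmaking: it consumes an RDF graph containing
#' at least one instance of its input class and returns the same graph plus
#' annotations — an attribute instance of the produced type attached through
#' the service's attachment property, and an `rdf:type` assertion into the
#' output class. The input class always subsumes the output class (checked at
#' registration), which is what makes services stateless, atomic and
#' annotative.
#'
#' @param name short service name (unique within a registry).
#' @param input_class,output_class named-class IRIs resolvable in `ctx`.
#' @param attachment_property property IRI used to attach the annotation.
#' @param produced_types character vector of attribute-type IRIs the service
#'   can produce.
#' @param value_kind `"integer"`, `"double"` or `"string"`.
#' @param compute `function(molgraph) -> value` for descriptor-style services
#'   (may be `NULL` when `annotate_fn` is given).
#' @param annotate_fn optional `function(g, node, ctx, service) -> rdf_graph`
#'   overriding the default descriptor annotation.
#' @param parameter_default optional default parameter value (numeric) for
#'   parameterized services.
#' @param software `c(name =, version =)` recorded in provenance.
#' @return a `service_description`.
#' @export
service_description <- function(name, input_class, output_class,
                                attachment_property, produced_types,
                                value_kind = "double", compute = NULL,
                                annotate_fn = NULL, parameter_default = NULL,
                                software = c(name = "semdesc", version = "0.1.0")) {
  structure(list(name = name,
                 iri = paste0("http://semanticscience.org/sadi/service/", name),
                 input_class = input_class, output_class = output_class,
                 attachment_property = attachment_property,
                 produced_types = produced_types, value_kind = value_kind,
                 compute = compute, annotate_fn = annotate_fn,
                 parameter_default = parameter_default, software = software),
            class = "service_description")
}

#' @export
print.service_description <- function(x, ...) {
  cat(sprintf("<service> %s\n  input:  %s\n  output: %s\n  produces: %s\n",
              x$name, local_name(x$input_class), local_name(x$output_class),
              paste(vapply(x$produced_types, local_name, ""), collapse = ", ")))
  invisible(x)
}

#' Service registries
#'
#' An ordered collection of service descriptions sharing one ontology
#' context. Registration enforces the annotative-service invariant: the input
#' class must subsume the output class.
#'
#' @param ctx an `ontology_context` (default: the bundled service ontology).
#' @return a `service_registry`.
#' @export
service_registry <- function(ctx = load_ontology()) {
  structure(list(services = list(), ctx = ctx), class = "service_registry")
}

#' @rdname service_registry
#' @param registry a `service_registry`.
#' @param service a `service_description`.
#' @export
register <- function(registry, service) {
  stopifnot(inherits(registry, "service_registry"),
            inherits(service, "service_description"))
  if (service$iri %in% vapply(registry$services, `[[`, "", "iri"))
    stop("service IRI already registered: ", service$iri, call. = FALSE)
  ctx <- registry$ctx
  if (!subsumes(ce_named(service$input_class), ce_named(service$output_class), ctx))
    stop(sprintf("registration rejected: input class %s does not subsume output class %s",
                 local_name(service$input_class), local_name(service$output_class)),
         call. = FALSE)
  registry$services[[service$name]] <- service
  registry
}

#' @rdname service_registry
#' @param name service name.
#' @export
get_service <- function(registry, name) {
  svc <- registry$services[[name]]
  if (is.null(svc)) stop("unknown service: ", name, call. = FALSE)
  svc
}

#' Semantic description of a service (the GET contract)
#'
#' @param registry a `service_registry`.
#' @param name registered service name.
#' @return an [rdf_graph()] naming the input class, output class, attachment
#'   property, produced attribute types and (if any) the parameter class.
#' @export
describe <- function(registry, name) {
  svc <- get_service(registry, name)
  v <- vocab()
  lso <- function(x) iri(paste0(NS$lso, x))
  g <- rdf_graph()
  s <- iri(svc$iri)
  g <- rdf_add(g, s, iri(v$rdf_type), lso("Service"))
  g <- rdf_add(g, s, iri(v$rdfs_label), lit(svc$name))
  g <- rdf_add(g, s, lso("inputClass"), iri(svc$input_class))
  g <- rdf_add(g, s, lso("outputClass"), iri(svc$output_class))
  g <- rdf_add(g, s, lso("attachmentProperty"), iri(svc$attachment_property))
  for (ty in svc$produced_types)
    g <- rdf_add(g, s, lso("producedAttributeType"), iri(ty))
  if (!is.null(svc$parameter_default)) {
    g <- rdf_add(g, s, lso("parameterClass"), iri(v$parameter))
    g <- rdf_add(g, s, lso("parameterDefault"), lit(as.numeric(svc$parameter_default)))
  }
  g <- rdf_add(g, s, iri(v$software_name), lit(svc$software[["name"]]))
  g <- rdf_add(g, s, iri(v$software_version), lit(svc$software[["version"]]))
  g
}

#' Find services producing a given annotation
#'
#' Matches every registered service whose attachment property entails the
#' requested property (itself, a declared subproperty or an equivalent) and
#' whose produced attribute types include the requested type.
#'
#' @param registry a `service_registry`.
#' @param property attachment property IRI.
#' @param attribute_type produced attribute-type IRI.
#' @param ctx ontology context (defaults to the registry's).
#' @return list of `service_description`s, in registration order.
#' @export
find_services_producing <- function(registry, property, attribute_type,
                                    ctx = registry$ctx) {
  Filter(function(svc) {
    svc$attachment_property %in% property_closure(property, ctx) &&
      attribute_type %in% svc$produced_types
  }, registry$services)
}

# literal for a computed descriptor value
descriptor_literal <- function(value, value_kind) {
  switch(value_kind,
         integer = lit(as.integer(value)),
         double = lit(as.numeric(value), XSD$double),
         string = lit(as.character(value)),
         stop("unknown value kind: ", value_kind, call. = FALSE))
}

# SMILES string carried by a node (first attribute of the SMILES type)
node_smiles <- function(g, node, ctx = NULL) {
  v <- vocab()
  closure <- property_closure(v$has_attribute, ctx)
  attrs <- get_attributes(g, node, v$smiles_descriptor, closure = closure)
  if (length(attrs) == 0L) return(NULL)
  lit_lexical(attrs[[1]]$value)
}

# attach one descriptor annotation, materializing superproperty triples so
# data written through hasChemicalDescriptor also answers has-attribute queries
annotate_with_value <- function(g, node, svc, value_term, ctx) {
  v <- vocab()
  res <- add_attribute(g, node, svc$produced_types[[1]], value_term,
                       property = svc$attachment_property)
  g <- res$graph
  for (p in setdiff(property_superclosure(svc$attachment_property, ctx),
                    svc$attachment_property))
    g <- rdf_add(g, node, iri(p), res$attribute)
  g <- rdf_add(g, node, iri(v$rdf_type), iri(svc$output_class))
  g <- rdf_add(g, node, iri(v$rdf_type), iri(svc$input_class))
  list(graph = g, attribute = res$attribute)
}

default_annotate <- function(g, node, ctx, svc) {
  smi <- node_smiles(g, node, ctx)
  if (is.null(smi))
    stop("no SMILES descriptor on qualifying node ", node, call. = FALSE)
  mol <- parse_smiles(smi)
  value <- svc$compute(mol)
  annotate_with_value(g, node, svc, descriptor_literal(value, svc$value_kind),
                      ctx)$graph
}

#' Invoke a service on an input graph (the POST contract)
#'
#' Every node classified into the service's input class is annotated; the
#' result is a superset of the input graph. Errors if no node qualifies,
#' naming the input class whose restrictions were not met.
#'
#' @param registry a `service_registry`.
#' @param name registered service name.
#' @param input an [rdf_graph()].
#' @param ctx ontology context (defaults to the registry's).
#' @return the annotated [rdf_graph()].
#' @export
invoke <- function(registry, name, input, ctx = registry$ctx) {
  svc <- get_service(registry, name)
  input_expr <- ce_named(svc$input_class)
  nodes <- Filter(function(nd) is_instance(input, nd, input_expr, ctx),
                  rdf_nodes(input))
  if (length(nodes) == 0L)
    stop(sprintf("no instance of input class '%s' in the input graph (restriction unmet: %s)",
                 local_name(svc$input_class),
                 format(ctx$definitions[[svc$input_class]] %||%
                          ce_named(svc$input_class))),
         call. = FALSE)
  fn <- svc$annotate_fn %||2% default_annotate
  for (nd in nodes) input <- fn(input, nd, ctx, svc)
  input
}

`%||2%` <- function(a, b) if (is.null(a)) b else a

#' Invoke a parameterized service
#'
#' Same contract as [invoke()], plus parameter handling: an explicit
#' parameter instance (`rdf:type` SIO_000144 with a value) in the input graph
#' controls the computation; otherwise the service's internal default is
#' used. Either way the parameter value is reported in the output, linked to
#' a parameterized-data-transformation process node that the produced
#' descriptor references through the output-of property, together with the
#' software name and version.
#'
#' @inheritParams invoke
#' @export
invoke_parameterized <- function(registry, name, input, ctx = registry$ctx) {
  invoke(registry, name, input, ctx)
}

# annotation routine for the scaled-logP service
parameterized_logp_annotate <- function(g, node, ctx, svc) {
  v <- vocab()
  smi <- node_smiles(g, node, ctx)
  if (is.null(smi))
    stop("no SMILES descriptor on qualifying node ", node, call. = FALSE)
  mol <- parse_smiles(smi)
  # explicit parameter instance, if any
  params <- rdf_match(g, p = iri(v$rdf_type), o = iri(v$parameter))$s
  param_value <- NULL
  param_node <- NULL
  for (pn in params) {
    vals <- rdf_match(g, s = pn, p = iri(v$has_value))$o
    vals <- vals[startsWith(vals, "\"")]
    if (length(vals) == 0L) next
    pv <- suppressWarnings(as.numeric(lit_lexical(vals[[1]])))
    if (is.na(pv))
      stop("parameter value is not parseable as double: ",
           lit_lexical(vals[[1]]), call. = FALSE)
    param_value <- pv
    param_node <- pn
    break
  }
  if (is.null(param_value)) {
    param_value <- svc$parameter_default
    param_node <- iri(paste0(iri_value(node), "#parameter-default"))
  }
  value <- logp(mol, scale = param_value)
  res <- annotate_with_value(g, node, svc, lit(value, XSD$double), ctx)
  g <- res$graph
  pdt <- iri(paste0(iri_value(node), "#PDT-logP-",
                    content_hash(paste0(smi, "|", param_value))))
  g <- rdf_add(g, res$attribute, iri(v$is_output_of), pdt)
  g <- rdf_add(g, pdt, iri(v$rdf_type), iri(v$pdt))
  g <- rdf_add(g, pdt, iri(v$has_parameter), param_node)
  g <- rdf_add(g, param_node, iri(v$rdf_type), iri(v$parameter))
  g <- rdf_add(g, param_node, iri(v$has_value), lit(param_value, XSD$double))
  g <- rdf_add(g, pdt, iri(v$software_name), lit(svc$software[["name"]]))
  g <- rdf_add(g, pdt, iri(v$software_version), lit(svc$software[["version"]]))
  g
}

# annotation routine for the functional-group annotator
functional_group_annotate <- function(g, node, ctx, svc) {
  v <- vocab()
  smi <- node_smiles(g, node, ctx)
  if (is.null(smi))
    stop("no SMILES descriptor on qualifying node ", node, call. = FALSE)
  mol <- parse_smiles(smi)
  hits <- detect_functional_groups(mol)
  group_class <- function(grp) paste0(NS$lso, fg_class_names[[grp]])
  counter <- 0L
  for (h in hits) {
    counter <- counter + 1L
    inst <- iri(paste0(iri_value(node), "#fg-", h$group, "-",
                       paste(h$atom_indices, collapse = "_")))
    g <- rdf_add(g, node, iri(v$has_proper_part), inst)
    g <- rdf_add(g, inst, iri(v$rdf_type), iri(group_class(h$group)))
    g <- rdf_add(g, inst, iri(v$rdf_type), iri(v$functional_group))
  }
  g <- rdf_add(g, node, iri(v$rdf_type), iri(svc$output_class))
  g <- rdf_add(g, node, iri(v$rdf_type), iri(svc$input_class))
  g
}

fg_class_names <- c(hydroxyl = "Hydroxyl_Group", carbonyl = "Carbonyl_Group",
                    carboxyl = "Carboxyl_Group",
                    primary_amine = "Primary_Amine_Group",
                    alkene = "Alkene_Group", alkyne = "Alkyne_Group",
                    aromatic_ring = "Aromatic_Ring_Group",
                    alkyl = "Alkyl_Group")

# annotation routine for the format converter (backend injectable)
converter_annotate_factory <- function(backend) {
  function(g, node, ctx, svc) {
    v <- vocab()
    if (is.null(backend))
      stop("no conversion backend injected for service '", svc$name, "'",
           call. = FALSE)
    closure <- property_closure(v$has_attribute, ctx)
    attrs <- get_attributes(g, node, v$inchi_descriptor, closure = closure)
    if (length(attrs) == 0L)
      stop("no InChI descriptor on qualifying node ", node, call. = FALSE)
    smi <- backend(lit_lexical(attrs[[1]]$value))
    annotate_with_value(g, node, svc, lit(smi, XSD$string), ctx)$graph
  }
}

#' The built-in service registry
#'
#' One annotative service per registered descriptor, the parameterized
#' (scaled) logP service, the functional-group annotator and a format
#' converter adapter (InChI to SMILES) whose conversion backend is
#' injectable; with no backend the converter's description is still served
#' but invocation errors.
#'
#' @param ctx an `ontology_context`.
#' @param inchi_backend optional `function(inchi_string) -> smiles_string`.
#' @return a `service_registry`.
#' @export
builtin_registry <- function(ctx = load_ontology(), inchi_backend = NULL) {
  v <- vocab()
  reg <- service_registry(ctx)
  lso_class <- function(x) paste0(NS$lso, x)
  for (spec in descriptor_registry()) {
    out_class <- lso_class(paste0(gsub("[^a-z]", "", tolower(spec$label)),
                                  "smilesmolecule"))
    svc <- service_description(
      name = paste0(gsub("[^a-z]", "", tolower(spec$label)), "-calculator"),
      input_class = v$smilesmolecule, output_class = out_class,
      attachment_property = v$has_chemical_descriptor,
      produced_types = spec$id, value_kind = spec$value_kind,
      compute = spec$fun)
    reg <- register(reg, svc)
  }
  reg <- register(reg, service_description(
    name = "scaledlogp-calculator",
    input_class = v$smilesmolecule,
    output_class = lso_class("parameterizedlogpsmilesmolecule"),
    attachment_property = v$has_chemical_descriptor,
    produced_types = v$param_logp, value_kind = "double",
    annotate_fn = parameterized_logp_annotate, parameter_default = 1.0))
  reg <- register(reg, service_description(
    name = "functionalgroup-annotator",
    input_class = v$smilesmolecule,
    output_class = v$annotatedsmilesmolecule,
    attachment_property = v$has_proper_part,
    produced_types = unname(paste0(NS$lso, fg_class_names)),
    value_kind = "string",
    annotate_fn = functional_group_annotate))
  reg <- register(reg, service_description(
    name = "inchi-to-smiles",
    input_class = v$inchimolecule,
    output_class = lso_class("smilesinchimolecule"),
    attachment_property = v$has_attribute,
    produced_types = v$smiles_descriptor, value_kind = "string",
    annotate_fn = converter_annotate_factory(inchi_backend)))
  reg
}
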