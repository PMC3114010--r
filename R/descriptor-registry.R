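#' Registry of descriptor specifications
#'
#' One spec per in-scope descriptor: a stable attribute-type IRI, a
#' human-readable label, the value kind (`integer`, `double` or `string`) and
#' the computation over a `molgraph`. Identifiers published in the CHEMINF
#' vocabulary (bond count, hydrogen-bond donor count) are used where they
#' exist; the rest are package defaults in the service-ontology namespace.
#'
#' @return named list of specs keyed by attribute-type IRI; each spec has
#'   `id`, `label`, `value_kind`, `fun`.
#' @export
descriptor_registry <- function() {
  v <- vocab()
  specs <- list(
    list(id = v$atom_count, label = "Atom Count", value_kind = "integer",
         fun = function(g) count_descriptor(g, "atoms")),
    list(id = v$heavy_atom_count, label = "Heavy Atom Count",
         value_kind = "integer",
         fun = function(g) count_descriptor(g, "heavy_atoms")),
    list(id = v$bond_count, label = "Bond Count", value_kind = "integer",
         fun = function(g) count_descriptor(g, "bonds")),
    list(id = v$aromatic_atom_count, label = "Aromatic Atom Count",
         value_kind = "integer",
         fun = function(g) count_descriptor(g, "aromatic_atoms")),
    list(id = v$hbd_count, label = "Hydrogen Bond Donor Count",
         value_kind = "integer",
         fun = function(g) count_descriptor(g, "hbd")),
    list(id = v$hba_count, label = "Hydrogen Bond Acceptor Count",
         value_kind = "integer",
         fun = function(g) count_descriptor(g, "hba")),
    list(id = v$mass_descriptor, label = "Molecular Mass",
         value_kind = "double", fun = molecular_mass),
    list(id = v$molecular_formula, label = "Molecular Formula",
         value_kind = "string", fun = molecular_formula),
    list(id = v$logp_descriptor, label = "XlogP", value_kind = "double",
         fun = function(g) logp(g)),
    list(id = v$zagreb, label = "Zagreb Index", value_kind = "integer",
         fun = function(g) topological_index(g, "zagreb")),
    list(id = v$eccentric_connectivity, label = "Eccentric Connectivity Index",
         value_kind = "integer",
         fun = function(g) topological_index(g, "eccentric_connectivity")),
    list(id = v$wiener_polarity, label = "Wiener Polarity Number",
         value_kind = "integer",
         fun = function(g) topological_index(g, "wiener_polarity")),
    list(id = v$petitjean, label = "Petitjean Number", value_kind = "double",
         fun = function(g) topological_index(g, "petitjean")),
    list(id = v$vadjma, label = "Vertex Adjacency Magnitude",
         value_kind = "double",
         fun = function(g) topological_index(g, "vadjma")),
    list(id = v$largest_chain, label = "Largest Chain", value_kind = "integer",
         fun = function(g) topological_index(g, "largest_chain")),
    list(id = v$largest_pi, label = "Largest PI System", value_kind = "integer",
         fun = function(g) topological_index(g, "largest_pi"))
  )
  ids <- vapply(specs, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate descriptor id in registry", call. = FALSE)
  stats::setNames(specs, ids)
}

#' Compute every registered descriptor for a molecule
#'
#' @param g a `molgraph`.
#' @param only optional character vector of attribute-type IRIs to restrict to.
#' @return data.frame with columns `id`, `label`, `value_kind`, `value`
#'   (character rendering).
#' @export
compute_descriptors <- function(g, only = NULL) {
  reg <- descriptor_registry()
  if (!is.null(only)) reg <- reg[names(reg) %in% only]
  rows <- lapply(reg, function(spec) {
    val <- tryCatch(spec$fun(g), error = function(e) NA)
    data.frame(id = spec$id, label = spec$label, value_kind = spec$value_kind,
               value = if (length(val) == 1L && !is.na(val)) format(val) else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
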