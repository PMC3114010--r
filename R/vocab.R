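# Namespaces and fixed vocabulary.
#
# The SIO/CHEMINF identifiers that appear in the annotation pattern are fixed;
# descriptor types with no published identifier get stable defaults in the
# service-ontology namespace (LSO).

NS <- list(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  xsd  = "http://www.w3.org/2001/XMLSchema#",
  ss   = "http://semanticscience.org/resource/",
  sio  = "http://semanticscience.org/resource/",
  lso  = "http://semanticscience.org/sadi/ontology/lipinskiserviceontology.owl#"
)

XSD <- list(
  string  = paste0(NS$xsd, "string"),
  int     = paste0(NS$xsd, "int"),
  integer = paste0(NS$xsd, "integer"),
  long    = paste0(NS$xsd, "long"),
  double  = paste0(NS$xsd, "double"),
  float   = paste0(NS$xsd, "float"),
  decimal = paste0(NS$xsd, "decimal"),
  boolean = paste0(NS$xsd, "boolean")
)

#' Vocabulary of fixed and default identifiers
#'
#' Returns the IRIs used throughout the annotation pattern: the SIO
#' entity-attribute-value core (`molecule`, `has_attribute`, `has_value`,
#' `parameter`, `is_output_of`), the CHEMINF descriptor types with published
#' identifiers (SMILES descriptor, bond count, hydrogen-bond donor count,
#' parameterized logP) and the package's stable defaults for everything else.
#'
#' @return named list of IRI strings.
#' @export
vocab <- function() .vocab_cache

make_vocab <- function() {
  sio <- function(x) paste0(NS$sio, x)
  lso <- function(x) paste0(NS$lso, x)
  list(
    rdf_type        = paste0(NS$rdf, "type"),
    rdfs_label      = paste0(NS$rdfs, "label"),
    rdfs_subprop    = paste0(NS$rdfs, "subPropertyOf"),
    owl_equivprop   = paste0(NS$owl, "equivalentProperty"),

    molecule        = sio("SIO_011125"),
    has_attribute   = sio("SIO_000008"),
    has_value       = sio("SIO_000300"),
    parameter       = sio("SIO_000144"),
    is_output_of    = sio("SIO_000232"),

    smiles_descriptor = sio("CHEMINF_000018"),
    bond_count        = sio("CHEMINF_000233"),
    hbd_count         = sio("CHEMINF_000244"),
    param_logp        = sio("CHEMINF_000251"),

    has_chemical_descriptor = lso("hasChemicalDescriptor"),
    has_proper_part         = lso("hasProperPart"),
    has_parameter           = lso("hasParameter"),
    software_name           = lso("softwareName"),
    software_version        = lso("softwareVersion"),
    definition              = lso("definition"),
    pdt                     = lso("ParameterizedDataTransformation"),

    # descriptor types without printed identifiers: package defaults
    inchi_descriptor = lso("InChIDescriptor"),
    atom_count       = lso("AtomCount"),
    heavy_atom_count = lso("HeavyAtomCount"),
    aromatic_atom_count = lso("AromaticAtomCount"),
    hba_count        = lso("HydrogenBondAcceptorCount"),
    mass_descriptor  = lso("MassDescriptor"),
    molecular_formula = lso("MolecularFormulaDescriptor"),
    logp_descriptor  = lso("LogPDescriptor"),
    zagreb           = lso("ZagrebIndex"),
    eccentric_connectivity = lso("EccentricConnectivityIndex"),
    wiener_polarity  = lso("WienerPolarityNumber"),
    petitjean        = lso("PetitjeanNumber"),
    vadjma           = lso("VertexAdjacencyMagnitude"),
    largest_chain    = lso("LargestChain"),
    largest_pi       = lso("LargestPiSystem"),
    functional_group = lso("FunctionalGroup"),

    # classes
    smilesmolecule          = lso("smilesmolecule"),
    inchimolecule           = lso("inchimolecule"),
    lipinskismilesmolecule  = lso("lipinskismilesmolecule"),
    annotatedsmilesmolecule = lso("annotatedsmilesmolecule")
  )
}

.vocab_cache <- NULL  # filled below, after make_vocab is defined

default_prefixes <- function() {
  c(rdf = NS$rdf, rdfs = NS$rdfs, owl = NS$owl, xsd = NS$xsd,
    ss = NS$ss, sio = NS$sio, lso = NS$lso)
}

.vocab_cache <- make_vocab()
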