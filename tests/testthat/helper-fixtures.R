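# shared fixtures: ontology context, registries and oracle helpers

the_ctx <- load_ontology()
the_vocab <- vocab()
LSO <- "http://semanticscience.org/sadi/ontology/lipinskiserviceontology.owl#"
lso_iri <- function(x) paste0(LSO, x)

make_registry <- function(...) builtin_registry(the_ctx, ...)

ethanol_graph <- function(entity = "http://semanticscience.org/resource/Ethanol") {
  molecule_to_input_graph(parse_smiles("OCC"), entity)
}

listing_path <- function(name) {
  system.file("extdata", name, package = "semdesc", mustWork = TRUE)
}

lipinski_query_text <- paste(
  "PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>",
  "PREFIX lso: <http://semanticscience.org/sadi/ontology/lipinskiserviceontology.owl#>",
  "select ?s",
  "where { ?s rdf:type lso:lipinskismilesmolecule. }", sep = "\n")

hbd_query_text <- paste(
  "PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>",
  "PREFIX ss: <http://semanticscience.org/resource/>",
  "PREFIX lso: <http://semanticscience.org/sadi/ontology/lipinskiserviceontology.owl#>",
  "select ?s ?value",
  "where {",
  "?s rdf:type lso:smilesmolecule. #S is a molecule with a SMILES descriptor.",
  "?s lso:hasChemicalDescriptor ?attr. #S has a chemical descriptor attr.",
  "?attr rdf:type ss:CHEMINF_000244. #Attr is a H bond donor descriptor.",
  "?attr ss:SIO_000300 ?value. #Attr must have some value.",
  "}", sep = "\n")

# warm-up: exercise the parse/invoke/query path once so that timed blocks
# measure steady-state operation latency, not first-call byte compilation
invisible(tryCatch({
  wreg <- make_registry()
  wl <- parse_turtle(readLines(listing_path("listing1.ttl")), lenient = TRUE)
  wg <- invoke(wreg, "bondcount-calculator", wl)
  get_attributes(wg, iri("http://semanticscience.org/Ethanol"),
                 the_vocab$bond_count,
                 closure = property_closure(the_vocab$has_attribute, the_ctx))
  execute_query(lipinski_query_text, ethanol_graph(), wreg, the_ctx)
  rm(wreg, wl, wg)
}, error = function(e) NULL))

# labelled-graph isomorphism oracle via igraph VF2
mol_isomorphic <- function(g1, g2) {
  if (n_atoms(g1) != n_atoms(g2)) return(FALSE)
  if (nrow(g1$bonds) != nrow(g2$bonds)) return(FALSE)
  label_of <- function(g) paste(g$atoms$element, g$atoms$charge,
                                g$atoms$aromatic, g$atoms$implicit_h)
  labs <- union(label_of(g1), label_of(g2))
  orders <- c("single", "double", "triple", "aromatic")
  to_ig <- function(g) {
    ig <- igraph::make_empty_graph(n = n_atoms(g), directed = FALSE)
    if (nrow(g$bonds) > 0L)
      ig <- igraph::add_edges(ig, rbind(g$bonds$a, g$bonds$b))
    ig
  }
  igraph::isomorphic(to_ig(g1), to_ig(g2), method = "vf2",
                     vertex.color1 = match(label_of(g1), labs),
                     vertex.color2 = match(label_of(g2), labs),
                     edge.color1 = match(g1$bonds$order, orders),
                     edge.color2 = match(g2$bonds$order, orders))
}

# independent Floyd-Warshall distance oracle on the heavy-atom graph
fw_distances <- function(g) {
  n <- n_atoms(g)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (k in seq_len(nrow(g$bonds))) {
    d[g$bonds$a[k], g$bonds$b[k]] <- 1
    d[g$bonds$b[k], g$bonds$a[k]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# largest-fragment restriction mirroring the documented convention, built
# independently from components of the Floyd-Warshall matrix
fw_largest_fragment_matrix <- function(g) {
  d <- fw_distances(g)
  n <- nrow(d)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    comp[is.finite(d[i, ])] <- cid
  }
  keep <- which(comp == which.max(tabulate(comp)))
  list(d = d[keep, keep, drop = FALSE], keep = keep)
}
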