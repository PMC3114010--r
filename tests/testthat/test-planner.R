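test_that("the query parser covers the supported subset and rejects the rest", {
  q <- parse_query(paste(
    "PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>",
    "PREFIX ss: <http://semanticscience.org/resource/>",
    "PREFIX lso: <http://semanticscience.org/sadi/ontology/lipinskiserviceontology.owl#>",
    "select ?s ?value",
    "FROM <http://semanticscience.org/sadi/ontology/lipinskiserviceontology.owl>",
    "FROM <lipinski_test.rdf>",
    "where {",
    "?s rdf:type lso:smilesmolecule. #S is a molecule with a SMILES descriptor.",
    "?s lso:hasChemicalDescriptor ?attr. #S has a chemical descriptor attr.",
    "?attr rdf:type ss:CHEMINF_000244. #Attr is a H-bond donor descriptor.",
    "?attr ss:SIO_000300 ?value. #Attr must have some value.",
    "}", sep = "\n"))
  expect_equal(q$select, c("s", "value"))
  expect_equal(nrow(q$pattern), 4L)
  expect_length(q$from, 2L)
  expect_equal(q$pattern$p[1],
               "<http://www.w3.org/1999/02/22-rdf-syntax-ns#type>")
  expect_equal(q$pattern$o[3],
               "<http://semanticscience.org/resource/CHEMINF_000244>")

  q4 <- parse_query(lipinski_query_text)
  expect_equal(nrow(q4$pattern), 1L)
  expect_equal(q4$select, "s")

  expect_error(parse_query("select ?s where { OPTIONAL { ?s ?p ?o } }"),
               "unsupported SPARQL feature")
  expect_error(parse_query("select ?s where { ?s ?p ?o FILTER(?o > 1) }"),
               "unsupported SPARQL feature")
  expect_error(parse_query("select ?x where { ?s ?p ?o . }"),
               "not in pattern")
})

test_that("planning discharges exactly the unmet restrictions", {
  reg <- make_registry()
  data <- ethanol_graph()
  # one unmet restriction: the HBD descriptor
  p1 <- plan(parse_query(hbd_query_text), data, reg, the_ctx)
  expect_equal(vapply(p1$steps, `[[`, "", "service"),
               "hydrogenbonddonorcount-calculator")
  # drug-likeness needs the four descriptor services, any order
  p4 <- plan(parse_query(lipinski_query_text), data, reg, the_ctx)
  expect_setequal(vapply(p4$steps, `[[`, "", "service"),
                  c("molecularmass-calculator",
                    "hydrogenbonddonorcount-calculator",
                    "hydrogenbondacceptorcount-calculator",
                    "xlogp-calculator"))
  # a query answerable from the data alone yields an empty plan
  answered <- invoke(reg, "hydrogenbonddonorcount-calculator", data)
  p0 <- plan(parse_query(hbd_query_text), answered, reg, the_ctx)
  expect_length(p0$steps, 0L)
  # determinism
  p4b <- plan(parse_query(lipinski_query_text), data, reg, the_ctx)
  expect_identical(p4, p4b)
})

test_that("a converter is planned before the descriptor that needs SMILES", {
  reg <- builtin_registry(the_ctx, inchi_backend = function(x) sub("^FAKE:", "", x))
  v <- the_vocab
  ent <- "http://x.org/inchimol"
  g <- rdf_add(rdf_graph(), iri(ent), iri(v$rdf_type), iri(v$molecule))
  g <- add_attribute(g, iri(ent), v$inchi_descriptor, lit("FAKE:OCC"))$graph
  p <- plan(parse_query(hbd_query_text), g, reg, the_ctx)
  services <- vapply(p$steps, `[[`, "", "service")
  expect_true("inchi-to-smiles" %in% services)
  expect_lt(which(services == "inchi-to-smiles"),
            which(services == "hydrogenbonddonorcount-calculator"))
  res <- execute_query(parse_query(hbd_query_text), g, reg, the_ctx)
  expect_equal(nrow(res$bindings), 1L)
  expect_equal(lit_value(res$bindings$value), 1L)
})

test_that("executing the donor-count query returns the ethanol value", {
  reg <- make_registry()
  res <- execute_query(hbd_query_text, ethanol_graph(), reg, the_ctx)
  expect_equal(nrow(res$bindings), 1L)
  expect_equal(res$bindings$s,
               iri("http://semanticscience.org/resource/Ethanol"))
  expect_equal(lit_value(res$bindings$value), 1L)
})

test_that("the drug-likeness query returns molecules meeting all criteria", {
  reg <- make_registry()
  res <- execute_query(lipinski_query_text, ethanol_graph(), reg, the_ctx)
  expect_equal(nrow(res$bindings), 1L)
  expect_equal(res$bindings$s,
               iri("http://semanticscience.org/resource/Ethanol"))
  # constructed single-criterion failures return zero rows
  for (cs in lipinski_counterexamples(seed = 11)) {
    r <- execute_query(lipinski_query_text, cs$graph, reg, the_ctx)
    expect_equal(nrow(r$bindings), if (cs$expected) 1L else 0L,
                 label = paste("case", cs$label))
  }
})

test_that("unsatisfiable restrictions are reported, not silently dropped", {
  reg <- make_registry()  # no InChI backend; still no service for unknown types
  q <- parse_query(paste(
    "PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>",
    "PREFIX x: <http://x.org/>",
    "select ?s ?attr",
    "where { ?s rdf:type <http://semanticscience.org/resource/SIO_011125> .",
    "?s <http://semanticscience.org/resource/SIO_000008> ?attr .",
    "?attr rdf:type x:UnknownDescriptor . }", sep = "\n"))
  p <- plan(q, ethanol_graph(), reg, the_ctx)
  expect_length(p$steps, 0L)
  expect_match(p$unsatisfiable, "UnknownDescriptor")
})

test_that("saturation reaches a fixpoint that carries every descriptor", {
  reg <- make_registry()
  sat <- saturate(ethanol_graph(), reg, the_ctx)
  eth <- iri("http://semanticscience.org/resource/Ethanol")
  closure <- property_closure(the_vocab$has_attribute, the_ctx)
  attrs <- get_attributes(sat, eth, type = NULL, closure = closure)
  produced <- unique(unlist(lapply(attrs, `[[`, "type")))
  expect_gte(length(setdiff(produced, the_vocab$smiles_descriptor)), 15L)
  # fixpoint: saturating again adds nothing
  expect_true(rdf_equal(sat, saturate(sat, reg, the_ctx)))
  # empty graph unchanged
  expect_equal(rdf_size(saturate(rdf_graph(), reg, the_ctx)), 0L)
})

test_that("execution agrees with the saturation oracle on randomized cases", {
  reg <- make_registry()
  v <- the_vocab
  descriptor_types <- c(v$bond_count, v$hbd_count, v$hba_count,
                        lso_iri("MassDescriptor"), lso_iri("ZagrebIndex"),
                        lso_iri("WienerPolarityNumber"), lso_iri("AtomCount"),
                        lso_iri("LargestChain"))
  mols <- random_molecules(40, seed = 303, n_atoms = c(2L, 8L))
  set.seed(909)
  for (i in seq_along(mols)) {
    ent_iri <- paste0("http://x.org/sat", i)
    data <- molecule_to_input_graph(mols[[i]], ent_iri)
    ty <- sample(descriptor_types, 1)
    q <- parse_query(paste0(
      "PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>\n",
      "select ?s ?value\nwhere {\n",
      "?s rdf:type <", lso_iri("smilesmolecule"), "> .\n",
      "?s <", v$has_attribute, "> ?attr .\n",
      "?attr rdf:type <", ty, "> .\n",
      "?attr <", v$has_value, "> ?value . }"))
    res <- execute_query(q, data, reg, the_ctx)
    oracle <- evaluate_bgp(q, saturate(data, reg, the_ctx), the_ctx)
    oracle <- unique(oracle[, q$select, drop = FALSE])
    rownames(oracle) <- NULL
    expect_equal(nrow(res$bindings), nrow(oracle), label = paste("case", i))
    if (nrow(oracle) > 0L) {
      key <- function(df) sort(do.call(paste, df))
      expect_equal(key(res$bindings), key(oracle), label = paste("case", i))
    }
  }
})

test_that("returned plans are minimal for the four-service query", {
  reg <- make_registry()
  data <- ethanol_graph()
  q <- parse_query(lipinski_query_text)
  p <- plan(q, data, reg, the_ctx)
  expect_length(p$steps, 4L)
  full <- execute_query(q, data, reg, the_ctx)$bindings
  expect_equal(nrow(full), 1L)
  # dropping any single step loses the binding
  for (drop in seq_along(p$steps)) {
    g <- data
    for (step in p$steps[-drop]) g <- invoke(reg, step$service, g, the_ctx)
    partial <- evaluate_bgp(q, g, the_ctx)
    expect_equal(nrow(partial), 0L, label = paste("without step", drop))
  }
})

test_that("every returned binding satisfies the pattern on the final graph", {
  reg <- make_registry()
  res <- execute_query(hbd_query_text, ethanol_graph(), reg, the_ctx)
  q <- parse_query(hbd_query_text)
  again <- evaluate_bgp(q, res$graph, the_ctx)
  expect_true(nrow(again) >= nrow(res$bindings))
  for (k in seq_len(nrow(res$bindings))) {
    hit <- merge(res$bindings[k, , drop = FALSE], again)
    expect_equal(nrow(hit), 1L)
  }
})
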