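test_that("the built-in registry is complete and annotative", {
  reg <- make_registry()
  expect_gte(length(reg$services), 17L)
  expect_error(get_service(reg, "no-such-service"), "unknown service")
  # every built-in service satisfies the subsumption invariant on its classes
  for (svc in reg$services) {
    expect_true(subsumes(svc$input_class, svc$output_class, the_ctx),
                label = paste("subsumption for", svc$name))
  }
})

test_that("registration rejects services violating subsumption", {
  reg <- service_registry(the_ctx)
  bad <- service_description(
    name = "backwards", input_class = lso_iri("bondcountsmilesmolecule"),
    output_class = the_vocab$smilesmolecule,
    attachment_property = the_vocab$has_attribute,
    produced_types = the_vocab$bond_count, value_kind = "integer",
    compute = function(g) count_descriptor(g, "bonds"))
  expect_error(register(reg, bad), "does not subsume")
})

test_that("service descriptions are served and round-trip through RDF", {
  reg <- make_registry()
  d <- describe(reg, "bondcount-calculator")
  objs <- rdf_match(d)$o
  expect_true(iri(the_vocab$smilesmolecule) %in% objs)
  expect_true(iri(lso_iri("bondcountsmilesmolecule")) %in% objs)
  expect_true(iri(the_vocab$bond_count) %in% objs)
  for (fmt in c("turtle", "rdfxml")) {
    back <- if (fmt == "turtle") parse_turtle(serialize_graph(d, fmt))
    else parse_rdfxml(serialize_graph(d, fmt))
    expect_true(rdf_equal(d, back))
  }
  expect_error(describe(reg, "unregistered"), "unknown service")
})

test_that("bond-count invocation reproduces the annotation shape", {
  reg <- make_registry()
  l1 <- parse_turtle(readLines(listing_path("listing1.ttl")), lenient = TRUE)
  out <- invoke(reg, "bondcount-calculator", l1)
  v <- the_vocab
  eth <- iri("http://semanticscience.org/Ethanol")
  # monotone: all input triples survive
  expect_true(all(l1$triples %in% out$triples))
  # typing into the output class (and the input class)
  expect_true(rdf_contains(out, eth, iri(v$rdf_type),
                           iri(lso_iri("bondcountsmilesmolecule"))))
  expect_true(rdf_contains(out, eth, iri(v$rdf_type),
                           iri(v$smilesmolecule)))
  # one attribute instance with a typed int value of 2 (heavy-atom bonds)
  attrs <- get_attributes(out, eth, v$bond_count,
                          closure = property_closure(v$has_attribute, the_ctx))
  expect_length(attrs, 1L)
  expect_equal(lit_value(attrs[[1]]$value), 2L)
  expect_equal(lit_datatype(attrs[[1]]$value),
               "http://www.w3.org/2001/XMLSchema#int")
  # is_instance witnesses the output class on data
  expect_true(is_instance(out, eth, "bondcountsmilesmolecule", the_ctx))
  expect_true(is_instance(out, eth, "smilesmolecule", the_ctx))

  # idempotent
  out2 <- invoke(reg, "bondcount-calculator", out)
  expect_true(rdf_equal(out, out2))
  # error when nothing qualifies, naming the restriction
  expect_error(invoke(reg, "bondcount-calculator", rdf_graph()),
               "smilesmolecule")
})

test_that("invocation annotates every qualifying node and commutes", {
  reg <- make_registry()
  g <- rdf_union(ethanol_graph("http://x.org/a"),
                 molecule_to_input_graph(parse_smiles("CCO"), "http://x.org/b"))
  out <- invoke(reg, "molecularmass-calculator", g)
  for (ent in c("http://x.org/a", "http://x.org/b")) {
    attrs <- get_attributes(out, iri(ent), lso_iri("MassDescriptor"),
                            closure = property_closure(the_vocab$has_attribute,
                                                       the_ctx))
    expect_length(attrs, 1L)
    expect_equal(lit_value(attrs[[1]]$value), 46.069, tolerance = 1e-9)
  }
  # order independence across distinct services
  ab <- invoke(reg, "hydrogenbonddonorcount-calculator",
               invoke(reg, "molecularmass-calculator", g))
  ba <- invoke(reg, "molecularmass-calculator",
               invoke(reg, "hydrogenbonddonorcount-calculator", g))
  expect_true(rdf_equal(ab, ba))
})

test_that("parameterized logP propagates the input parameter into provenance", {
  reg <- make_registry()
  v <- the_vocab
  l5 <- parse_turtle(readLines(listing_path("listing5.ttl")), lenient = TRUE)
  out <- invoke_parameterized(reg, "scaledlogp-calculator", l5)
  eth <- iri("http://semanticscience.org/Ethanol")
  attrs <- get_attributes(out, eth, v$param_logp,
                          closure = property_closure(v$has_attribute, the_ctx))
  expect_length(attrs, 1L)
  base <- logp(parse_smiles("OCC"))
  expect_equal(lit_value(attrs[[1]]$value), 1.05 * base, tolerance = 1e-9)
  # descriptor -> process -> parameter chain, as in the published output shape
  pdt <- rdf_match(out, s = attrs[[1]]$attribute, p = iri(v$is_output_of))$o
  expect_length(pdt, 1L)
  expect_true(rdf_contains(out, pdt, iri(v$rdf_type), iri(v$pdt)))
  param <- rdf_match(out, s = pdt, p = iri(v$has_parameter))$o
  expect_equal(param, iri("http://semanticscience.org/parameterX"))
  expect_true(rdf_contains(out, param, iri(v$rdf_type), iri(v$parameter)))
  pv <- rdf_match(out, s = param, p = iri(v$has_value))$o
  pv <- pv[vapply(pv, lit_datatype, "") == "http://www.w3.org/2001/XMLSchema#double"]
  expect_equal(lit_value(pv), 1.05)
  # software name and version are recorded
  expect_length(rdf_match(out, s = pdt, p = iri(v$software_name))$o, 1L)
  expect_length(rdf_match(out, s = pdt, p = iri(v$software_version))$o, 1L)
  # the output classifies into the parameterized output class
  expect_true(is_instance(out, eth, "parameterizedlogpsmilesmolecule", the_ctx))
})

test_that("parameterized logP falls back to the reported default", {
  reg <- make_registry()
  v <- the_vocab
  out <- invoke_parameterized(reg, "scaledlogp-calculator", ethanol_graph())
  eth <- iri("http://semanticscience.org/resource/Ethanol")
  attrs <- get_attributes(out, eth, v$param_logp,
                          closure = property_closure(v$has_attribute, the_ctx))
  expect_length(attrs, 1L)
  # default scale 1.0: equals the unparameterized value, and the default is
  # still reported in the output
  expect_equal(lit_value(attrs[[1]]$value), logp(parse_smiles("OCC")),
               tolerance = 1e-12)
  pdt <- rdf_match(out, s = attrs[[1]]$attribute, p = iri(v$is_output_of))$o
  param <- rdf_match(out, s = pdt, p = iri(v$has_parameter))$o
  pv <- rdf_match(out, s = param, p = iri(v$has_value))$o
  expect_equal(lit_value(pv), 1.0)
  # unparseable parameter values error
  bad <- rdf_add(ethanol_graph(), iri("http://x.org/p"), iri(v$rdf_type),
                 iri(v$parameter))
  bad <- rdf_add(bad, iri("http://x.org/p"), iri(v$has_value), lit("not-a-number"))
  expect_error(invoke(reg, "scaledlogp-calculator", bad), "not parseable")
})

test_that("the functional-group annotator attaches proper parts", {
  reg <- make_registry()
  out <- invoke(reg, "functionalgroup-annotator", ethanol_graph())
  eth <- iri("http://semanticscience.org/resource/Ethanol")
  parts <- rdf_match(out, s = eth, p = iri(the_vocab$has_proper_part))$o
  expect_gte(length(parts), 2L)  # hydroxyl + alkyl
  types <- unlist(lapply(parts, function(p)
    rdf_match(out, s = p, p = iri(the_vocab$rdf_type))$o))
  expect_true(iri(lso_iri("Hydroxyl_Group")) %in% types)
  expect_true(iri(lso_iri("Alkyl_Group")) %in% types)
  expect_true(is_instance(out, eth, "annotatedsmilesmolecule", the_ctx))
  # drug-like alkyl compounds: the repurposing expression classifies after
  # saturation
  sat <- saturate(ethanol_graph(), reg, the_ctx)
  expect_true(is_instance(sat, eth,
                          "lipinskismilesmolecule and 'hasProperPart' some Alkyl_Group",
                          the_ctx))
})

test_that("the converter adapter serves its description but needs a backend", {
  reg <- make_registry()
  d <- describe(reg, "inchi-to-smiles")
  expect_true(iri(lso_iri("inchimolecule")) %in% rdf_match(d)$o)
  v <- the_vocab
  inchi_graph <- function(value, ent = "http://x.org/inchimol") {
    g <- rdf_add(rdf_graph(), iri(ent), iri(v$rdf_type), iri(v$molecule))
    add_attribute(g, iri(ent), v$inchi_descriptor, lit(value))$graph
  }
  g <- inchi_graph("FAKE:OCC")
  expect_error(invoke(reg, "inchi-to-smiles", g), "no conversion backend")
  # with an injected backend the output classifies as a SMILES molecule
  reg2 <- builtin_registry(the_ctx, inchi_backend = function(x) sub("^FAKE:", "", x))
  out <- invoke(reg2, "inchi-to-smiles", g)
  expect_true(is_instance(out, iri("http://x.org/inchimol"), "smilesmolecule",
                          the_ctx))
  expect_true(is_instance(out, iri("http://x.org/inchimol"), "smilesinchimolecule",
                          the_ctx))
})

test_that("service outputs keep witnessing input and output classes on fixtures", {
  reg <- make_registry()
  mols <- random_molecules(8, seed = 13, n_atoms = c(2L, 10L))
  some_services <- c("bondcount-calculator", "molecularmass-calculator",
                     "hydrogenbondacceptorcount-calculator", "zagrebindex-calculator")
  for (i in seq_along(mols)) {
    ent_iri <- paste0("http://x.org/f", i)
    g <- molecule_to_input_graph(mols[[i]], ent_iri)
    for (nm in some_services) {
      out <- invoke(reg, nm, g)
      svc <- get_service(reg, nm)
      expect_true(all(g$triples %in% out$triples))
      expect_true(is_instance(out, iri(ent_iri), svc$output_class, the_ctx))
      expect_true(is_instance(out, iri(ent_iri), svc$input_class, the_ctx))
    }
  }
})

test_that("service matchmaking respects the property closure", {
  reg <- make_registry()
  v <- the_vocab
  hits <- find_services_producing(reg, v$has_attribute, v$hbd_count)
  expect_equal(unname(vapply(hits, `[[`, "", "name")), "hydrogenbonddonorcount-calculator")
  # via the equivalent property
  hits2 <- find_services_producing(reg, lso_iri("hatChemischeDeskriptor"),
                                   v$hbd_count)
  expect_equal(unname(vapply(hits2, `[[`, "", "name")), "hydrogenbonddonorcount-calculator")
  expect_length(find_services_producing(reg, v$has_attribute,
                                        "http://x.org/UnknownType"), 0L)
})
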