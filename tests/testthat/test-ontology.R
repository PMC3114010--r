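test_that("class expression parsing mirrors the written syntax", {
  labels <- the_ctx$labels
  v <- the_vocab
  e <- parse_class_expression(
    "molecule and 'has attribute' some ('SMILES descriptor' and 'has value' some string)",
    labels)
  expect_equal(e$kind, "and")
  expect_length(e$parts, 2L)
  expect_equal(e$parts[[1]]$kind, "named")
  expect_equal(e$parts[[1]]$iri, v$molecule)
  expect_equal(e$parts[[2]]$kind, "some")
  expect_equal(e$parts[[2]]$property, v$has_attribute)
  filler <- e$parts[[2]]$filler
  expect_equal(filler$parts[[1]]$iri, v$smiles_descriptor)
  expect_equal(filler$parts[[2]]$kind, "data_some")
  expect_equal(filler$parts[[2]]$base, "string")

  d <- parse_class_expression("double[< = 500.0]")
  expect_equal(d$kind, "data")
  expect_equal(d$facets[[1]]$kind, "maxInclusive")
  expect_equal(d$facets[[1]]$bound, 500.0)

  r <- parse_class_expression("double[< 5.0, > -5.0]")
  expect_equal(vapply(r$facets, `[[`, "", "kind"),
               c("maxExclusive", "minExclusive"))
  expect_equal(vapply(r$facets, `[[`, 0, "bound"), c(5, -5))

  m <- parse_class_expression("molecule", labels)
  expect_equal(m, structure(list(kind = "named", iri = v$molecule),
                            class = "class_expr"))
  expect_error(parse_class_expression("molecule and"), "parse error")
  expect_error(parse_class_expression("int[~ 5]"), "parse error")
})

test_that("facet evaluation honours strict and inclusive bounds", {
  maxi <- list(list(kind = "maxInclusive", bound = 500.0))
  expect_true(facet_satisfied(500.0, maxi))
  expect_false(facet_satisfied(500.1, maxi))
  maxe <- list(list(kind = "maxExclusive", bound = 5))
  expect_false(facet_satisfied(5, maxe))
  expect_true(facet_satisfied(4, maxe))
  both <- list(list(kind = "maxExclusive", bound = 5.0),
               list(kind = "minExclusive", bound = -5.0))
  expect_true(facet_satisfied(0.0, both))
  expect_false(facet_satisfied(-5.0, both))
  expect_false(facet_satisfied("five", maxe))
  expect_true(facet_satisfied(3, list()))
  # monotone in the bound
  for (b in c(1, 2, 10)) {
    expect_true(facet_satisfied(0.5, list(list(kind = "maxExclusive", bound = b))))
  }
})

test_that("instance checking is closed-world over the annotation pattern", {
  v <- the_vocab
  ent <- iri("http://semanticscience.org/resource/Ethanol")
  g <- ethanol_graph()
  expect_true(is_instance(g, ent, "smilesmolecule", the_ctx))
  # annotate a bond count -> bondcountsmilesmolecule holds (Listing-2 shape)
  g2 <- add_attribute(g, ent, v$bond_count, lit(2L))$graph
  expect_true(is_instance(g2, ent, "bondcountsmilesmolecule", the_ctx))
  expect_false(is_instance(g, ent, "bondcountsmilesmolecule", the_ctx))

  # a 501 Da mass fails the Lipinski mass conjunct
  heavy <- add_attribute(g, ent, paste0(LSO, "MassDescriptor"),
                         lit(501.0, "http://www.w3.org/2001/XMLSchema#double"),
                         property = v$has_chemical_descriptor)$graph
  mass_conjunct <- "'hasChemicalDescriptor' some ('mass descriptor' and 'has value' some double[< = 500.0])"
  ok <- add_attribute(g, ent, paste0(LSO, "MassDescriptor"),
                      lit(46.07, "http://www.w3.org/2001/XMLSchema#double"),
                      property = v$has_chemical_descriptor)$graph
  expect_false(is_instance(heavy, ent, mass_conjunct, the_ctx))
  expect_true(is_instance(ok, ent, mass_conjunct, the_ctx))

  # empty graph: nothing is an instance of anything
  expect_false(is_instance(rdf_graph(), ent, "smilesmolecule", the_ctx))
  expect_false(is_instance(rdf_graph(), ent, "molecule", the_ctx))
})

test_that("equivalent properties yield identical classifications", {
  v <- the_vocab
  ent <- iri("http://x.org/m")
  base <- add_attribute(rdf_graph(), ent, v$hbd_count, lit(1L),
                        property = v$has_chemical_descriptor)$graph
  subst <- add_attribute(rdf_graph(), ent, v$hbd_count, lit(1L),
                         property = paste0(LSO, "hatChemischeDeskriptor"))$graph
  expr <- "'hasChemicalDescriptor' some ('hydrogen bond donor count' and 'has value' some int)"
  expect_true(is_instance(base, ent, expr, the_ctx))
  expect_identical(is_instance(subst, ent, expr, the_ctx),
                   is_instance(base, ent, expr, the_ctx))
  # and querying through the German-named equivalent finds English-named data
  expr_de <- "'hatChemischeDeskriptor' some ('hydrogen bond donor count' and 'has value' some int)"
  expect_true(is_instance(base, ent, expr_de, the_ctx))
})

test_that("structural subsumption matches the service class hierarchy", {
  expect_true(subsumes("smilesmolecule", "bondcountsmilesmolecule", the_ctx))
  expect_false(subsumes("bondcountsmilesmolecule", "smilesmolecule", the_ctx))
  expect_true(subsumes("molecule", "smilesmolecule", the_ctx))
  expect_true(subsumes("smilesmolecule", "lipinskismilesmolecule", the_ctx))
  # reflexive
  for (cls in c("molecule", "smilesmolecule", "lipinskismilesmolecule")) {
    expect_true(subsumes(cls, cls, the_ctx))
  }
  # facets: a tighter bound is subsumed by a looser one
  expect_true(subsumes("'has value' some double[< = 500.0]",
                       "'has value' some double[< 400.0]", the_ctx))
  expect_false(subsumes("'has value' some double[< 400.0]",
                        "'has value' some double[< = 500.0]", the_ctx))
  # property specialization: a restriction on a subproperty is more specific
  expect_true(subsumes("'has attribute' some ('bond count' and 'has value' some int)",
                       "'hasChemicalDescriptor' some ('bond count' and 'has value' some int)",
                       the_ctx))
  expect_false(subsumes("'hasChemicalDescriptor' some ('bond count' and 'has value' some int)",
                        "'has attribute' some ('bond count' and 'has value' some int)",
                        the_ctx))
})

test_that("is_instance agrees with a brute-force evaluator on random cases", {
  # exhaustive evaluator: enumerate all property paths explicitly
  brute <- function(g, node, expr, ctx) {
    v <- vocab()
    df <- rdf_match(g)
    switch(expr$kind,
      named = {
        asserted <- any(df$s == node & df$p == iri(v$rdf_type) &
                          df$o == iri(expr$iri))
        if (asserted) return(TRUE)
        def <- ctx$definitions[[expr$iri]]
        if (is.null(def)) return(FALSE)
        brute(g, node, def, ctx)
      },
      and = all(vapply(expr$parts, function(p) brute(g, node, p, ctx), TRUE)),
      some = {
        preds <- property_closure(expr$property, ctx)
        rows <- df[df$s == node & df$p %in% paste0("<", preds, ">"), , drop = FALSE]
        any(vapply(rows$o[!startsWith(rows$o, "\"")], function(o)
          brute(g, o, expr$filler, ctx), TRUE))
      },
      data_some = {
        preds <- property_closure(expr$property, ctx)
        rows <- df[df$s == node & df$p %in% paste0("<", preds, ">"), , drop = FALSE]
        lits <- rows$o[startsWith(rows$o, "\"")]
        ok_types <- switch(expr$base,
                           string = "http://www.w3.org/2001/XMLSchema#string",
                           int = paste0("http://www.w3.org/2001/XMLSchema#",
                                        c("int", "integer", "long")),
                           double = paste0("http://www.w3.org/2001/XMLSchema#",
                                           c("double", "float", "decimal",
                                             "int", "integer", "long")))
        any(vapply(lits, function(l) lit_datatype(l) %in% ok_types &&
                     facet_satisfied(lit_value(l), expr$facets), TRUE))
      })
  }
  v <- the_vocab
  types <- c(v$bond_count, v$hbd_count, paste0(LSO, "MassDescriptor"))
  props <- c(v$has_attribute, v$has_chemical_descriptor,
             paste0(LSO, "hatChemischeDeskriptor"))
  exprs <- c(
    "smilesmolecule",
    "bondcountsmilesmolecule",
    "molecule and 'has attribute' some ('bond count' and 'has value' some int)",
    "'hasChemicalDescriptor' some ('mass descriptor' and 'has value' some double[< = 100.0])",
    "'has attribute' some ('hydrogen bond donor count' and 'has value' some int[< 2])")
  set.seed(42)
  for (rep in seq_len(60)) {
    ent <- iri("http://x.org/m")
    g <- rdf_graph()
    if (stats::runif(1) < 0.7)
      g <- rdf_add(g, ent, iri(v$rdf_type), iri(v$molecule))
    if (stats::runif(1) < 0.7)
      g <- add_attribute(g, ent, v$smiles_descriptor, lit("OCC"))$graph
    for (k in seq_len(sample(0:3, 1))) {
      ty <- sample(types, 1)
      pr <- sample(props, 1)
      val <- if (stats::runif(1) < 0.5) lit(sample(0:6, 1))
      else lit(stats::runif(1, 0, 600), "http://www.w3.org/2001/XMLSchema#double")
      g <- add_attribute(g, ent, ty, val, property = pr)$graph
    }
    for (ex in exprs) {
      expr <- parse_class_expression(ex, the_ctx$labels)
      expect_identical(is_instance(g, ent, expr, the_ctx),
                       brute(g, ent, expr, the_ctx),
                       label = paste("case", rep, ex))
    }
  }
})

test_that("subsumption implies instance containment on random graphs", {
  v <- the_vocab
  pairs <- list(
    c("smilesmolecule", "bondcountsmilesmolecule"),
    c("molecule", "smilesmolecule"),
    c("smilesmolecule", "lipinskismilesmolecule"))
  set.seed(7)
  mols <- random_molecules(15, seed = 7)
  reg <- make_registry()
  for (i in seq_along(mols)) {
    ent_iri <- paste0("http://x.org/m", i)
    g <- molecule_to_input_graph(mols[[i]], ent_iri)
    if (i %% 2 == 0) g <- saturate(g, reg, the_ctx)
    for (p in pairs) {
      expect_true(subsumes(p[1], p[2], the_ctx))
      if (is_instance(g, iri(ent_iri), p[2], the_ctx))
        expect_true(is_instance(g, iri(ent_iri), p[1], the_ctx),
                    label = paste(p[1], "contains", p[2], "for", ent_iri))
    }
  }
})

test_that("definitional cycles among named classes are rejected", {
  a <- parse_class_expression("b", c(b = "http://x.org/b"))
  b <- parse_class_expression("a", c(a = "http://x.org/a"))
  expect_error(ontology_context(definitions = list("http://x.org/a" = a,
                                                   "http://x.org/b" = b)),
               "cycle")
})
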