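Package: semdesc
Title: Semantic QSAR Descriptor Services over RDF Molecular Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained framework for semantic QSAR analysis. Molecular
    descriptors (atom/bond counts, hydrogen-bond donors and acceptors,
    molecular mass and formula, an atomic-contribution logP and a set of
    topological indices) are computed from SMILES strings and exposed as
    annotative services: each service consumes an RDF graph describing a
    molecule, and returns the same graph decorated with a typed
    attribute/value annotation, following an entity-attribute-value pattern
    built on the SIO and CHEMINF vocabularies. Service inputs and outputs are
    described by restricted OWL class expressions (conjunctions of named
    classes, existential restrictions and datatype facets), and a
    backward-chaining planner turns a SPARQL-subset query -- for example, a
    drug-likeness (Lipinski Rule of Five) class membership question -- into
    an executed chain of service invocations. Includes seeded generators for
    random valid molecules and annotation graphs so the whole stack is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
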