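# semdesc — semantic QSAR descriptor services over RDF

`semdesc` is a self-contained R implementation of a semantic web-service
stack for QSAR (quantitative structure–activity relationship) descriptors.
It is aimed at cheminformaticians and semantic-web practitioners who want to
express computational questions about molecules — *is this compound
drug-like?* — as ontology class membership rather than as hand-built
pipelines.

The stack has three layers:

1. **Molecules and descriptors.** A SMILES parser/writer and an attributed
   molecular graph, from which the package computes atom/bond/aromatic-atom
   counts, hydrogen-bond donors and acceptors (Lipinski counting: donors =
   H on N/O, acceptors = N+O), molecular mass and Hill formula, an
   atomic-contribution logP, topological indices (Zagreb Σdeg², eccentric
   connectivity Σdeg·ecc, Wiener polarity |{pairs at distance 3}|, Petitjean
   (D−R)/R, vertex adjacency magnitude 1+log₂m, largest chain, largest
   π-system) and functional-group annotations.
2. **Annotative services.** Each descriptor is wrapped as a service that
   consumes an RDF graph containing a molecule with a SMILES attribute
   (the SIO/CHEMINF entity–attribute–value pattern) and returns the same
   graph plus a typed attribute instance and an `rdf:type` assertion into
   the service's output class. Input classes always subsume output classes;
   a parameterized logP service records its scaling parameter and software
   version as provenance on the value it produces.
3. **Query planning.** A SPARQL-subset engine backward-chains over the
   service registry: the drug-likeness class

   ```
   smilesmolecule
   and 'hasChemicalDescriptor' some ('mass descriptor' and 'has value' some double[< = 500.0])
   and 'hasChemicalDescriptor' some ('hydrogen bond donor count' and 'has value' some int[< 5])
   and 'hasChemicalDescriptor' some ('hydrogen bond acceptor count' and 'has value' some int[< 10])
   and 'hasChemicalDescriptor' some ('logP descriptor' and 'has value' some double[< 5.0, > -5.0])
   ```

   is turned automatically into the four service invocations needed to
   decide membership.

## Worked example

```r
library(semdesc)

ctx <- load_ontology()          # bundled Lipinski service ontology
reg <- builtin_registry(ctx)    # 19 services: 16 descriptors + scaled logP
                                # + functional groups + InChI converter slot

# a molecule enters as an annotation graph
data <- molecule_to_input_graph(parse_smiles("OCC"),
                                "http://semanticscience.org/resource/Ethanol")

query <- '
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX lso: <http://semanticscience.org/sadi/ontology/lipinskiserviceontology.owl#>
select ?s
where { ?s rdf:type lso:lipinskismilesmolecule. }'

res <- execute_query(query, data, reg, ctx)
print(res$plan)
#> <plan> 4 step(s):
#>   1. molecularmass-calculator on <http://semanticscience.org/resource/Ethanol>  [produce MassDescriptor via hasChemicalDescriptor]
#>   2. hydrogenbonddonorcount-calculator on <http://semanticscience.org/resource/Ethanol>  [produce CHEMINF_000244 via hasChemicalDescriptor]
#>   3. hydrogenbondacceptorcount-calculator on <http://semanticscience.org/resource/Ethanol>  [produce HydrogenBondAcceptorCount via hasChemicalDescriptor]
#>   4. xlogp-calculator on <http://semanticscience.org/resource/Ethanol>  [produce LogPDescriptor via hasChemicalDescriptor]
res$bindings
#>                                               s
#> 1 <http://semanticscience.org/resource/Ethanol>
```

The planner decided, from the class definition alone, that mass, donor
count, acceptor count and logP were missing, invoked exactly those four
services, and returned the ethanol IRI because all four computed values meet
the thresholds (mass 46.069 Da ≤ 500; 1 donor < 5; 1 acceptor < 10;
logP 0.3893 ∈ (−5, 5)). A molecule failing any single criterion returns zero
rows.

Descriptors are also available directly:

```r
eth <- parse_smiles("OCC")
count_descriptor(eth, "bonds")   # 2   (bonds between heavy atoms)
molecular_mass(eth)              # 46.069
molecular_formula(eth)           # "C2H6O"
logp(eth)                        # 0.3893
logp(eth, scale = 1.05)          # 0.408765  (parameterized-service contract)
```

A command-line front end lives at `inst/scripts/semdesc.R`:

```sh
Rscript inst/scripts/semdesc.R descriptors --smiles "OCC" --format json
Rscript inst/scripts/semdesc.R describe bondcount-calculator
Rscript inst/scripts/semdesc.R invoke bondcount-calculator --in molecule.ttl
Rscript inst/scripts/semdesc.R query --sparql query.rq --data molecule.ttl
Rscript inst/scripts/semdesc.R fixtures --seed 7 --count 10 --out fixtures/
```

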