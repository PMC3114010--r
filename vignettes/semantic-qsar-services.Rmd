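---
title: "Semantic QSAR descriptor services: model, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic QSAR descriptor services: model, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdesc)
```

## The problem

Computational chemistry tooling is fragmented: descriptor calculators,
format converters and database lookups live in different packages with
incompatible interfaces, so answering a question such as *"is this molecule
drug-like?"* usually means hand-building a pipeline. `semdesc` implements an
alternative organization in which every computation is an **annotative
service**: a pure function that consumes an RDF graph describing a molecule
and returns the *same* graph plus new typed attribute/value triples. Because
each service's input and output are described by formal class expressions, a
planner can treat a SPARQL query — or an ontology class definition such as a
Lipinski drug-likeness class — as a goal and assemble the chain of service
invocations needed to answer it.

Everything here runs in-process and offline. The HTTP verbs of a deployed
service stack (GET a description, POST a graph) map onto `describe()` and
`invoke()`; keeping services as ordinary functions makes the whole stack
testable without a network, and a web layer would be a thin wrapper over the
same contract.

## The annotation pattern

A molecule enters the system as an entity-attribute-value graph built on the
SIO vocabulary:

```
ss:Ethanol rdf:type sio:SIO_011125 .                # a molecule
ss:Ethanol sio:SIO_000008 ss:EthanolSmilesDescriptor .   # has attribute
ss:EthanolSmilesDescriptor rdf:type sio:CHEMINF_000018 . # SMILES descriptor
ss:EthanolSmilesDescriptor sio:SIO_000300 "OCC" .        # has value
```

Every service adds exactly this shape: an attribute node, its type, and its
value, plus an `rdf:type` assertion into the service's output class.
Attribute IRIs are minted deterministically from the entity IRI, the local
name of the attribute type and a content hash of the value, so invoking a
service twice is a no-op and annotation nodes remain stable, dereferenceable
anchors across service chains. Blank nodes are supported by the RDF layer
but never emitted by services, for the same reason.

Identifiers: the annotation core (`SIO_000008` has-attribute, `SIO_000300`
has-value, `SIO_011125` molecule, `SIO_000144` parameter, `SIO_000232`
is-output-of) and the descriptor types with published CHEMINF identifiers
(SMILES descriptor `CHEMINF_000018`, bond count `CHEMINF_000233`,
hydrogen-bond donor count `CHEMINF_000244`, parameterized logP
`CHEMINF_000251`) are fixed. Descriptor types with no published identifier
(mass, acceptor count, the topological indices, functional groups) get
stable defaults in the bundled service-ontology namespace; they are ordinary
IRIs and can be remapped by editing the ontology file.

One vocabulary subtlety is load-bearing. Query patterns and the
drug-likeness class use a dedicated `hasChemicalDescriptor` property, while
plain input data uses the generic has-attribute. The bundled ontology
declares `hasChemicalDescriptor` as a subproperty of has-attribute, and
services *materialize* the superproperty triple whenever they attach an
annotation through the subproperty. Matching then only ever looks downward
through the declared sub/equivalent closure, which keeps evaluation sound
(nothing is inferred that was not written), yet queries phrased with either
property — or with a declared equivalent such as `hatChemischeDeskriptor` —
see the same data.

## Molecules: SMILES dialect and graph conventions

`parse_smiles()` accepts the organic subset (`B C N O S P F Cl Br I`),
aromatic lowercase forms, bracket atoms with isotope/charge/explicit H
counts, branches, ring closures (digits and `%nn`), the bond symbols
`- = # :` and dot-separated fragments. Stereo marks (`@`, `/`, `\`) are
parsed and discarded: every descriptor in scope depends on constitution and
topology only. Output SMILES from `write_smiles()` is not canonical; its
contract is round-tripping — reparsing always yields a labelled graph
isomorphic to the original, which the test suite checks with a VF2
isomorphism oracle.

Implicit hydrogens come from default valences (B 3; C 4; N 3; O 2; P 3 or 5;
S 2, 4 or 6, smallest that fits; halogens 1). Aromatic bonds are counted so
that the universal conventions hold: an aromatic atom with two ring bonds
sums to 3 (benzene carbons get exactly one hydrogen), and a fusion atom with
three aromatic bonds sums to 4 (no hydrogen). Exceeding an element's maximum
valence is a parse error that names the offending atom.

Rings are perceived as a smallest-set-of-smallest-rings: the shortest cycle
through every edge (BFS with the edge removed), deduplicated, sorted by
length with ties broken by the lowest atom-index tuple, and greedily
selected up to the cyclomatic number. This is deterministic and sufficient
for aromaticity marking, which is its only internal consumer.

`perceive_aromaticity()` applies a Hueckel 4n+2 electron count per SSSR
ring. Contributions: an atom already flagged aromatic, or holding a double
bond inside the ring, contributes one electron; an atom whose only double
bond is exocyclic (a carbonyl carbon, say) contributes zero; a saturated N,
O, S or P contributes its lone pair (two); a saturated carbon disqualifies
the ring. The operation never removes aromaticity present in the input, is
idempotent, and does not touch hydrogen counts, so a Kekulé benzene keeps
its six CH after marking.

## Descriptor conventions

Counting conventions, chosen once and used consistently:

* **atom count** includes implicit hydrogens; **bond count** counts bonds
  between heavy atoms only. The published worked example prints a bond count
  of 3 for ethanol, which matches neither heavy-atom counting (2) nor
  all-atom counting (8); this package treats that value as illustrative and
  reports 2.
* **hydrogen-bond donors** = hydrogens attached to N or O; **acceptors** =
  count of N and O atoms. This is the original Lipinski counting scheme and
  is exactly what the drug-likeness class consumes.
* **topological indices** use the heavy-atom graph: Zagreb = sum of squared
  degrees; eccentric connectivity = sum of degree times eccentricity; Wiener
  polarity = pairs at distance exactly 3; Petitjean number =
  (diameter − radius)/radius, undefined (an error) for single-atom graphs;
  vertex adjacency magnitude = 1 + log2(bond count), 0 with no bonds.
* **largest chain** is the longest simple path through non-ring heavy atoms
  (exhaustive DFS; fixture molecules are capped at 30 atoms, so this is
  cheap). **largest pi system** is the largest connected set of atoms joined
  by bonds of order ≥ 2 or aromatic, merged across a single intervening
  single bond whose both ends already carry pi bonds — an operational
  reading of "conjugated system".
* **disconnected inputs**: counts run over all fragments; distance-based
  indices run on the largest fragment, which keeps them finite while leaving
  counts intuitive.
* **molecular mass** sums CIAAW standard atomic weights plus 1.008 per
  implicit hydrogen; a bracket isotope contributes its nominal mass number
  instead. **Molecular formula** uses Hill order.

**logP** is a sum of per-atom contributions from a compact built-in table
(identifier `semdesc-atomic-v1`) with Wildman–Crippen-inspired classes:
aromatic vs aliphatic carbon, carbon bonded to a heteroatom, amine nitrogen,
carbonyl vs hydroxyl/ether oxygen, the halogens, and a per-hydrogen term;
unknown environments contribute zero. No claim of numeric parity with any
particular cheminformatics toolkit is made — the published logP example
value (1.727 for ethanol) depends on one toolkit's internal
parameterization, which is out of scope. What *is* reproduced exactly is the
parameterized-service contract: the reported value equals the base value
multiplied by the scaling-factor parameter, the table identifier is fixed,
and the parameter used (explicit or the default 1.0) is always reported in
the output provenance.

## Class expressions and reasoning

Service inputs and outputs, and user-facing classes like the drug-likeness
class, are written in a restricted class-expression language: named classes,
conjunction (`and`, with `that` as a synonym), existential restrictions
(`'property' some Filler`) and datatype facets (`double[< = 500.0]`,
`int[< 5]`, `double[< 5.0, > -5.0]`). The bundled ontology
(`inst/extdata/lso.ttl`) stores each class definition as expression text
under a `definition` property, together with `rdfs:label` bindings that
resolve quoted names to IRIs and the property-hierarchy triples. Encoding
the definitions as expression text rather than as OWL restriction blank-node
structures keeps the ontology readable and exactly matches the fragment the
evaluator supports; the full axiom set of the original service ontology was
never published, so classes beyond the printed ones are reconstructed from
the printed patterns.

Two semantic choices matter:

* **Closed-world instance checking.** `is_instance()` treats a missing
  triple as failure of the restriction. This is the right reading here
  because the planner *materializes* service outputs before classification —
  the system's answer to missing data is to compute it, not to leave the
  question open. A consequence to be aware of: asking for drug-likeness
  without running the planner gives `FALSE` for an unannotated molecule.
* **Structural subsumption.** `subsumes()` expands named-class definitions
  and checks that every conjunct of the general class is covered by a
  conjunct of the specific one (named classes by equality, existentials on
  an entailing property with a subsumed filler, facets by bound
  implication). This is sound and complete for the conjunctive-existential
  fragment used by the services, decidable, and fast; it is not an OWL-DL
  reasoner and does not attempt negation, disjunction or cardinalities.

The drug-likeness class bundles the four criteria with the printed bounds:
mass ≤ 500.0 Da, donors < 5, acceptors < 10, and logP strictly between −5.0
and 5.0. The boundary semantics follow the printed facets (`< = 500.0` is
inclusive; the others strict).

## Services, parameters and provenance

A service description carries its input class, output class, attachment
property, produced attribute type(s) and optional parameter information.
Registration enforces the annotative invariant — the input class must
subsume the output class — so a registry can only ever contain services
whose outputs remain valid inputs.

The built-in registry holds one service per registered descriptor (16), the
parameterized scaled-logP service, a functional-group annotator that
attaches `hasProperPart` links to typed group instances (hydroxyl, carbonyl,
carboxyl, primary amine, alkene, alkyne, aromatic ring, alkyl), and an
InChI-to-SMILES converter slot whose conversion backend is injectable. With
no backend the converter still serves its description but errors on
invocation; tests inject a trivial backend. The original system shelled out
to a format-conversion binary here; wrapping a real converter is deliberately
left to the caller so the package stays self-contained. Note the published
discussion pairs the phrase "drug-like alkynes" with an expression using the
*alkyl* group class; both group classes exist here, and the expression is
evaluated as written.

A parameterized invocation looks for a parameter instance (`rdf:type`
SIO_000144 with a value) in the input graph, falls back to the service's
internal default otherwise, and in both cases writes the value used into the
output: the produced descriptor links via the output-of property to a
parameterized-data-transformation node that carries the parameter and the
software name/version. This makes every computed value reproducible from its
own provenance.

## The planner

`execute_query()` parses a SPARQL subset (PREFIX/SELECT/FROM/WHERE with
triple patterns; OPTIONAL, FILTER and UNION are rejected as unsupported),
derives the annotation requirements implied by the pattern — both explicit
attribute-type patterns and those hidden inside defined classes named in
`rdf:type` patterns — and backward-chains over the registry: for each
requirement unmet by the data, the first registered producer is planned;
if that producer's own input class is unsatisfied (an InChI-only molecule
facing a SMILES-consuming service), a producer for the missing restriction
is planned first. Each (service, node) pair is planned at most once, which
guarantees termination even with converters that could otherwise ping-pong.
Plans are deterministic: ties break by registration order.

After running the plan, the basic graph pattern is evaluated on the
materialized graph. `rdf:type` patterns whose class is defined in the
ontology are answered by `is_instance()` rather than by asserted triples
(materialize-then-match) — this is what lets the drug-likeness query return
a molecule that never received an asserted drug-likeness type. Predicate
patterns match through the declared sub/equivalent property closure.

The correctness oracle is `saturate()`: invoke every applicable service to
fixpoint and evaluate the pattern on the result. The planner may invoke far
fewer services but must return the same bindings; the suite checks this
equivalence on randomized molecule/query cases, and checks plan minimality
for the four-service drug-likeness plan by dropping each step and observing
the binding disappear.

## Synthetic molecules

The fixture generator builds a random spanning tree over elements sampled
with organic-chemistry-flavoured weights (mostly carbon, some N/O, a little
S and halogen), optionally closes one ring between atoms with spare valence,
and upgrades bonds to double/triple where both ends have room. Every draw is
valence-consistent by construction and deterministic per seed; molecules are
capped at 30 heavy atoms so the brute-force oracles (VF2 isomorphism,
Floyd–Warshall distances, exhaustive path enumeration) stay trivially fast.

What the generator does *not* emulate: chemical realism (functional-group
frequencies, ring-system statistics, charge states, stereochemistry) and
aromatic input SMILES (aromaticity in fixtures arises only via perception on
Kekulé structures). Passing property tests therefore demonstrate the
correctness of the graph algorithms and the service/planner contracts on
valid molecular graphs — not that descriptor values are calibrated against
laboratory data.

Labelled drug-likeness fixtures are constructed, not sampled: ethanol (all
four criteria pass), a hexaol (6 donors — fails donors only), a 10-oxygen
polyether (fails acceptors only), icosane (logP ≈ 8 — fails logP only,
mass 283 Da), and tetracontane (563 Da — fails mass, and logP too). The
expected labels were derived by hand from the stated conventions and are
frozen in the fixtures.

## Numerical and scale choices

Facet comparisons are exact floating-point comparisons; the bounds in play
(500.0, 5, 10, ±5.0) and the values compared against them are
well-separated, so no tolerance machinery is needed. Literal datatypes are
respected: an `int`-typed literal satisfies a `double` base (integers are
numbers) but not vice versa. Ties everywhere (SSSR selection, DFS order in
the SMILES writer, planner service choice) break by index or registration
order, making every output reproducible bit-for-bit.

Test problem sizes, chosen to exercise the combinatorics while keeping the
default suite comfortably fast on one CPU: 500 molecules for the round-trip
isomorphism property, 200 for the descriptor-versus-oracle comparisons, 100
randomized planner-versus-saturation cases (plus a smaller module-level
regression set), and 1000 draws for generator invariants.

## Known limitations

* The SMILES dialect omits stereochemistry semantics, multi-digit ring-bond
  reuse edge cases beyond `%nn`, and exotic bracket-atom features (atom
  maps, wildcards).
* Aromaticity perception is ring-local; macrocyclic or charged aromatic
  systems (e.g. cyclopentadienyl anion) are not recognized.
* The logP table is coarse; it orders hydrophobicity sensibly but is not a
  fitted model.
* The reasoner covers only the conjunctive-existential-facet fragment; the
  RDF layer is not a full RDF 1.1 implementation (no named graphs; language
  tags pass through untouched).
* The planner minimizes plan length per requirement greedily; it does not
  search for globally cheaper alternative chains when several services could
  produce the same type (registration order decides).
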