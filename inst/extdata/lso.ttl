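# Lipinski Service Ontology (structural fragment).
# Class definitions are carried as class-expression text under lso:definition;
# rdfs:label triples bind the names used inside those expressions to IRIs.

@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix sio: <http://semanticscience.org/resource/> .
@prefix ss: <http://semanticscience.org/resource/> .
@prefix lso: <http://semanticscience.org/sadi/ontology/lipinskiserviceontology.owl#> .

# --- upper-level terms -------------------------------------------------------
sio:SIO_011125 rdfs:label "molecule" .
sio:SIO_000008 rdfs:label "has attribute" .
sio:SIO_000300 rdfs:label "has value" .
sio:SIO_000144 rdfs:label "parameter" .
sio:SIO_000232 rdfs:label "is output of" .

# --- descriptor attribute types ----------------------------------------------
sio:CHEMINF_000018 rdfs:label "SMILES descriptor" .
sio:CHEMINF_000233 rdfs:label "bond count" .
sio:CHEMINF_000244 rdfs:label "hydrogen bond donor count" .
sio:CHEMINF_000251 rdfs:label "parameterized logP descriptor" .
lso:InChIDescriptor rdfs:label "InChI descriptor" .
lso:AtomCount rdfs:label "atom count" .
lso:HeavyAtomCount rdfs:label "heavy atom count" .
lso:AromaticAtomCount rdfs:label "aromatic atom count" .
lso:HydrogenBondAcceptorCount rdfs:label "hydrogen bond acceptor count" .
lso:MassDescriptor rdfs:label "mass descriptor" .
lso:MolecularFormulaDescriptor rdfs:label "molecular formula descriptor" .
lso:LogPDescriptor rdfs:label "logP descriptor" .
lso:ZagrebIndex rdfs:label "Zagreb index" .
lso:EccentricConnectivityIndex rdfs:label "eccentric connectivity index" .
lso:WienerPolarityNumber rdfs:label "Wiener polarity number" .
lso:PetitjeanNumber rdfs:label "Petitjean number" .
lso:VertexAdjacencyMagnitude rdfs:label "vertex adjacency magnitude" .
lso:LargestChain rdfs:label "largest chain" .
lso:LargestPiSystem rdfs:label "largest PI system" .
lso:ParameterizedDataTransformation rdfs:label "parameterized data transformation" .
lso:FunctionalGroup rdfs:label "functional group" .

# --- functional group classes ------------------------------------------------
lso:Hydroxyl_Group rdfs:label "Hydroxyl_Group" .
lso:Carbonyl_Group rdfs:label "Carbonyl_Group" .
lso:Carboxyl_Group rdfs:label "Carboxyl_Group" .
lso:Primary_Amine_Group rdfs:label "Primary_Amine_Group" .
lso:Alkene_Group rdfs:label "Alkene_Group" .
lso:Alkyne_Group rdfs:label "Alkyne_Group" .
lso:Aromatic_Ring_Group rdfs:label "Aromatic_Ring_Group" .
lso:Alkyl_Group rdfs:label "Alkyl_Group" .

# --- property hierarchy ------------------------------------------------------
lso:hasChemicalDescriptor rdfs:label "hasChemicalDescriptor" ;
    rdfs:subPropertyOf sio:SIO_000008 .
lso:hatChemischeDeskriptor rdfs:label "hatChemischeDeskriptor" ;
    owl:equivalentProperty lso:hasChemicalDescriptor .
lso:hasProperPart rdfs:label "hasProperPart" .
lso:hasParameter rdfs:label "has parameter" .

# --- input classes -----------------------------------------------------------
lso:smilesmolecule rdfs:label "smilesmolecule" ;
    lso:definition "molecule and 'has attribute' some ('SMILES descriptor' and 'has value' some string)" .
lso:inchimolecule rdfs:label "inchimolecule" ;
    lso:definition "molecule and 'has attribute' some ('InChI descriptor' and 'has value' some string)" .

# --- output classes (one per descriptor service) -----------------------------
lso:atomcountsmilesmolecule rdfs:label "atomcountsmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('atom count' and 'has value' some int)" .
lso:heavyatomcountsmilesmolecule rdfs:label "heavyatomcountsmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('heavy atom count' and 'has value' some int)" .
lso:bondcountsmilesmolecule rdfs:label "bondcountsmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('bond count' and 'has value' some int)" .
lso:aromaticatomcountsmilesmolecule rdfs:label "aromaticatomcountsmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('aromatic atom count' and 'has value' some int)" .
lso:hydrogenbonddonorcountsmilesmolecule rdfs:label "hydrogenbonddonorcountsmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('hydrogen bond donor count' and 'has value' some int)" .
lso:hydrogenbondacceptorcountsmilesmolecule rdfs:label "hydrogenbondacceptorcountsmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('hydrogen bond acceptor count' and 'has value' some int)" .
lso:molecularmasssmilesmolecule rdfs:label "molecularmasssmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('mass descriptor' and 'has value' some double)" .
lso:molecularformulasmilesmolecule rdfs:label "molecularformulasmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('molecular formula descriptor' and 'has value' some string)" .
lso:xlogpsmilesmolecule rdfs:label "xlogpsmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('logP descriptor' and 'has value' some double)" .
lso:zagrebindexsmilesmolecule rdfs:label "zagrebindexsmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('Zagreb index' and 'has value' some int)" .
lso:eccentricconnectivityindexsmilesmolecule rdfs:label "eccentricconnectivityindexsmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('eccentric connectivity index' and 'has value' some int)" .
lso:wienerpolaritynumbersmilesmolecule rdfs:label "wienerpolaritynumbersmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('Wiener polarity number' and 'has value' some int)" .
lso:petitjeannumbersmilesmolecule rdfs:label "petitjeannumbersmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('Petitjean number' and 'has value' some double)" .
lso:vertexadjacencymagnitudesmilesmolecule rdfs:label "vertexadjacencymagnitudesmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('vertex adjacency magnitude' and 'has value' some double)" .
lso:largestchainsmilesmolecule rdfs:label "largestchainsmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('largest chain' and 'has value' some int)" .
lso:largestpisystemsmilesmolecule rdfs:label "largestpisystemsmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('largest PI system' and 'has value' some int)" .

# parameterized logP: the produced descriptor carries provenance
lso:parameterizedlogpsmilesmolecule rdfs:label "parameterizedlogpsmilesmolecule" ;
    lso:definition "smilesmolecule and 'has attribute' some ('parameterized logP descriptor' and 'has value' some double and 'is output of' some 'parameterized data transformation')" .

# format converter: an InChI molecule that also carries a SMILES descriptor
lso:smilesinchimolecule rdfs:label "smilesinchimolecule" ;
    lso:definition "inchimolecule and 'has attribute' some ('SMILES descriptor' and 'has value' some string)" .

# functional group annotator output
lso:annotatedsmilesmolecule rdfs:label "annotatedsmilesmolecule" ;
    lso:definition "smilesmolecule and 'hasProperPart' some 'functional group'" .

# --- drug-likeness -----------------------------------------------------------
lso:lipinskismilesmolecule rdfs:label "lipinskismilesmolecule" ;
    lso:definition "smilesmolecule and 'hasChemicalDescriptor' some ('mass descriptor' and 'has value' some double[< = 500.0]) and 'hasChemicalDescriptor' some ('hydrogen bond donor count' and 'has value' some int[< 5]) and 'hasChemicalDescriptor' some ('hydrogen bond acceptor count' and 'has value' some int[< 10]) and 'hasChemicalDescriptor' some ('logP descriptor' and 'has value' some double[< 5.0, > -5.0])" .
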