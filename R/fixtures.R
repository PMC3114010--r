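#' Seeded random-molecule generator
#'
#' Builds a valence-consistent molecular graph as a random spanning tree over
#' sampled elements, followed by optional ring-closing edges and bond-order
#' upgrades that respect each atom's remaining valence. Deterministic per
#' seed. Generated molecules are capped at 30 heavy atoms so the brute-force
#' test oracles (labelled-graph isomorphism, path enumeration) stay
#' tractable.
#'
#' @param cfg a [fixture_config()].
#' @return a `molgraph`.
#' @export
random_molecule <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(cfg$seed, random_molecule_impl(cfg))
}

#' @rdname random_molecule
#' @param seed integer seed.
#' @param n_atoms integer range (length 2) of heavy-atom counts.
#' @param element_weights named numeric sampling weights.
#' @param ring_prob probability of attempting one extra ring-closing edge.
#' @param multiple_bond_prob probability of upgrading an eligible bond.
#' @export
fixture_config <- function(seed = 1L, n_atoms = c(3L, 12L),
                           element_weights = c(C = 0.70, N = 0.10, O = 0.14,
                                               S = 0.03, F = 0.015, Cl = 0.015),
                           ring_prob = 0.35, multiple_bond_prob = 0.25) {
  stopifnot(n_atoms[1] >= 1L, n_atoms[2] <= 30L, n_atoms[1] <= n_atoms[2],
            ring_prob >= 0, ring_prob <= 1,
            multiple_bond_prob >= 0, multiple_bond_prob <= 1,
            all(element_weights >= 0))
  structure(list(seed = as.integer(seed), n_atoms = as.integer(n_atoms),
                 element_weights = element_weights, ring_prob = ring_prob,
                 multiple_bond_prob = multiple_bond_prob),
            class = "fixture_config")
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_molecule_impl <- function(cfg) {
  n <- if (cfg$n_atoms[1] == cfg$n_atoms[2]) cfg$n_atoms[1]
  else sample(cfg$n_atoms[1]:cfg$n_atoms[2], 1L)
  els <- sample(names(cfg$element_weights), n, replace = TRUE,
                prob = cfg$element_weights)
  max_val <- vapply(els, function(e) max(element_valences(e)), 0L)
  used <- integer(n)
  bonds <- data.frame(a = integer(0), b = integer(0), order = character(0),
                      stringsAsFactors = FALSE)
  # spanning tree: attach each new atom to a random earlier atom with free
  # valence (falling back to a fresh fragment when none is free)
  for (k in seq_len(n)[-1]) {
    free <- which(used[seq_len(k - 1L)] < max_val[seq_len(k - 1L)])
    if (length(free) == 0L) next  # start a new fragment
    at <- if (length(free) == 1L) free else sample(free, 1L)
    bonds <- rbind(bonds, data.frame(a = at, b = k, order = "single",
                                     stringsAsFactors = FALSE))
    used[at] <- used[at] + 1L
    used[k] <- used[k] + 1L
  }
  # optional ring closure between non-adjacent atoms with free valence
  if (stats::runif(1) < cfg$ring_prob && n >= 3L) {
    free <- which(used < max_val)
    if (length(free) >= 2L) {
      pick <- sample(free, 2L)
      a <- min(pick); b <- max(pick)
      adjacent <- any((bonds$a == a & bonds$b == b) | (bonds$a == b & bonds$b == a))
      if (!adjacent) {
        bonds <- rbind(bonds, data.frame(a = a, b = b, order = "single",
                                         stringsAsFactors = FALSE))
        used[a] <- used[a] + 1L
        used[b] <- used[b] + 1L
      }
    }
  }
  # bond-order upgrades where both ends have spare valence
  for (k in seq_len(nrow(bonds))) {
    if (stats::runif(1) >= cfg$multiple_bond_prob) next
    a <- bonds$a[k]; b <- bonds$b[k]
    spare <- min(max_val[a] - used[a], max_val[b] - used[b])
    if (spare >= 2L && stats::runif(1) < 0.3) {
      bonds$order[k] <- "triple"; used[a] <- used[a] + 2L; used[b] <- used[b] + 2L
    } else if (spare >= 1L) {
      bonds$order[k] <- "double"; used[a] <- used[a] + 1L; used[b] <- used[b] + 1L
    }
  }
  atoms <- data.frame(element = els, charge = 0L, aromatic = FALSE,
                      isotope = NA_integer_, implicit_h = NA_integer_,
                      stringsAsFactors = FALSE)
  g <- structure(list(atoms = atoms, bonds = bonds, rings = list()),
                 class = "molgraph")
  for (k in seq_len(n)) {
    ih <- implicit_h_for(els[k], 0L, bond_order_sum(g, k))
    g$atoms$implicit_h[k] <- if (is.na(ih)) 0L else ih
  }
  g$rings <- find_sssr(g)
  g
}

#' A batch of seeded random molecules
#'
#' @param n number of molecules.
#' @param seed base seed; molecule `i` uses `seed + i`.
#' @param ... passed to [fixture_config()].
#' @return list of `molgraph`s.
#' @export
random_molecules <- function(n, seed = 1L, ...) {
  lapply(seq_len(n), function(i) random_molecule(fixture_config(seed = seed + i, ...)))
}

#' Wrap a molecule in an annotation input graph
#'
#' Produces the standard service input: the entity typed as a molecule with a
#' SMILES attribute whose value is [write_smiles()] of the graph — the same
#' triple shape as the bundled ethanol listing. The result always classifies
#' into the SMILES-molecule input class.
#'
#' @param g a `molgraph` with at least one atom.
#' @param entity_iri IRI for the molecule node.
#' @return an [rdf_graph()].
#' @export
molecule_to_input_graph <- function(g,
                                    entity_iri = "http://semanticscience.org/resource/Molecule1") {
  stopifnot(inherits(g, "molgraph"))
  if (n_atoms(g) == 0L) stop("cannot annotate an empty molecule", call. = FALSE)
  v <- vocab()
  out <- rdf_graph()
  ent <- iri(entity_iri)
  out <- rdf_add(out, ent, iri(v$rdf_type), iri(v$molecule))
  add_attribute(out, ent, v$smiles_descriptor, lit(write_smiles(g)))$graph
}

#' Labelled drug-likeness fixtures
#'
#' Molecules constructed to pass all four Lipinski criteria or to fail
#' exactly one. Expected labels are derived by hand from the package's stated
#' conventions (mass from standard atomic weights; donors = H on N/O;
#' acceptors = N+O count; logP from the built-in contribution table):
#'
#' * ethanol `OCC`: mass 46.07, 1 donor, 1 acceptor, logP ~0.39 — pass.
#' * sorbitol-like hexaol: 6 donors (>= 5) — fail (donors only).
#' * decaether chain: 10 acceptors (>= 10) — fail (acceptors only).
#' * icosane `C20H42`: logP ~8.0 (> 5), mass 282.6 — fail (logP only).
#' * tetracontane `C40H82`: mass 563.1 (> 500) and logP out of range — fail.
#'
#' @param seed unused except to also include one seeded random passing
#'   molecule kept under 200 Da with no N/O.
#' @return list of cases: `list(graph =, entity =, expected =, label =)`.
#' @export
lipinski_counterexamples <- function(seed = 1L) {
  ss <- function(x) paste0("http://semanticscience.org/resource/", x)
  smiles_case <- function(smi, name, expected) {
    list(graph = molecule_to_input_graph(parse_smiles(smi), ss(name)),
         entity = iri(ss(name)), expected = expected, label = name)
  }
  cases <- list(
    smiles_case("OCC", "Ethanol", TRUE),
    smiles_case("OCC(O)C(O)C(O)C(O)CO", "Hexaol", FALSE),        # 6 donors
    smiles_case(paste0("CO", paste(rep("CCO", 9L), collapse = ""), "C"),
                "Decaether", FALSE),                              # 10 acceptors
    smiles_case(paste(rep("C", 20L), collapse = ""), "Icosane", FALSE),  # logP
    smiles_case(paste(rep("C", 40L), collapse = ""), "Tetracontane", FALSE)  # mass+logP
  )
  # a small seeded all-carbon molecule below every threshold
  g <- random_molecule(fixture_config(seed = seed, n_atoms = c(3L, 8L),
                                      element_weights = c(C = 1),
                                      ring_prob = 0, multiple_bond_prob = 0))
  cases[[length(cases) + 1L]] <-
    list(graph = molecule_to_input_graph(g, ss("RandomAlkane")),
         entity = iri(ss("RandomAlkane")), expected = TRUE,
         label = "RandomAlkane")
  cases
}
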