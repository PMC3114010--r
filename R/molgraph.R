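#' Molecular graphs
#'
#' A molecule is an attributed simple graph: a table of atoms (element,
#' formal charge, aromatic flag, implicit hydrogen count, optional isotope),
#' a table of bonds (atom indices `a`, `b` and an order among single, double,
#' triple, aromatic) and the smallest-set-of-smallest-rings membership
#' computed at parse time. Atom indices are 1-based. Hydrogens are implicit
#' unless written explicitly in the input.
#'
#' @name molgraph
NULL

ORGANIC_SUBSET <- c("B", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
BRACKET_ELEMENTS <- c(ORGANIC_SUBSET, "H", "Si", "Se", "As", "Li", "Na", "K",
                      "Mg", "Ca", "Fe", "Zn", "Cu", "Mn", "Co", "Ni", "Al",
                      "Sn", "Te")

# allowed valence states, smallest first
element_valences <- function(element) {
  switch(element,
         B = 3L, C = 4L, N = 3L, O = 2L,
         P = c(3L, 5L), S = c(2L, 4L, 6L),
         F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L,
         NA_integer_)
}

bond_order_value <- function(order) {
  c(single = 1, double = 2, triple = 3, aromatic = 1.5)[order]
}

new_molgraph <- function(atoms, bonds) {
  g <- structure(list(atoms = atoms, bonds = bonds, rings = list()),
                 class = "molgraph")
  g$rings <- find_sssr(g)
  g
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", n_atoms(x), " heavy atoms, ", nrow(x$bonds),
      " bonds, ", length(x$rings), " rings, formula ",
      molecular_formula(x), "\n", sep = "")
  invisible(x)
}

#' @rdname molgraph
#' @param g a `molgraph`.
#' @export
n_atoms <- function(g) nrow(g$atoms)

# Sum of incident bond orders for one atom. For an aromatic atom each
# aromatic bond counts 1 plus one shared pi increment for the whole ring
# system: benzene carbons get 3 (1 implicit H), fusion carbons 4 (no H). A
# non-aromatic atom counts aromatic bonds as 1.5 (rounded up by the caller).
bond_order_sum <- function(g, idx) {
  inc <- g$bonds[g$bonds$a == idx | g$bonds$b == idx, , drop = FALSE]
  if (nrow(inc) == 0L) return(0)
  n_ar <- sum(inc$order == "aromatic")
  rest <- sum(bond_order_value(inc$order[inc$order != "aromatic"]))
  if (n_ar == 0L) return(rest)
  if (isTRUE(g$atoms$aromatic[idx])) rest + n_ar + 1L
  else rest + 1.5 * n_ar
}

# implicit hydrogens under the organic-subset convention: the smallest
# permitted valence accommodating the (rounded-up) bond order sum, minus that
# sum; clamped at zero. Aromatic rounding gives benzene carbons exactly 1 H.
implicit_h_for <- function(element, charge, order_sum) {
  vals <- element_valences(element)
  if (all(is.na(vals))) return(0L)
  need <- ceiling(order_sum)
  vals <- vals + charge * 0L  # charge does not shift valence here
  fit <- vals[vals >= need]
  if (length(fit) == 0L) return(NA_integer_)  # valence overflow
  as.integer(fit[1] - need)
}

molgraph_to_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = n_atoms(g), directed = FALSE)
  if (nrow(g$bonds) > 0L)
    ig <- igraph::add_edges(ig, rbind(g$bonds$a, g$bonds$b))
  ig
}

# smallest set of smallest rings: shortest cycle through every edge,
# deduplicated, then greedily selected (shortest first, ties by the sorted
# atom-index tuple) until the cyclomatic number is reached
find_sssr <- function(g) {
  m <- nrow(g$bonds)
  n <- n_atoms(g)
  if (m == 0L || n < 3L) return(list())
  ig <- molgraph_to_igraph(g)
  n_comp <- igraph::components(ig)$no
  cyclomatic <- m - n + n_comp
  if (cyclomatic <= 0L) return(list())
  cand <- list()
  for (e in seq_len(m)) {
    u <- g$bonds$a[e]; v <- g$bonds$b[e]
    ig2 <- igraph::delete_edges(ig, igraph::get_edge_ids(ig, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(ig2, from = u, to = v)$vpath[[1]])
    if (length(sp) == 0L) next
    ring <- sort(as.integer(sp))
    cand[[length(cand) + 1L]] <- ring
  }
  if (length(cand) == 0L) return(list())
  keys <- vapply(cand, function(r) paste(r, collapse = ","), "")
  cand <- cand[!duplicated(keys)]
  ord <- order(lengths(cand),
               vapply(cand, function(r) sprintf("%04d", r[1]), ""),
               vapply(cand, function(r) paste(sprintf("%04d", r), collapse = ""), ""))
  cand <- cand[ord]
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ring_edges <- function(ring) {
    sub <- g$bonds[g$bonds$a %in% ring & g$bonds$b %in% ring, , drop = FALSE]
    edge_key(sub$a, sub$b)
  }
  covered <- character(0)
  out <- list()
  for (r in cand) {
    if (length(out) >= cyclomatic) break
    ek <- ring_edges(r)
    if (any(!(ek %in% covered))) {
      out[[length(out) + 1L]] <- r
      covered <- union(covered, ek)
    }
  }
  out
}

#' Heavy-atom topological distance matrix
#'
#' Unweighted shortest-path lengths between heavy atoms (BFS); `Inf` marks
#' pairs in different fragments.
#'
#' @param g a `molgraph`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(g) {
  n <- n_atoms(g)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  ig <- molgraph_to_igraph(g)
  d <- igraph::distances(ig)
  dimnames(d) <- NULL
  d
}

#' Mark aromatic rings on a parsed molecule
#'
#' Scans every SSSR ring: if all ring atoms are sp2-capable and the ring's
#' pi-electron count satisfies Hueckel's 4n+2 rule, the ring's atoms and
#' bonds are marked aromatic. Contribution rules: an atom already aromatic or
#' holding a double bond inside the ring contributes 1; an atom whose only
#' double bond is exocyclic (e.g. a carbonyl carbon) contributes 0; a
#' saturated N, O, S or P contributes its lone pair (2); a saturated carbon
#' makes the ring non-aromatic. Lowercase-input aromaticity is never removed,
#' and the operation is idempotent. Implicit hydrogen counts are unchanged.
#'
#' @param g a `molgraph`.
#' @return the molecule with aromatic flags updated.
#' @export
perceive_aromaticity <- function(g) {
  if (length(g$rings) == 0L) return(g)
  for (ring in g$rings) {
    pi_total <- 0L
    ok <- TRUE
    for (at in ring) {
      inc <- g$bonds[g$bonds$a == at | g$bonds$b == at, , drop = FALSE]
      other <- ifelse(inc$a == at, inc$b, inc$a)
      in_ring_double <- any(inc$order == "double" & other %in% ring)
      exo_double <- any(inc$order == "double" & !(other %in% ring))
      has_triple <- any(inc$order == "triple")
      el <- g$atoms$element[at]
      if (has_triple) { ok <- FALSE; break }
      if (g$atoms$aromatic[at] || in_ring_double) {
        pi_total <- pi_total + 1L
      } else if (exo_double) {
        pi_total <- pi_total + 0L
      } else if (el %in% c("N", "O", "S", "P")) {
        pi_total <- pi_total + 2L
      } else {
        ok <- FALSE; break   # saturated carbon: not sp2-capable
      }
    }
    if (ok && pi_total >= 2L && (pi_total - 2L) %% 4L == 0L) {
      g$atoms$aromatic[ring] <- TRUE
      # mark ring-perimeter bonds aromatic
      for (bi in which(g$bonds$a %in% ring & g$bonds$b %in% ring)) {
        if (g$bonds$order[bi] %in% c("single", "double"))
          g$bonds$order[bi] <- "aromatic"
      }
    }
  }
  g
}

# connected fragments as lists of atom indices
fragments <- function(g) {
  ig <- molgraph_to_igraph(g)
  comp <- igraph::components(ig)$membership
  split(seq_len(n_atoms(g)), comp)
}
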