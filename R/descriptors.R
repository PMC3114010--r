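#' QSAR count descriptors
#'
#' Conventions: `atoms` counts heavy atoms plus all hydrogens (implicit and
#' explicit); `bonds` counts bonds between heavy atoms only; `hbd` is the
#' number of hydrogens attached to N or O and `hba` the number of N and O
#' atoms (Lipinski's counting scheme); `aromatic_atoms` counts atoms flagged
#' aromatic after perception.
#'
#' @param g a `molgraph`.
#' @param kind one of `"atoms"`, `"heavy_atoms"`, `"bonds"`,
#'   `"aromatic_atoms"`, `"hbd"`, `"hba"`.
#' @return non-negative integer.
#' @export
count_descriptor <- function(g, kind) {
  stopifnot(inherits(g, "molgraph"))
  no_idx <- which(g$atoms$element %in% c("N", "O"))
  explicit_h_on <- function(idx) {
    inc <- g$bonds[g$bonds$a %in% idx | g$bonds$b %in% idx, , drop = FALSE]
    other <- c(inc$b[inc$a %in% idx], inc$a[inc$b %in% idx])
    sum(g$atoms$element[other] == "H")
  }
  switch(kind,
         atoms = n_atoms(g) + sum(g$atoms$implicit_h),
         heavy_atoms = n_atoms(g) - sum(g$atoms$element == "H"),
         bonds = sum(g$atoms$element[g$bonds$a] != "H" &
                       g$atoms$element[g$bonds$b] != "H"),
         aromatic_atoms = sum(perceive_aromaticity(g)$atoms$aromatic),
         hbd = sum(g$atoms$implicit_h[no_idx]) + explicit_h_on(no_idx),
         hba = length(no_idx),
         stop("unknown count descriptor kind: ", kind, call. = FALSE))
}

# standard atomic weights (CIAAW 2021 abridged)
ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
  Se = 78.971, As = 74.922, Li = 6.94, Na = 22.990, K = 39.098, Mg = 24.305,
  Ca = 40.078, Fe = 55.845, Zn = 65.38, Cu = 63.546, Mn = 54.938,
  Co = 58.933, Ni = 58.693, Al = 26.982, Sn = 118.71, Te = 127.60)

#' Molecular mass in Daltons
#'
#' Sum of standard atomic weights over all atoms plus 1.008 per implicit
#' hydrogen; atoms with a specified isotope contribute their nominal isotope
#' mass instead of the standard weight.
#'
#' @param g a `molgraph`.
#' @return mass in Daltons.
#' @export
molecular_mass <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  if (n_atoms(g) == 0L) stop("molecular mass undefined for an empty molecule",
                             call. = FALSE)
  w <- numeric(n_atoms(g))
  for (k in seq_len(n_atoms(g))) {
    el <- g$atoms$element[k]
    iso <- g$atoms$isotope[k]
    if (!is.na(iso)) { w[k] <- iso; next }
    if (!el %in% names(ATOMIC_WEIGHTS))
      stop("no atomic weight for element: ", el, call. = FALSE)
    w[k] <- ATOMIC_WEIGHTS[[el]]
  }
  sum(w) + 1.008 * sum(g$atoms$implicit_h)
}

#' Molecular formula in Hill order
#'
#' Carbon first, hydrogen second, all other elements alphabetical; if no
#' carbon is present all elements (including H) sort alphabetically. Count
#' suffixes of 1 are omitted.
#'
#' @param g a `molgraph`.
#' @return formula string, e.g. `"C2H6O"`.
#' @export
molecular_formula <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  counts <- table(g$atoms$element)
  counts <- stats::setNames(as.integer(counts), names(counts))
  h <- sum(g$atoms$implicit_h) + (counts["H"] %||% 0L)
  counts <- counts[names(counts) != "H"]
  if (h > 0L) counts["H"] <- h
  els <- names(counts)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", if (h > 0L) "H", rest)
  } else {
    ord <- sort(els)
  }
  paste0(vapply(ord, function(e) {
    k <- counts[[e]]
    if (k == 1L) e else paste0(e, k)
  }, ""), collapse = "")
}

`%||%` <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.atomic(a) && (length(a) == 0L || (length(a) == 1L && is.na(a)))) return(b)
  a
}

# heavy-atom subgraph of the largest fragment (distance-based indices operate
# on it so disconnected inputs stay finite)
largest_fragment <- function(g) {
  fr <- fragments(g)
  if (length(fr) <= 1L) return(g)
  keep <- fr[[which.max(lengths(fr))[1]]]
  subgraph_mol(g, keep)
}

subgraph_mol <- function(g, keep) {
  keep <- sort(keep)
  remap <- match(seq_len(n_atoms(g)), keep)
  bonds <- g$bonds[g$bonds$a %in% keep & g$bonds$b %in% keep, , drop = FALSE]
  bonds$a <- remap[bonds$a]; bonds$b <- remap[bonds$b]
  rownames(bonds) <- NULL
  structure(list(atoms = g$atoms[keep, , drop = FALSE],
                 bonds = bonds, rings = list()), class = "molgraph")
}

heavy_degrees <- function(g) {
  deg <- integer(n_atoms(g))
  for (k in seq_len(nrow(g$bonds))) {
    deg[g$bonds$a[k]] <- deg[g$bonds$a[k]] + 1L
    deg[g$bonds$b[k]] <- deg[g$bonds$b[k]] + 1L
  }
  deg
}

#' Topological indices over the heavy-atom graph
#'
#' * `zagreb`: sum of squared degrees.
#' * `eccentric_connectivity`: sum over atoms of degree times eccentricity.
#' * `wiener_polarity`: number of unordered atom pairs at distance exactly 3.
#' * `petitjean`: (diameter - radius) / radius; errors on single-atom graphs
#'   where the radius is zero.
#' * `vadjma`: vertex adjacency magnitude, `1 + log2(m)` for `m` heavy-atom
#'   bonds (0 when there are no bonds).
#' * `largest_chain`: atom count of the longest simple path through non-ring
#'   heavy atoms.
#' * `largest_pi`: size of the largest conjugated pi system (atoms connected
#'   by bonds of order >= 2 or aromatic, merged across one intervening single
#'   bond).
#'
#' Distance-based indices are computed on the largest fragment of a
#' disconnected input.
#'
#' @param g a `molgraph`.
#' @param kind one of `"zagreb"`, `"eccentric_connectivity"`,
#'   `"wiener_polarity"`, `"petitjean"`, `"vadjma"`, `"largest_chain"`,
#'   `"largest_pi"`.
#' @return a number.
#' @export
topological_index <- function(g, kind) {
  stopifnot(inherits(g, "molgraph"))
  if (kind == "zagreb") return(sum(heavy_degrees(g)^2))
  if (kind == "vadjma") {
    m <- nrow(g$bonds)
    return(if (m == 0L) 0 else 1 + log2(m))
  }
  if (kind == "largest_pi") return(largest_pi_system(g))
  if (kind == "largest_chain") return(largest_chain(g))
  gf <- largest_fragment(g)
  d <- distance_matrix(gf)
  if (kind == "wiener_polarity") {
    if (nrow(d) < 2L) return(0L)
    return(sum(d[upper.tri(d)] == 3))
  }
  ecc <- if (nrow(d) > 1L) apply(d, 1L, max) else 0
  if (kind == "eccentric_connectivity")
    return(sum(heavy_degrees(gf) * ecc))
  if (kind == "petitjean") {
    R <- min(ecc); D <- max(ecc)
    if (R == 0) stop("Petitjean number undefined for a single-atom graph",
                     call. = FALSE)
    return((D - R) / R)
  }
  stop("unknown topological index kind: ", kind, call. = FALSE)
}

ring_atoms <- function(g) unique(unlist(g$rings))

# longest simple path restricted to non-ring heavy atoms; exhaustive DFS is
# fine at fixture scale (<= 30 atoms, trees after ring removal)
largest_chain <- function(g) {
  keep <- setdiff(seq_len(n_atoms(g)), ring_atoms(g))
  keep <- keep[g$atoms$element[keep] != "H"]
  if (length(keep) == 0L) return(0L)
  sub <- subgraph_mol(g, keep)
  n <- n_atoms(sub)
  adj <- vector("list", n)
  for (k in seq_len(nrow(sub$bonds))) {
    a <- sub$bonds$a[k]; b <- sub$bonds$b[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  best <- 1L
  visit <- function(v, seen, len) {
    best <<- max(best, len)
    for (nb in adj[[v]]) if (!seen[nb]) {
      seen[nb] <- TRUE
      visit(nb, seen, len + 1L)
      seen[nb] <- FALSE
    }
  }
  for (start in seq_len(n)) {
    seen <- rep(FALSE, n); seen[start] <- TRUE
    visit(start, seen, 1L)
  }
  best
}

largest_pi_system <- function(g) {
  pi_bonds <- g$bonds[g$bonds$order %in% c("double", "triple", "aromatic"), ,
                      drop = FALSE]
  if (nrow(pi_bonds) == 0L) return(0L)
  pi_atoms <- unique(c(pi_bonds$a, pi_bonds$b))
  ig <- igraph::make_empty_graph(n = n_atoms(g), directed = FALSE)
  ig <- igraph::add_edges(ig, rbind(pi_bonds$a, pi_bonds$b))
  # conjugation bridge: one single bond whose both ends are pi atoms
  single <- g$bonds[g$bonds$order == "single" &
                      g$bonds$a %in% pi_atoms & g$bonds$b %in% pi_atoms, ,
                    drop = FALSE]
  if (nrow(single) > 0L)
    ig <- igraph::add_edges(ig, rbind(single$a, single$b))
  comp <- igraph::components(ig)
  sizes <- tabulate(comp$membership[pi_atoms])
  max(sizes)
}
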