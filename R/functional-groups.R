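#' Detect functional groups
#'
#' Matches a built-in library of structural patterns against the molecule and
#' returns all maximal non-overlapping hits per group. Groups:
#'
#' * `hydroxyl`: non-aromatic O with at least one hydrogen and only single bonds.
#' * `carbonyl`: C=O (non-aromatic).
#' * `carboxyl`: C(=O)OH.
#' * `primary_amine`: non-aromatic N with two hydrogens and one heavy neighbour.
#' * `alkene`: non-aromatic C=C.
#' * `alkyne`: C#C.
#' * `aromatic_ring`: an SSSR ring whose atoms are all aromatic.
#' * `alkyl`: a maximal connected set of sp3 carbons (no multiple or aromatic
#'   bonds on the atom).
#'
#' @param g a `molgraph`.
#' @param library character vector of group names to search for; defaults to
#'   the full built-in set.
#' @return list of hits, each `list(group =, atom_indices =)`.
#' @export
detect_functional_groups <- function(g, library = names(FG_PATTERNS)) {
  stopifnot(inherits(g, "molgraph"))
  unknown <- setdiff(library, names(FG_PATTERNS))
  if (length(unknown) > 0L)
    stop("unknown functional group(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  g <- perceive_aromaticity(g)
  hits <- list()
  for (grp in library) {
    for (match_atoms in FG_PATTERNS[[grp]](g)) {
      hits[[length(hits) + 1L]] <- list(group = grp,
                                        atom_indices = sort(match_atoms))
    }
  }
  hits
}

fg_neighbors <- function(g, k) {
  inc <- g$bonds[g$bonds$a == k | g$bonds$b == k, , drop = FALSE]
  data.frame(other = ifelse(inc$a == k, inc$b, inc$a), order = inc$order,
             stringsAsFactors = FALSE)
}

atom_total_h <- function(g, k) {
  nb <- fg_neighbors(g, k)
  g$atoms$implicit_h[k] + sum(g$atoms$element[nb$other] == "H")
}

FG_PATTERNS <- list(
  hydroxyl = function(g) {
    out <- list()
    for (k in which(g$atoms$element == "O" & !g$atoms$aromatic)) {
      nb <- fg_neighbors(g, k)
      if (all(nb$order == "single") && atom_total_h(g, k) >= 1L)
        out[[length(out) + 1L]] <- k
    }
    out
  },
  carbonyl = function(g) {
    out <- list()
    dbl <- g$bonds[g$bonds$order == "double", , drop = FALSE]
    for (k in seq_len(nrow(dbl))) {
      a <- dbl$a[k]; b <- dbl$b[k]
      els <- g$atoms$element[c(a, b)]
      if (setequal(els, c("C", "O")) && !any(g$atoms$aromatic[c(a, b)]))
        out[[length(out) + 1L]] <- c(a, b)
    }
    out
  },
  carboxyl = function(g) {
    out <- list()
    for (cc in which(g$atoms$element == "C" & !g$atoms$aromatic)) {
      nb <- fg_neighbors(g, cc)
      o_dbl <- nb$other[nb$order == "double" & g$atoms$element[nb$other] == "O"]
      o_sgl <- nb$other[nb$order == "single" & g$atoms$element[nb$other] == "O"]
      o_oh <- o_sgl[vapply(o_sgl, function(o) atom_total_h(g, o) >= 1L, TRUE)]
      if (length(o_dbl) >= 1L && length(o_oh) >= 1L)
        out[[length(out) + 1L]] <- c(cc, o_dbl[1], o_oh[1])
    }
    out
  },
  primary_amine = function(g) {
    out <- list()
    for (k in which(g$atoms$element == "N" & !g$atoms$aromatic)) {
      nb <- fg_neighbors(g, k)
      heavy <- nb$other[g$atoms$element[nb$other] != "H"]
      if (atom_total_h(g, k) == 2L && length(heavy) == 1L &&
          all(nb$order == "single"))
        out[[length(out) + 1L]] <- k
    }
    out
  },
  alkene = function(g) {
    out <- list()
    dbl <- g$bonds[g$bonds$order == "double", , drop = FALSE]
    for (k in seq_len(nrow(dbl))) {
      a <- dbl$a[k]; b <- dbl$b[k]
      if (all(g$atoms$element[c(a, b)] == "C") && !any(g$atoms$aromatic[c(a, b)]))
        out[[length(out) + 1L]] <- c(a, b)
    }
    out
  },
  alkyne = function(g) {
    out <- list()
    tri <- g$bonds[g$bonds$order == "triple", , drop = FALSE]
    for (k in seq_len(nrow(tri))) {
      a <- tri$a[k]; b <- tri$b[k]
      if (all(g$atoms$element[c(a, b)] == "C"))
        out[[length(out) + 1L]] <- c(a, b)
    }
    out
  },
  aromatic_ring = function(g) {
    Filter(function(r) all(g$atoms$aromatic[r]), g$rings)
  },
  alkyl = function(g) {
    sp3 <- which(g$atoms$element == "C" & !g$atoms$aromatic &
                   vapply(seq_len(n_atoms(g)), function(k) {
                     nb <- fg_neighbors(g, k)
                     nrow(nb) == 0L || all(nb$order == "single")
                   }, TRUE))
    if (length(sp3) == 0L) return(list())
    ig <- igraph::make_empty_graph(n = n_atoms(g), directed = FALSE)
    sub <- g$bonds[g$bonds$a %in% sp3 & g$bonds$b %in% sp3, , drop = FALSE]
    if (nrow(sub) > 0L) ig <- igraph::add_edges(ig, rbind(sub$a, sub$b))
    comp <- igraph::components(ig)$membership
    unname(split(sp3, comp[sp3]))
  }
)
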