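#' Write a molecular graph as a SMILES string
#'
#' Output is not canonical but always round-trips: reparsing yields a graph
#' isomorphic to the input (same labelled atoms, same bond relation). Atoms
#' that need a non-default hydrogen count, a charge or an isotope are written
#' in brackets; single bonds between two aromatic atoms are written `-`
#' explicitly so they do not reparse as aromatic.
#'
#' @param g a `molgraph`.
#' @return a SMILES string.
#' @export
write_smiles <- function(g) {
  stopifnot(inherits(g, "molgraph"), n_atoms(g) > 0L)
  n <- n_atoms(g)
  adj <- vector("list", n)
  bond_lookup <- new.env(parent = emptyenv())
  bkey <- function(a, b) paste(min(a, b), max(a, b))
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a[k]; b <- g$bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    assign(bkey(a, b), g$bonds$order[k], envir = bond_lookup)
  }
  adj <- lapply(adj, sort)

  bond_sym <- function(a, b) {
    order <- get(bkey(a, b), envir = bond_lookup)
    both_arom <- g$atoms$aromatic[a] && g$atoms$aromatic[b]
    switch(order,
           single = if (both_arom) "-" else "",
           double = "=",
           triple = "#",
           aromatic = if (both_arom) "" else ":")
  }

  atom_token <- function(k) {
    el <- g$atoms$element[k]
    arom <- g$atoms$aromatic[k]
    chg <- g$atoms$charge[k]
    iso <- g$atoms$isotope[k]
    ih <- g$atoms$implicit_h[k]
    default_ih <- implicit_h_for(el, 0L, bond_order_sum(g, k))
    plain_ok <- el %in% ORGANIC_SUBSET && chg == 0L && is.na(iso) &&
      !is.na(default_ih) && identical(as.integer(default_ih), as.integer(ih)) &&
      (!arom || tolower(el) %in% c("b", "c", "n", "o", "s", "p"))
    if (plain_ok) return(if (arom) tolower(el) else el)
    sym <- if (arom && tolower(el) %in% c("b", "c", "n", "o", "s", "p"))
      tolower(el) else el
    h <- if (ih == 0L) "" else if (ih == 1L) "H" else paste0("H", ih)
    c_str <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
    else sprintf("%+d", chg)
    i_str <- if (is.na(iso)) "" else as.character(iso)
    paste0("[", i_str, sym, h, c_str, "]")
  }

  visited <- rep(FALSE, n)
  ring_digit <- 0L
  ring_label <- function() {
    ring_digit <<- ring_digit + 1L
    if (ring_digit <= 9L) as.character(ring_digit)
    else sprintf("%%%02d", ring_digit)
  }
  # pre-pass per fragment: classify edges as tree/back via DFS
  emit_fragment <- function(root) {
    closures <- list()  # per atom: list of labels (with bond sym) to print
    back_edges <- character(0)
    # iterative DFS to find back edges and tree structure
    parent <- rep(NA_integer_, n)
    order_visited <- integer(0)
    stack <- root
    in_tree <- rep(FALSE, n)
    in_tree[root] <- TRUE
    children <- vector("list", n)
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      order_visited <- c(order_visited, cur)
      for (nb in adj[[cur]]) {
        if (!in_tree[nb]) {
          in_tree[nb] <- TRUE
          parent[nb] <- cur
          children[[cur]] <- c(children[[cur]], nb)
          stack <- c(stack, nb)
        } else if (!identical(parent[cur], nb)) {
          k <- bkey(cur, nb)
          if (!(k %in% back_edges)) back_edges <- c(back_edges, k)
        }
      }
    }
    # assign ring-closure labels to back edges
    atom_closures <- vector("list", n)
    for (k in back_edges) {
      ab <- as.integer(strsplit(k, " ")[[1]])
      lbl <- ring_label()
      sym <- bond_sym(ab[1], ab[2])
      atom_closures[[ab[1]]] <- c(atom_closures[[ab[1]]], paste0(sym, lbl))
      atom_closures[[ab[2]]] <- c(atom_closures[[ab[2]]], paste0("", lbl))
    }
    write_atom <- function(k) {
      visited[k] <<- TRUE
      out <- paste0(atom_token(k), paste(atom_closures[[k]], collapse = ""))
      kids <- children[[k]]
      if (length(kids) > 0L) {
        for (idx in seq_along(kids)) {
          kid <- kids[idx]
          part <- paste0(bond_sym(k, kid), write_atom(kid))
          if (idx < length(kids)) part <- paste0("(", part, ")")
          out <- paste0(out, part)
        }
      }
      out
    }
    write_atom(root)
  }
  parts <- character(0)
  for (root in seq_len(n)) {
    if (!visited[root]) parts <- c(parts, emit_fragment(root))
  }
  paste(parts, collapse = ".")
}
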