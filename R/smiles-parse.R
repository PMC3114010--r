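#' Parse a SMILES string into a molecular graph
#'
#' Supported dialect: the organic subset (`B C N O S P F Cl Br I`), aromatic
#' lowercase forms (`b c n o s p`), bracket atoms with isotope, charge and
#' explicit hydrogen counts, branches, ring closures (digits and `%nn`), the
#' bond symbols `- = # :`, dot-separated fragments, and stereo marks
#' (`@`, `/`, `\`) which are accepted and discarded. Implicit hydrogens are
#' assigned from default valences (B 3; C 4; N 3; O 2; P 3/5; S 2/4/6;
#' halogens 1), aromatic bonds counting 1.5 with the total rounded up.
#'
#' @param s a non-empty SMILES string.
#' @return a `molgraph` (see [molgraph]).
#' @export
parse_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("SMILES must be a non-empty string", call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  perr <- function(i, msg)
    stop(sprintf("SMILES parse error at position %d ('%s'): %s",
                 i, substr(s, i, i), msg), call. = FALSE)

  atoms <- list()   # each: element, charge, aromatic, isotope, hcount(NA=implicit)
  bonds <- list()   # each: a, b, order
  prev <- 0L                # last atom index on current chain
  stack <- integer(0)       # branch stack
  pending_bond <- NA_character_
  ring_open <- list()       # label -> list(atom, bond)

  add_atom <- function(element, aromatic, charge = 0L, isotope = NA_integer_,
                       hcount = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, charge = charge,
                                         aromatic = aromatic, isotope = isotope,
                                         hcount = hcount)
    idx <- length(atoms)
    if (prev > 0L) add_bond(prev, idx, pending_bond)
    pending_bond <<- NA_character_
    prev <<- idx
    idx
  }
  add_bond <- function(a, b, sym, at = NA_integer_) {
    if (a == b) perr(if (is.na(at)) 1L else at, "self bond")
    order <- if (is.na(sym)) {
      if (atoms[[a]]$aromatic && atoms[[b]]$aromatic) "aromatic" else "single"
    } else switch(sym, "-" = "single", "=" = "double", "#" = "triple",
                  ":" = "aromatic")
    for (bd in bonds) {
      if ((bd$a == a && bd$b == b) || (bd$a == b && bd$b == a))
        perr(if (is.na(at)) 1L else at, "duplicate bond between atom pair")
    }
    bonds[[length(bonds) + 1L]] <<- list(a = a, b = b, order = order)
  }
  close_ring <- function(label, i) {
    key <- as.character(label)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      sym <- if (!is.na(pending_bond)) pending_bond else op$bond
      add_bond(op$atom, prev, sym, at = i)
      pending_bond <<- NA_character_
      ring_open[[key]] <<- NULL
    } else {
      ring_open[[key]] <<- list(atom = prev, bond = pending_bond)
      pending_bond <<- NA_character_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (prev == 0L) perr(i, "branch before any atom")
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (length(stack) == 0L) perr(i, "unmatched closing parenthesis")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch %in% c("-", "=", "#", ":")) { pending_bond <- ch; i <- i + 1L; next }
    if (ch %in% c("/", "\\")) { pending_bond <- "-"; i <- i + 1L; next }  # stereo discarded
    if (ch == ".") {
      if (!is.na(pending_bond)) perr(i, "bond symbol before fragment separator")
      prev <- 0L; i <- i + 1L; next
    }
    if (grepl("[0-9]", ch)) {
      if (prev == 0L) perr(i, "ring closure before any atom")
      close_ring(as.integer(ch), i); i <- i + 1L; next
    }
    if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        perr(i, "%% ring closure needs two digits")
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L; next
    }
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) perr(i, "unterminated bracket atom")
      body <- substr(s, i + 1L, j - 1L)
      at <- parse_bracket_atom(body, i)
      add_atom(at$element, at$aromatic, at$charge, at$isotope, at$hcount)
      i <- j + 1L; next
    }
    # organic subset, two-letter halogens first
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) { add_atom(two, FALSE); i <- i + 2L; next }
    if (ch %in% c("B", "C", "N", "O", "S", "P", "F", "I")) {
      add_atom(ch, FALSE); i <- i + 1L; next
    }
    if (ch %in% c("b", "c", "n", "o", "s", "p")) {
      add_atom(toupper(ch), TRUE); i <- i + 1L; next
    }
    perr(i, "unknown element or symbol")
  }
  if (length(stack) > 0L)
    stop("SMILES parse error: unmatched opening parenthesis", call. = FALSE)
  if (length(ring_open) > 0L)
    stop(sprintf("SMILES parse error: unclosed ring bond (label %s)",
                 paste(names(ring_open), collapse = ",")), call. = FALSE)
  if (length(atoms) == 0L)
    stop("SMILES parse error: no atoms", call. = FALSE)

  adf <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
    isotope = vapply(atoms, function(a) as.integer(a$isotope), 0L),
    implicit_h = NA_integer_,
    stringsAsFactors = FALSE)
  bdf <- if (length(bonds) == 0L)
    data.frame(a = integer(0), b = integer(0), order = character(0),
               stringsAsFactors = FALSE)
  else data.frame(a = vapply(bonds, `[[`, 0L, "a"),
                  b = vapply(bonds, `[[`, 0L, "b"),
                  order = vapply(bonds, `[[`, "", "order"),
                  stringsAsFactors = FALSE)
  g <- structure(list(atoms = adf, bonds = bdf, rings = list()),
                 class = "molgraph")
  # implicit hydrogens: bracket atoms use their explicit count, organic-subset
  # atoms get the default-valence assignment; overflow is a parse error
  for (k in seq_len(nrow(adf))) {
    hc <- atoms[[k]]$hcount
    osum <- bond_order_sum(g, k)
    if (!is.na(hc)) {
      g$atoms$implicit_h[k] <- as.integer(hc)
    } else {
      ih <- implicit_h_for(adf$element[k], adf$charge[k], osum)
      if (is.na(ih))
        stop(sprintf("SMILES parse error: valence overflow on atom %d (%s, bond order sum %.1f)",
                     k, adf$element[k], osum), call. = FALSE)
      g$atoms$implicit_h[k] <- ih
    }
  }
  # hard cap: total valence must not exceed the element's maximum
  for (k in seq_len(nrow(adf))) {
    vals <- element_valences(adf$element[k])
    if (all(is.na(vals))) next
    total <- ceiling(bond_order_sum(g, k)) + g$atoms$implicit_h[k]
    if (total > max(vals) + abs(adf$charge[k]))
      stop(sprintf("SMILES parse error: valence overflow on atom %d (%s)",
                   k, adf$element[k]), call. = FALSE)
  }
  g$rings <- find_sssr(g)
  g
}

parse_bracket_atom <- function(body, pos) {
  rest <- body
  take <- function(pattern) {
    m <- regexpr(pattern, rest)
    if (m == 1L) {
      v <- substr(rest, 1L, attr(m, "match.length"))
      rest <<- substr(rest, attr(m, "match.length") + 1L, nchar(rest))
      v
    } else NA_character_
  }
  iso <- take("^[0-9]+")
  el <- take("^[A-Z][a-z]?")
  aromatic <- FALSE
  if (is.na(el)) {
    el <- take("^[bcnops]")
    if (!is.na(el)) { aromatic <- TRUE; el <- toupper(el) }
  }
  if (is.na(el) || !(el %in% BRACKET_ELEMENTS))
    stop(sprintf("SMILES parse error at position %d: unknown element in [%s]",
                 pos, body), call. = FALSE)
  take("^@{1,2}")  # stereo parsed and discarded
  hcount <- 0L
  h <- take("^H[0-9]*")
  if (!is.na(h)) hcount <- if (nchar(h) == 1L) 1L else as.integer(substr(h, 2L, nchar(h)))
  charge <- 0L
  chg <- take("^(\\+[0-9]+|-[0-9]+|\\++|-+)")
  if (!is.na(chg)) {
    charge <- if (grepl("^[+-][0-9]+$", chg)) {
      as.integer(chg)
    } else {
      sign <- if (startsWith(chg, "+")) 1L else -1L
      sign * nchar(chg)
    }
  }
  if (nzchar(rest))
    stop(sprintf("SMILES parse error at position %d: trailing '%s' in [%s]",
                 pos, rest, body), call. = FALSE)
  list(element = el, aromatic = aromatic, charge = charge,
       isotope = if (is.na(iso)) NA_integer_ else as.integer(iso),
       hcount = hcount)
}
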