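#' Atomic-contribution logP
#'
#' Octanol-water partition coefficient estimated as a sum of per-atom
#' contributions, optionally multiplied by a scaling factor (the
#' parameterized-service contract: output = base value x scale). The built-in
#' table (`"semdesc-atomic-v1"`) uses coarse Wildman-Crippen-inspired atom
#' classes: aliphatic carbon bonded only to C/H, carbon bonded to a
#' heteroatom, aromatic carbon, amine-like nitrogen, carbonyl-type oxygen,
#' hydroxyl/ether oxygen, the common heteroatoms and halogens, and a
#' per-hydrogen term. Unknown environments fall back to a zero contribution.
#'
#' @param g a `molgraph`.
#' @param scale multiplicative scaling factor (default 1.0).
#' @param table contribution table identifier; only the built-in
#'   `"semdesc-atomic-v1"` is shipped.
#' @return logP estimate (double).
#' @export
logp <- function(g, scale = 1.0, table = "semdesc-atomic-v1") {
  stopifnot(inherits(g, "molgraph"), is.numeric(scale), length(scale) == 1L)
  if (!identical(table, "semdesc-atomic-v1"))
    stop("unknown logP contribution table: ", table, call. = FALSE)
  contrib <- vapply(seq_len(n_atoms(g)), function(k) logp_atom_class(g, k), 0)
  h_total <- sum(g$atoms$implicit_h)
  base <- sum(contrib) + LOGP_TABLE[["H"]] * h_total
  base * scale
}

LOGP_TABLE <- c(
  C_aliph  =  0.1441,   # sp3/sp2 carbon bonded only to C or H
  C_het    = -0.2035,   # carbon bonded to at least one heteroatom
  C_arom   =  0.1581,   # aromatic carbon
  N        = -1.0190,
  N_arom   = -0.3239,
  O_carbonyl = -0.1526, # oxygen in a double bond
  O        = -0.2893,   # hydroxyl / ether oxygen
  O_arom   =  0.1552,
  S        =  0.6482,
  P        =  0.8612,
  F        =  0.4202,
  Cl       =  0.6895,
  Br       =  0.8456,
  I        =  0.8857,
  B        =  0.1800,
  H        =  0.1230,
  fallback =  0.0000)

logp_atom_class <- function(g, k) {
  el <- g$atoms$element[k]
  arom <- g$atoms$aromatic[k]
  inc <- g$bonds[g$bonds$a == k | g$bonds$b == k, , drop = FALSE]
  other <- ifelse(inc$a == k, inc$b, inc$a)
  nbr_el <- g$atoms$element[other]
  cls <- if (el == "C") {
    if (arom) "C_arom"
    else if (any(!(nbr_el %in% c("C", "H")))) "C_het"
    else "C_aliph"
  } else if (el == "N") {
    if (arom) "N_arom" else "N"
  } else if (el == "O") {
    if (arom) "O_arom"
    else if (any(inc$order == "double")) "O_carbonyl"
    else "O"
  } else if (el == "H") {
    "H"
  } else if (el %in% names(LOGP_TABLE)) {
    el
  } else {
    "fallback"
  }
  LOGP_TABLE[[cls]]
}
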