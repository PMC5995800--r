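# Atom-environment and ring tokens.
#
# Each heavy atom maps to exactly one token determined by its element,
# formal charge, implicit hydrogen count, bond-order multiset and aromatic
# flag. The vocabulary reproduces the symbols conventional for this
# descriptor family ("-CH3", ">C(<)", ">C=", "-C(Ar)<", "-N<", "-N=",
# ">N+=", "=NH", "-OH", ">O", "=O", ">S", "-Cl", ">PH<", ...); environments
# outside it fall back to a generated `El(pattern)` token rather than
# failing, so screening never drops an atom.

#' Atom-environment token for one atom
#'
#' @param mol a `ql_molecule`.
#' @param atom atom index.
#' @return a single token string.
#' @examples
#' atom_token(parse_smiles("CC"), 1)      # "-CH3"
#' atom_token(parse_smiles("Clc1ccccc1"), 1)  # "-Cl"
#' @export
atom_token <- function(mol, atom) {
  stopifnot(inherits(mol, "ql_molecule"))
  n <- nrow(mol$atoms)
  if (!(is.numeric(atom) && length(atom) == 1L && atom >= 1L && atom <= n)) {
    stopf("atom index %s out of bounds (molecule has %d atoms)", toString(atom), n)
  }
  a <- mol$atoms[atom, ]
  b <- mol$bonds[mol$bonds$a1 == atom | mol$bonds$a2 == atom, , drop = FALSE]
  n_double <- sum(b$order == 2L & !b$aromatic)
  n_triple <- sum(b$order == 3L)
  el <- a$element; ch <- a$charge; nh <- a$n_h

  tok <- switch(
    el,
    C = {
      if (ch != 0L) NULL
      else if (a$aromatic) "-C(Ar)<"
      else if (n_triple >= 1L) { if (nh == 1L) "#CH" else if (nh == 0L) "-C#" else NULL }
      else if (n_double >= 2L) "=C="
      else if (n_double == 1L) switch(as.character(nh), `0` = ">C=", `1` = "=CH-", `2` = "=CH2", NULL)
      else switch(as.character(nh), `3` = "-CH3", `2` = "-CH2-", `1` = ">CH-", `0` = ">C(<)", NULL)
    },
    N = {
      if (ch == 1L && n_double >= 1L && nh == 0L) ">N+="
      else if (ch != 0L) NULL
      else if (n_triple >= 1L && nh == 0L) "#N"
      else if (n_double >= 1L) { if (nh == 0L) "-N=" else if (nh == 1L) "=NH" else NULL }
      else switch(as.character(nh), `0` = "-N<", `1` = ">NH", `2` = "-NH2", NULL)
    },
    O = {
      if (ch != 0L) NULL
      else if (n_double >= 1L) "=O"
      else if (nh == 1L) "-OH"
      else if (nh == 0L) ">O"
      else NULL
    },
    S = {
      if (ch != 0L || n_triple > 0L) NULL
      else if (n_double >= 1L && a$degree == 1L) "=S"
      else if (nh == 1L && a$degree == 1L) "-SH"
      else if (nh == 0L && a$degree == 2L && n_double == 0L) ">S"
      else NULL
    },
    P = {
      if (ch == 0L && nh == 1L && a$degree == 3L && n_double == 0L) ">PH<" else NULL
    },
    F = if (ch == 0L) "-F" else NULL,
    Cl = if (ch == 0L) "-Cl" else NULL,
    Br = if (ch == 0L) "-Br" else NULL,
    I = if (ch == 0L) "-I" else NULL,
    NULL
  )
  if (is.null(tok)) .fallback_token(a, b) else tok
}

.fallback_token <- function(a, b) {
  sprintf("%s(%sH%ds%dd%dt%d%s)",
          a$element,
          if (a$charge != 0L) sprintf("%+d", a$charge) else "",
          a$n_h,
          sum(b$order == 1L), sum(b$order == 2L), sum(b$order == 3L),
          if (a$aromatic) "Ar" else "")
}

#' Tokens for every atom of a molecule
#' @param mol a `ql_molecule`.
#' @return character vector, one token per heavy atom.
#' @export
atom_tokens <- function(mol) {
  vapply(seq_len(nrow(mol$atoms)), function(i) atom_token(mol, i), "")
}

#' Ring token for a perceived ring
#'
#' `CycNN` for an NN-membered aliphatic ring, `CycArNN` when the ring is
#' aromatic (so a benzene ring is `CycAr06`).
#'
#' @param size ring atom count.
#' @param aromatic logical aromatic flag.
#' @return token string.
#' @export
ring_token <- function(size, aromatic) {
  stopifnot(size >= 3L)
  sprintf("Cyc%s%02d", if (isTRUE(aromatic)) "Ar" else "", as.integer(size))
}

#' Ring tokens for every perceived ring of a molecule
#' @param mol a `ql_molecule`.
#' @return character vector, one token per SSSR ring.
#' @export
ring_tokens <- function(mol) {
  arom <- attr(mol$rings, "aromatic")
  sizes <- attr(mol$rings, "size")
  if (length(mol$rings) == 0L) return(character(0))
  vapply(seq_along(mol$rings), function(k) ring_token(sizes[k], arom[k]), "")
}
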