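# Molecular graphs for descriptor generation.
#
# Structures are parsed with OpenBabel (via ChemmineOB/ChemmineR) and stored
# in a light connection-table container: heavy atoms with formal charge,
# implicit hydrogen count and aromatic flag; kekulized bonds; the smallest
# set of smallest rings; and the all-pairs topological distance matrix.

# old-style V2000 charge field -> formal charge
.CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)

.DEFAULT_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, B = 3L,
                      Si = 4L, F = 1L, Cl = 1L, Br = 1L, I = 1L)

.parse_cache <- new.env(parent = emptyenv())

#' Parse a SMILES record into a molecule
#'
#' Builds the package's molecular-graph container from a SMILES string.
#' Aromaticity is perceived by OpenBabel; rings are the smallest set of
#' smallest rings; implicit hydrogens are derived from standard valences on
#' the kekulized connection table. Multi-fragment records (dot-disconnected
#' SMILES) are rejected: descriptors are defined on a connected graph.
#'
#' @param smiles single SMILES string.
#' @param id compound identifier; defaults to the SMILES itself.
#' @param cache reuse previously parsed structures for identical SMILES
#'   strings (parsing is deterministic, so this only saves time).
#' @return an object of class `ql_molecule`: a list with elements `id`,
#'   `smiles`, `atoms` (data frame: element, charge, n_h, aromatic, degree,
#'   in_ring), `bonds` (data frame: a1, a2, order, aromatic), `rings`
#'   (list of member-index vectors with `aromatic`/`size` attributes) and
#'   `dist` (topological distance matrix, bonds).
#' @examples
#' mol <- parse_smiles("c1ccccc1", id = "benzene")
#' mol$atoms$aromatic
#' @export
parse_smiles <- function(smiles, id = NULL, cache = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  if (is.null(id)) id <- smiles
  if (cache && !is.null(hit <- .parse_cache[[smiles]])) {
    hit$id <- id
    return(hit)
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, id))),
    error = function(e) {
      stopf("failed to parse SMILES for record '%s': %s", id, conditionMessage(e))
    }
  )
  mol <- molecule_from_sdf(sdf[[1]], id = id)
  mol$smiles <- smiles
  if (cache) {
    stored <- mol
    .parse_cache[[smiles]] <- stored
  }
  mol
}

#' Read a SMILES file
#'
#' One record per line: `SMILES` optionally followed by whitespace and an
#' identifier. Blank lines and lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return list of [parse_smiles()] molecules.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stopf("SMILES file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stopf("no SMILES records in '%s'", path)
  parts <- strsplit(lines, "[\t ]+")
  smiles <- vapply(parts, `[[`, "", 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][[2L]] else sprintf("mol_%04d", i)
  }, "")
  if (anyDuplicated(ids)) stopf("duplicate molecule ids in '%s'", path)
  Map(parse_smiles, smiles, ids)
}

#' Read molecules from an SDF (V2000) file
#'
#' @param path file path to a kekulized V2000 SD file.
#' @return list of `ql_molecule` objects, named by SDF record id.
#' @export
read_sdf_molecules <- function(path) {
  sdfset <- ChemmineR::read.SDFset(path)
  ok <- ChemmineR::validSDF(sdfset)
  if (!all(ok)) {
    stopf("invalid SDF record(s): %s",
          paste(ChemmineR::sdfid(sdfset)[!ok], collapse = ", "))
  }
  ids <- ChemmineR::sdfid(sdfset)
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  out <- lapply(seq_along(sdfset), function(i) molecule_from_sdf(sdfset[[i]], ids[i]))
  stats::setNames(out, ids)
}

#' Build a molecule from a ChemmineR SDF object
#'
#' @param sdf a `ChemmineR::SDF` instance (kekulized bond orders 1-3).
#' @param id compound identifier.
#' @return a `ql_molecule`.
#' @export
molecule_from_sdf <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  rn <- rownames(ab)
  if (is.null(rn) || !all(grepl("_", rn, fixed = TRUE))) {
    stopf("record '%s': molecules must contain at least two heavy atoms", id)
  }
  element <- sub("_.*$", "", rn)
  n <- length(element)

  charge <- rep(0L, n)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(as.integer(ab[, "C6"]))
    known <- code %in% names(.CHARGE_CODE)
    charge[known] <- .CHARGE_CODE[code[known]]
  }

  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1L, dimnames = list(NULL, names(bb)))
  a1 <- as.integer(bb[, 1L]); a2 <- as.integer(bb[, 2L]); ord <- as.integer(bb[, 3L])
  if (any(a1 < 1L | a1 > n | a2 < 1L | a2 > n)) {
    stopf("record '%s': bond references a non-existent atom", id)
  }
  if (any(!ord %in% 1:3)) {
    stopf("record '%s': unsupported bond order(s) %s (kekulized input required)",
          id, paste(unique(ord[!ord %in% 1:3]), collapse = ", "))
  }

  adj <- vector("list", n)
  for (b in seq_along(a1)) {
    adj[[a1[b]]] <- c(adj[[a1[b]]], a2[b])
    adj[[a2[b]]] <- c(adj[[a2[b]]], a1[b])
  }

  dist <- .all_pairs_bfs(adj, n)
  if (any(is.infinite(dist))) {
    stopf("record '%s': multi-fragment structure rejected (descriptors require a connected graph)", id)
  }

  rng <- ChemmineR::rings(sdf, type = "all", arom = TRUE, inner = TRUE)
  ring_members <- lapply(rng$RINGS, function(r) sort(as.integer(sub("^.*_", "", r))))
  ring_arom <- as.logical(rng$AROMATIC)
  if (length(ring_members) == 0L) ring_arom <- logical(0)

  aromatic <- rep(FALSE, n)
  for (k in seq_along(ring_members)) {
    if (ring_arom[k]) aromatic[ring_members[[k]]] <- TRUE
  }
  in_ring <- rep(FALSE, n)
  for (k in seq_along(ring_members)) in_ring[ring_members[[k]]] <- TRUE

  bond_arom <- vapply(seq_along(a1), function(b) {
    any(vapply(seq_along(ring_members), function(k) {
      ring_arom[k] && all(c(a1[b], a2[b]) %in% ring_members[[k]])
    }, logical(1)))
  }, logical(1))
  if (length(a1) == 0L) bond_arom <- logical(0)

  order_sum <- vapply(seq_len(n), function(i) {
    sum(ord[a1 == i | a2 == i])
  }, integer(1))
  n_h <- .implicit_h(element, charge, order_sum)

  atoms <- data.frame(
    element = element, charge = charge, n_h = n_h,
    aromatic = aromatic, degree = lengths(adj), in_ring = in_ring,
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(a1 = a1, a2 = a2, order = ord, aromatic = bond_arom)
  rings <- unname(ring_members)
  attr(rings, "aromatic") <- unname(ring_arom)
  attr(rings, "size") <- unname(lengths(ring_members))

  structure(
    list(id = id, smiles = NA_character_, atoms = atoms, bonds = bonds,
         rings = rings, adj = adj, dist = dist),
    class = "ql_molecule"
  )
}

.all_pairs_bfs <- function(adj, n) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0L
    while (length(frontier) > 0L) {
      depth <- depth + 1L
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

.implicit_h <- function(element, charge, order_sum) {
  val <- .DEFAULT_VALENCE[element]
  unknown <- is.na(val)
  val[unknown] <- order_sum[unknown]   # no implicit H for exotic elements
  adj <- ifelse(element %in% c("N", "P", "O", "S"), charge, -abs(charge))
  pmax(0L, as.integer(val + adj - order_sum))
}

#' @export
print.ql_molecule <- function(x, ...) {
  cat(sprintf("<ql_molecule> %s: %d heavy atoms, %d bonds, %d ring(s)%s\n",
              x$id, nrow(x$atoms), nrow(x$bonds), length(x$rings),
              if (!is.na(x$smiles)) paste0("  [", x$smiles, "]") else ""))
  invisible(x)
}

#' Check the structural invariants of a molecule
#'
#' Verifies bond indices, aromatic-bond consistency and connectivity;
#' intended for defensive use after constructing molecules from external
#' SDF sources.
#'
#' @param mol a `ql_molecule`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_molecule <- function(mol) {
  stopifnot(inherits(mol, "ql_molecule"))
  n <- nrow(mol$atoms)
  if (nrow(mol$bonds) > 0L && any(c(mol$bonds$a1, mol$bonds$a2) > n)) {
    stopf("molecule '%s': bond references missing atom", mol$id)
  }
  if (any(mol$bonds$aromatic &
          !(mol$atoms$aromatic[mol$bonds$a1] & mol$atoms$aromatic[mol$bonds$a2]))) {
    stopf("molecule '%s': aromatic bond between non-aromatic atoms", mol$id)
  }
  if (any(is.infinite(mol$dist))) {
    stopf("molecule '%s': disconnected graph", mol$id)
  }
  invisible(TRUE)
}
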