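# Fragment-pair descriptor enumeration.
#
# A descriptor is a projection of the quadruple (SD1, LD, SD2, BD) onto a
# non-empty slot subset: SD1/SD2 are atom-environment or ring tokens, LD is
# the topological length (shortest-path bond count) between the two
# fragments, and BD is a five-letter code classifying the bonds along one
# canonical shortest path:
#
#   "..."  pure single-bond path
#   ".a."  single-bond path touching the aromatic system (an atom on the
#          path, including endpoints, is aromatic)
#   ".A."  path running through an aromatic ring (an aromatic bond on path)
#   "p.."  path containing a pi (double/triple) bond, no aromatic contact
#   "pA."  pi bond on a path that also touches the aromatic system
#
# Rings participate as entities via their atom sets; the distance between
# two entities is the minimum topological distance between their sets, so a
# ring is at distance 0 from its own member atoms. Symmetric pairs are
# stored with the lexicographically smaller token first.

.SLOTS <- c("sd1", "ld", "sd2", "bd")

# enumeration is deterministic, so profiles of identical structures under
# identical settings can be reused across calls (screening simulations
# revisit the same SMILES many times)
.profile_cache <- new.env(parent = emptyenv())

#' Default descriptor families
#'
#' The slot subsets enumerated by default: bare tokens, bare lengths, bare
#' bond codes, token+length, length+bond, token pairs, and the full
#' quadruples (with and without each of LD/BD).
#'
#' @return list of character vectors, each a subset of
#'   `c("sd1","ld","sd2","bd")`.
#' @export
ql_families <- function() {
  list("sd1", "ld", "bd",
       c("sd1", "ld"), c("ld", "bd"),
       c("sd1", "sd2"), c("sd1", "ld", "sd2"), c("sd1", "sd2", "bd"),
       c("sd1", "ld", "sd2", "bd"))
}

.check_families <- function(families) {
  if (!is.list(families) || length(families) == 0L) {
    stopf("`families` must be a non-empty list of slot subsets")
  }
  for (f in families) {
    if (length(f) == 0L || !all(f %in% .SLOTS)) {
      stopf("invalid descriptor family: {%s}", paste(f, collapse = ","))
    }
    if ("sd2" %in% f && !"sd1" %in% f) {
      stopf("descriptor family {%s} has sd2 without sd1", paste(f, collapse = ","))
    }
  }
  invisible(TRUE)
}

.bond_lookup <- function(mol) {
  n <- nrow(mol$atoms)
  ord <- matrix(0L, n, n)
  arom <- matrix(FALSE, n, n)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    idx <- cbind(c(b$a1, b$a2), c(b$a2, b$a1))
    ord[idx] <- c(b$order, b$order)
    arom[idx] <- c(b$aromatic, b$aromatic)
  }
  list(order = ord, aromatic = arom)
}

.canonical_shortest_path <- function(mol, i, j) {
  # greedy descent on distance-to-j, always taking the smallest-index
  # neighbour: yields the lexicographically smallest shortest atom-index path
  path <- i
  cur <- i
  while (cur != j) {
    nb <- mol$adj[[cur]]
    nb <- sort(nb[mol$dist[nb, j] == mol$dist[cur, j] - 1])
    cur <- nb[1L]
    path <- c(path, cur)
  }
  path
}

.path_code_from_lookup <- function(mol, path, lut) {
  if (length(path) < 2L) return("")
  u <- path[-length(path)]
  v <- path[-1L]
  bond_arom <- lut$aromatic[cbind(u, v)]
  bond_pi <- lut$order[cbind(u, v)] >= 2L & !bond_arom
  atom_arom <- mol$atoms$aromatic[path]
  has_ar <- any(bond_arom) || any(atom_arom)
  if (any(bond_pi) && has_ar) "pA."
  else if (any(bond_arom)) ".A."
  else if (any(bond_pi)) "p.."
  else if (any(atom_arom)) ".a."
  else "..."
}

#' Bond-path code between two atoms
#'
#' Classifies the bonds along the canonical shortest path between atoms
#' `i` and `j` (ties between equally short paths broken by taking the
#' lexicographically smallest atom-index path), returning one of the five
#' codes `"..."`, `".a."`, `".A."`, `"p.."`, `"pA."`.
#'
#' @param mol a `ql_molecule`.
#' @param i,j distinct atom indices.
#' @return a single code string.
#' @examples
#' path_bond_code(parse_smiles("CC"), 1, 2)    # "..."
#' path_bond_code(parse_smiles("C=CC"), 1, 3)  # "p.."
#' @export
path_bond_code <- function(mol, i, j) {
  stopifnot(inherits(mol, "ql_molecule"))
  n <- nrow(mol$atoms)
  if (i == j) stopf("path_bond_code requires two distinct atoms")
  if (min(i, j) < 1L || max(i, j) > n) stopf("atom index out of bounds")
  if (is.infinite(mol$dist[i, j])) stopf("atoms %d and %d are disconnected", i, j)
  .path_code_from_lookup(mol, .canonical_shortest_path(mol, i, j), .bond_lookup(mol))
}

#' Enumerate fragment-pair descriptors of a molecule
#'
#' Every heavy atom and every perceived ring contributes a token entity;
#' for each unordered pair of distinct entities at topological distance at
#' most `max_length` the full (SD1, LD, SD2, BD) quadruple is formed and
#' projected onto each requested family. Families containing a single SD
#' slot are counted per entity end (the bare `"sd1"` family enumerates the
#' entities themselves, so its total equals heavy atoms + rings).
#'
#' @param mol a `ql_molecule`.
#' @param max_length maximum topological length considered (default 5,
#'   matching the lengths that occur in practice for this fragment family).
#' @param families list of slot subsets, see [ql_families()].
#' @return a `ql_profile`: data frame with columns `sd1`, `ld`, `sd2`,
#'   `bd`, `count` (empty slots are `""`/`NA`), molecule id in
#'   `attr(, "id")`.
#' @examples
#' enumerate_descriptors(parse_smiles("CC"), families = list(c("sd1","ld","sd2","bd")))
#' @export
enumerate_descriptors <- function(mol, max_length = 5L,
                                  families = ql_families()) {
  stopifnot(inherits(mol, "ql_molecule"), max_length >= 0L)
  .check_families(families)

  cache_key <- if (!is.na(mol$smiles)) {
    paste(mol$smiles, max_length,
          paste(vapply(families, paste, "", collapse = "+"), collapse = ";"),
          sep = "\r")
  } else {
    NA_character_
  }
  if (!is.na(cache_key) && !is.null(hit <- .profile_cache[[cache_key]])) {
    attr(hit, "id") <- mol$id
    return(hit)
  }

  lut <- .bond_lookup(mol)

  atok <- atom_tokens(mol)
  rtok <- ring_tokens(mol)
  tokens <- c(atok, rtok)
  sets <- c(as.list(seq_along(atok)), unname(as.list(mol$rings)))
  m <- length(tokens)

  singleton_sd1 <- any(vapply(families, function(f) identical(sort(f), "sd1"), logical(1)))
  pair_families <- families[!vapply(families, function(f) identical(sort(f), "sd1"), logical(1))]

  acc <- list()
  if (singleton_sd1) {
    acc[[length(acc) + 1L]] <- paste(tokens, "", "", "", sep = "|")
  }

  if (length(pair_families) > 0L && m >= 2L) {
    for (p in seq_len(m - 1L)) {
      sp <- sets[[p]]
      for (q in seq((p + 1L), m)) {
        sq <- sets[[q]]
        sub <- mol$dist[sp, sq, drop = FALSE]
        d <- min(sub)
        if (d > max_length) next
        if (d == 0) {
          bd_full <- ""
        } else {
          w <- which(sub == d, arr.ind = TRUE)
          w <- w[order(sp[w[, 1L]], sq[w[, 2L]]), , drop = FALSE]
          i <- sp[w[1L, 1L]]; j <- sq[w[1L, 2L]]
          bd_full <- .path_code_from_lookup(mol, .canonical_shortest_path(mol, i, j), lut)
        }
        t1 <- tokens[p]; t2 <- tokens[q]
        if (t2 < t1) { tmp <- t1; t1 <- t2; t2 <- tmp }
        pair_keys <- unlist(lapply(pair_families, function(f) {
          ld <- if ("ld" %in% f) d else ""
          bd <- if ("bd" %in% f) bd_full else ""
          if ("sd2" %in% f) {
            paste(t1, ld, t2, bd, sep = "|")
          } else if ("sd1" %in% f) {
            paste(c(tokens[p], tokens[q]), ld, "", bd, sep = "|")
          } else {
            paste("", ld, "", bd, sep = "|")
          }
        }), use.names = FALSE)
        acc[[length(acc) + 1L]] <- pair_keys
      }
    }
  }

  keys <- unlist(acc, use.names = FALSE)
  if (is.null(keys)) keys <- character(0)
  tab <- table(keys)
  parts <- strsplit(names(tab), "|", fixed = TRUE)
  prof <- data.frame(
    sd1 = vapply(parts, function(x) if (length(x) >= 1L) x[1L] else "", ""),
    ld = suppressWarnings(as.integer(vapply(parts, function(x) if (length(x) >= 2L) x[2L] else "", ""))),
    sd2 = vapply(parts, function(x) if (length(x) >= 3L) x[3L] else "", ""),
    bd = vapply(parts, function(x) if (length(x) >= 4L) x[4L] else "", ""),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  prof <- prof[order(names(tab), method = "radix"), , drop = FALSE]
  rownames(prof) <- NULL
  attr(prof, "id") <- mol$id
  class(prof) <- c("ql_profile", "data.frame")
  if (!is.na(cache_key)) .profile_cache[[cache_key]] <- prof
  prof
}

#' Canonical key strings of a descriptor profile
#' @param profile a `ql_profile` (or any data frame with sd1/ld/sd2/bd).
#' @return character vector of `sd1|ld|sd2|bd` keys.
#' @export
descriptor_keys <- function(profile) {
  ld <- ifelse(is.na(profile$ld), "", as.character(profile$ld))
  paste(profile$sd1, ld, profile$sd2, profile$bd, sep = "|")
}

#' Enumerate descriptors for a list of molecules
#' @param molecules list of `ql_molecule` objects.
#' @inheritParams enumerate_descriptors
#' @return named list of `ql_profile` objects.
#' @export
profile_library <- function(molecules, max_length = 5L, families = ql_families()) {
  ids <- vapply(molecules, `[[`, "", "id")
  stats::setNames(lapply(molecules, enumerate_descriptors,
                         max_length = max_length, families = families), ids)
}
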