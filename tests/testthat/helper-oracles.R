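# Independent oracles used across the suite. Each is written from the
# definition, not from the package's code paths.

# Exhaustive hypergeometric tail: enumerate every subset of size n_active
# from an urn of n_total items of which total_key are marked, and count
# draws with at least / at most k_active marked items.
brute_hypergeom <- function(k_active, total_key, n_active, n_total,
                            direction = "enriched") {
  marked <- seq_len(total_key)
  draws <- utils::combn(n_total, n_active)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked))
  if (direction == "enriched") mean(hits >= k_active) else mean(hits <= k_active)
}

# All valid count tuples (k, total_key, n_active, n_total) for a given
# urn size bound.
valid_hyper_tuples <- function(max_total) {
  out <- list()
  for (N in 1:max_total) for (K in 0:N) for (n in 0:N) {
    lo <- max(0L, n - (N - K)); hi <- min(K, n)
    for (k in lo:hi) out[[length(out) + 1L]] <- c(k = k, K = K, n = n, N = N)
  }
  do.call(rbind, out)
}

# Closed-form Spearman for tie-free vectors.
closed_form_spearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Brute-force descriptor enumerator, independent of the package's
# enumeration internals: igraph shortest paths, naive all-pairs loops,
# its own canonical-path selection and bond classification. Reuses only
# the parsed molecule and its token vocabulary.
brute_profile_keys <- function(mol, max_length = 5L, families = iopqsar::ql_families()) {
  g <- igraph::graph_from_edgelist(cbind(mol$bonds$a1, mol$bonds$a2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mol$atoms) - igraph::vcount(g)))
  D <- igraph::distances(g)

  bond_of <- function(u, v) {
    hit <- which((mol$bonds$a1 == u & mol$bonds$a2 == v) |
                   (mol$bonds$a1 == v & mol$bonds$a2 == u))
    mol$bonds[hit, ]
  }
  classify_path <- function(path) {
    if (length(path) < 2L) return("")
    arom_bond <- pi_bond <- FALSE
    for (s in seq_len(length(path) - 1L)) {
      b <- bond_of(path[s], path[s + 1L])
      if (b$aromatic) arom_bond <- TRUE
      else if (b$order >= 2L) pi_bond <- TRUE
    }
    arom_atom <- any(mol$atoms$aromatic[path])
    if (pi_bond && (arom_bond || arom_atom)) "pA."
    else if (arom_bond) ".A."
    else if (pi_bond) "p.."
    else if (arom_atom) ".a."
    else "..."
  }
  lex_smallest_path <- function(i, j) {
    paths <- igraph::all_shortest_paths(g, from = i, to = j)$vpaths
    mats <- lapply(paths, as.integer)
    mats[[order(vapply(mats, function(p) paste(sprintf("%04d", p), collapse = ""), ""))[1L]]]
  }

  atok <- iopqsar::atom_tokens(mol)
  rtok <- iopqsar::ring_tokens(mol)
  tokens <- c(atok, rtok)
  sets <- c(as.list(seq_along(atok)), unname(as.list(mol$rings)))

  keys <- character(0)
  fam_sig <- vapply(families, function(f) paste(sort(f), collapse = "+"), "")
  if ("sd1" %in% fam_sig) keys <- c(keys, paste(tokens, "", "", "", sep = "|"))
  pair_fams <- families[fam_sig != "sd1"]

  m <- length(tokens)
  if (m >= 2L) {
    for (p in 1:(m - 1L)) for (q in (p + 1L):m) {
      dsub <- D[sets[[p]], sets[[q]], drop = FALSE]
      d <- min(dsub)
      if (d > max_length) next
      if (d == 0) {
        bd <- ""
      } else {
        best <- NULL
        for (ii in sets[[p]]) for (jj in sets[[q]]) {
          if (D[ii, jj] == d && (is.null(best) || ii < best[1] || (ii == best[1] && jj < best[2]))) {
            best <- c(ii, jj)
          }
        }
        bd <- classify_path(lex_smallest_path(best[1], best[2]))
      }
      ts <- sort(c(tokens[p], tokens[q]), method = "radix")
      for (f in pair_fams) {
        ldv <- if ("ld" %in% f) d else ""
        bdv <- if ("bd" %in% f) bd else ""
        if ("sd2" %in% f) {
          keys <- c(keys, paste(ts[1], ldv, ts[2], bdv, sep = "|"))
        } else if ("sd1" %in% f) {
          keys <- c(keys, paste(tokens[p], ldv, "", bdv, sep = "|"),
                    paste(tokens[q], ldv, "", bdv, sep = "|"))
        } else {
          keys <- c(keys, paste("", ldv, "", bdv, sep = "|"))
        }
      }
    }
  }
  sort(keys, method = "radix")
}

# Expand a profile back to one key string per descriptor instance.
profile_instances <- function(profile) {
  sort(rep(iopqsar::descriptor_keys(profile), profile$count), method = "radix")
}

# Exhaustive best 2-partition by within-cluster sum of squares (k-means
# oracle for small n).
best_two_partition <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    if (sum(grp) == 0 || sum(grp) == n) next
    wss <- sum(apply(x[grp == 1, , drop = FALSE], 2, function(c) sum((c - mean(c))^2))) +
      sum(apply(x[grp == 0, , drop = FALSE], 2, function(c) sum((c - mean(c))^2)))
    if (is.null(best) || wss < best$wss) best <- list(wss = wss, grp = grp)
  }
  best
}

# Hand-built tiny descriptor profile for frequency arithmetic tests.
make_profile <- function(id, keys, counts) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  slot <- function(i) vapply(parts, function(x) if (length(x) >= i) x[i] else "", "")
  p <- data.frame(sd1 = slot(1), ld = suppressWarnings(as.integer(slot(2))),
                  sd2 = slot(3), bd = slot(4), count = as.integer(counts),
                  stringsAsFactors = FALSE)
  attr(p, "id") <- id
  class(p) <- c("ql_profile", "data.frame")
  p
}
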