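# Pharmacophore enrichment.
#
# For every descriptor key the frequency in the active class (Pa) and the
# inactive class (Pi) is computed, together with a one-sided hypergeometric
# tail probability Pr for the observed class imbalance. A key is a
# potential pharmacophore of *presence* of activity when Pr <= alpha and
# Pa > Pi, of *absence* when Pr <= alpha and Pi > Pa, and neutral
# otherwise. No multiplicity correction is applied by default; a
# Benjamini-Hochberg option is available.
#
# Two urn models are supported. In "occurrence" mode (default) the urn
# holds every descriptor instance in the library, Pa is the share of the
# active class's instances carrying the key, and the test draws the active
# class's instances from the pooled instances. In "compound" mode the urn
# holds compounds and a key is counted once per compound containing it.

#' One-sided hypergeometric tail probability
#'
#' Probability of drawing at least (`direction = "enriched"`) or at most
#' (`direction = "depleted"`) `k_active` marked items in `n_active` draws
#' without replacement from `n_total` items of which `total_key` are
#' marked. Terms are accumulated in log space for numerical stability.
#'
#' @param k_active observed marked draws.
#' @param total_key marked items in the urn.
#' @param n_active number of draws.
#' @param n_total urn size.
#' @param direction `"enriched"` (upper tail) or `"depleted"` (lower tail).
#' @return tail probability in (0, 1].
#' @examples
#' hypergeometric_pr(2, 2, 2, 4)  # 1/6
#' @export
hypergeometric_pr <- function(k_active, total_key, n_active, n_total,
                              direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  k <- as.numeric(k_active); K <- as.numeric(total_key)
  n <- as.numeric(n_active); N <- as.numeric(n_total)
  if (any(c(k, K, n, N) < 0) || K > N || n > N) {
    stopf("inconsistent counts: k=%g, total_key=%g, n_active=%g, n_total=%g", k, K, n, N)
  }
  lo <- max(0, n - (N - K))   # smallest feasible k
  hi <- min(K, n)             # largest feasible k
  if (k < lo || k > hi) {
    stopf("k_active=%g outside feasible range [%g, %g]", k, lo, hi)
  }
  xs <- if (direction == "enriched") seq(k, hi) else seq(lo, k)
  logp <- lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)
  min(1, exp(logsumexp(logp)))
}

#' Hypergeometric point probability (log-space)
#' @inheritParams hypergeometric_pr
#' @return P(X = k_active).
#' @export
hypergeometric_point <- function(k_active, total_key, n_active, n_total) {
  exp(lchoose(total_key, k_active) +
        lchoose(n_total - total_key, n_active - k_active) -
        lchoose(n_total, n_active))
}

#' Per-key class frequencies
#'
#' @param profiles list of `ql_profile` objects (one per molecule).
#' @param labels binary vector (1 = active, 0 = inactive), one per profile.
#' @param mode `"occurrence"` (instance-based urn, default) or
#'   `"compound"` (presence/absence per compound).
#' @return data frame with one row per distinct key: `sd1`, `ld`, `sd2`,
#'   `bd`, `pa`, `pi`, `k_active`, `k_inactive`, and the urn margins
#'   `n_active_total`, `n_inactive_total` in attributes and columns.
#' @export
class_frequencies <- function(profiles, labels, mode = c("occurrence", "compound")) {
  mode <- match.arg(mode)
  labels <- .check_labels(labels, length(profiles))

  key_list <- lapply(profiles, descriptor_keys)
  cnt_list <- lapply(profiles, function(p) {
    cnt <- p$count
    if (mode == "compound") cnt <- as.integer(cnt > 0L)
    cnt
  })
  all_keys <- sort(unique(unlist(key_list, use.names = FALSE)), method = "radix")
  k_act <- k_inact <- stats::setNames(numeric(length(all_keys)), all_keys)
  for (i in seq_along(profiles)) {
    tgt <- if (labels[i] == 1L) "a" else "i"
    idx <- match(key_list[[i]], all_keys)
    if (tgt == "a") k_act[idx] <- k_act[idx] + cnt_list[[i]]
    else k_inact[idx] <- k_inact[idx] + cnt_list[[i]]
  }
  n_act_total <- if (mode == "occurrence") {
    sum(unlist(cnt_list[labels == 1L], use.names = FALSE))
  } else {
    sum(labels == 1L)
  }
  n_inact_total <- if (mode == "occurrence") {
    sum(unlist(cnt_list[labels == 0L], use.names = FALSE))
  } else {
    sum(labels == 0L)
  }

  parts <- strsplit(all_keys, "|", fixed = TRUE)
  slot <- function(i) vapply(parts, function(x) if (length(x) >= i) x[i] else "", "")
  out <- data.frame(
    sd1 = slot(1L),
    ld = suppressWarnings(as.integer(slot(2L))),
    sd2 = slot(3L),
    bd = slot(4L),
    pa = unname(k_act) / n_act_total,
    pi = unname(k_inact) / n_inact_total,
    k_active = unname(k_act),
    k_inactive = unname(k_inact),
    n_active_total = n_act_total,
    n_inactive_total = n_inact_total,
    stringsAsFactors = FALSE
  )
  attr(out, "mode") <- mode
  out
}

.check_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n) stopf("need one label per molecule (%d != %d)", length(labels), n)
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary 0/1")
  if (sum(labels == 1L) == 0L) stopf("active class is empty")
  if (sum(labels == 0L) == 0L) stopf("inactive class is empty")
  labels
}

#' Apply the pharmacophore presence/absence rule
#'
#' Adds the one-sided hypergeometric significance `pr` (direction chosen by
#' the sign of `pa - pi`) and the label: `"presence"` when `pr <= alpha`
#' and `pa > pi`, `"absence"` when `pr <= alpha` and `pi > pa`, otherwise
#' `"neutral"` (ties `pa == pi` are neutral).
#'
#' @param freq data frame from [class_frequencies()].
#' @param alpha significance level in (0, 1), default 0.05.
#' @param adjust `"none"` (default, mirroring common practice for this
#'   screen) or `"BH"` for Benjamini-Hochberg adjustment of `pr` before
#'   thresholding.
#' @return `freq` with columns `pr` and `label` appended, sorted by `pr`.
#' @export
classify_pharmacophores <- function(freq, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stopf("`alpha` must be a single value in (0, 1)")
  }
  n_tot <- freq$n_active_total + freq$n_inactive_total
  tot_key <- freq$k_active + freq$k_inactive
  pr <- vapply(seq_len(nrow(freq)), function(r) {
    dir <- if (freq$pa[r] > freq$pi[r]) "enriched" else "depleted"
    hypergeometric_pr(freq$k_active[r], tot_key[r],
                      freq$n_active_total[r], n_tot[r], dir)
  }, numeric(1))
  pr_eff <- if (adjust == "BH") stats::p.adjust(pr, method = "BH") else pr
  label <- ifelse(pr_eff <= alpha & freq$pa > freq$pi, "presence",
                  ifelse(pr_eff <= alpha & freq$pi > freq$pa, "absence", "neutral"))
  out <- freq
  out$pr <- pr
  out$label <- label
  out <- out[order(out$pr, descriptor_keys(out), method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  class(out) <- c("ql_enrichment", "data.frame")
  out
}

#' Screen a molecule library for pharmacophores
#'
#' Composition of descriptor enumeration, class-frequency computation and
#' the presence/absence rule over all enumerated keys.
#'
#' @param molecules list of `ql_molecule` objects.
#' @param labels binary activity labels (1 active / 0 inactive).
#' @param max_length,families passed to [enumerate_descriptors()].
#' @param mode,alpha,adjust passed on to the frequency/classification steps.
#' @return a `ql_enrichment` data frame, one row per distinct key.
#' @export
screen_library <- function(molecules, labels, max_length = 5L,
                           families = ql_families(),
                           mode = c("occurrence", "compound"),
                           alpha = 0.05, adjust = c("none", "BH")) {
  profiles <- profile_library(molecules, max_length = max_length, families = families)
  freq <- class_frequencies(profiles, labels, mode = match.arg(mode))
  classify_pharmacophores(freq, alpha = alpha, adjust = match.arg(adjust))
}

#' Re-check printed enrichment rows against the classification rule
#'
#' Given a table with `pa`, `pi`, `pr` columns (for example the packaged
#' presence/absence fixtures), returns the rule's verdict for each row and
#' flags mismatches with an expected label.
#'
#' @param tab data frame with numeric `pa`, `pi`, `pr`.
#' @param expected optional single label all rows are expected to carry.
#' @param alpha significance level.
#' @return `tab` with a `label` column (and `mismatch` if `expected` given).
#' @export
check_pharmacophore_table <- function(tab, expected = NULL, alpha = 0.05) {
  stopifnot(all(c("pa", "pi", "pr") %in% names(tab)))
  label <- ifelse(tab$pr <= alpha & tab$pa > tab$pi, "presence",
                  ifelse(tab$pr <= alpha & tab$pi > tab$pa, "absence", "neutral"))
  tab$label <- label
  if (!is.null(expected)) tab$mismatch <- label != expected
  tab
}
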