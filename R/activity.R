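# Hypotensive potency scale and IOP activity classing.
#
# Hypotensive potency is measured as ED20, the dose lowering systemic
# arterial pressure by 20%. An ordinal index condenses ED20 (mg/kg) into
# 0-3 points on fixed thresholds; doses convert to umol/kg through the
# molecular weight. Compounds are split into IOP-active and IOP-inactive
# classes by k-means (k = 2) over six IOP-lowering indicators.

#' Ordinal potency index from ED20
#'
#' 3 points for ED20 <= 4.0 mg/kg, 2 for 4.0 < ED20 <= 10.0, 1 for
#' 10.0 < ED20 <= 25.0, 0 for ED20 > 25.0. Range boundaries are
#' left-open/right-closed, which reproduces the published index of every
#' compound in the packaged activity table and the bendazole reference
#' (18.8 mg/kg, index 1).
#'
#' @param ed20 positive dose(s) in mg/kg.
#' @return integer vector of index points in {0, 1, 2, 3}.
#' @examples
#' index_from_ed20(c(3.6, 6.6, 18.8, 51.2))  # 3 2 1 0
#' @export
index_from_ed20 <- function(ed20) {
  if (!is.numeric(ed20) || any(!is.finite(ed20)) || any(ed20 <= 0)) {
    stopf("ED20 doses must be positive finite numbers")
  }
  as.integer(ifelse(ed20 <= 4, 3L, ifelse(ed20 <= 10, 2L, ifelse(ed20 <= 25, 1L, 0L))))
}

#' Convert a dose from mg/kg to umol/kg
#'
#' @param ed20 dose(s) in mg/kg, positive.
#' @param mw molecular weight(s) in g/mol, positive.
#' @return dose in umol/kg (`ed20 / mw * 1000`).
#' @examples
#' mgkg_to_umolkg(18.8, 208.26)  # ~90.3 for bendazole
#' @export
mgkg_to_umolkg <- function(ed20, mw) {
  if (!is.numeric(ed20) || any(!is.finite(ed20)) || any(ed20 <= 0)) {
    stopf("doses must be positive finite numbers")
  }
  if (!is.numeric(mw) || any(!is.finite(mw)) || any(mw <= 0)) {
    stopf("molecular weights must be positive finite numbers")
  }
  ed20 / mw * 1000
}

# IUPAC 2021 standard atomic weights, abridged
.ATOMIC_WEIGHT <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                    F = 18.998, Si = 28.085, P = 30.974, S = 32.06,
                    Cl = 35.45, Br = 79.904, I = 126.904)

#' Molecular weight from a molecular formula
#'
#' @param formula Hill-style formula string, e.g. `"C14H12N2"`.
#' @return average molecular weight in g/mol.
#' @examples
#' formula_weight("C14H12N2")  # bendazole, ~208.26
#' @export
formula_weight <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)(\\d*)", formula))[[1]]
  if (paste(parts, collapse = "") != formula) {
    stopf("cannot parse molecular formula '%s'", formula)
  }
  el <- sub("\\d*$", "", parts)
  cnt <- as.numeric(sub("^[A-Za-z]+", "", parts))
  cnt[is.na(cnt)] <- 1
  if (!all(el %in% names(.ATOMIC_WEIGHT))) {
    stopf("unknown element(s) in formula '%s': %s", formula,
          paste(setdiff(el, names(.ATOMIC_WEIGHT)), collapse = ", "))
  }
  sum(.ATOMIC_WEIGHT[el] * cnt)
}

#' k-means separation into IOP-active and IOP-inactive classes
#'
#' Lloyd's algorithm on column-standardized indicators, best of `restarts`
#' random initializations by total within-cluster sum of squares. The
#' cluster whose centroid has the larger mean indicator value (larger mean
#' IOP lowering) is labelled 1 (active).
#'
#' @param iop numeric matrix or data frame of IOP-lowering indicators,
#'   rows = compounds (rownames used as codes), columns = indicators.
#' @param k number of clusters, default 2.
#' @param seed RNG seed for the initializations (mandatory: the reference
#'   implementation's initialization is not reproducible otherwise).
#' @param restarts number of random starts, default 50.
#' @param standardize z-score columns first (default TRUE; the indicators
#'   may be on different scales).
#' @return list with `labels` (named binary vector, 1 = active),
#'   `centers` (on the standardized scale), `tot_withinss`, and the
#'   underlying [stats::kmeans()] fit.
#' @export
cluster_activity <- function(iop, k = 2L, seed, restarts = 50L, standardize = TRUE) {
  if (missing(seed)) stopf("`seed` is required for reproducible clustering")
  x <- as.matrix(iop)
  if (!is.numeric(x) || any(!is.finite(x))) stopf("indicator matrix must be finite numeric")
  if (nrow(unique(as.data.frame(x))) < k) {
    stopf("fewer than k = %d distinct indicator rows", k)
  }
  z <- if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    sds[sds == 0] <- 1
    scale(x, center = TRUE, scale = sds)
  } else {
    x
  }
  fit <- with_seed(seed, stats::kmeans(z, centers = k, nstart = restarts,
                                       iter.max = 100L, algorithm = "Lloyd"))
  active_cluster <- which.max(rowMeans(fit$centers))
  labels <- as.integer(fit$cluster == active_cluster)
  names(labels) <- rownames(x)
  list(labels = labels, centers = fit$centers,
       tot_withinss = fit$tot.withinss, fit = fit)
}

#' Load a hypotensive activity table
#'
#' Expects a CSV with columns `code`, `ed20_mg_kg`, `index`,
#' `ed20_umol_kg`, `level` and optionally `iop_cluster`. Doses must be
#' positive; the printed index of every row is checked against
#' [index_from_ed20()].
#'
#' @param path CSV path.
#' @param check what to do when a row's index disagrees with its ED20:
#'   `"error"` (default), `"warn"`, or `"none"`.
#' @return data frame of activity profiles.
#' @export
load_activity_table <- function(path, check = c("error", "warn", "none")) {
  check <- match.arg(check)
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stopf("cannot read '%s': %s", path, conditionMessage(e)))
  if (nrow(tab) == 0L) stopf("activity table '%s' is empty", path)
  required <- c("code", "ed20_mg_kg", "index", "ed20_umol_kg", "level")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stopf("activity table '%s' lacks column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  for (col in c("ed20_mg_kg", "index", "ed20_umol_kg", "level")) {
    if (!is.numeric(tab[[col]])) stopf("column '%s' is not numeric in '%s'", col, path)
  }
  bad_dose <- which(!is.finite(tab$ed20_mg_kg) | tab$ed20_mg_kg <= 0)
  if (length(bad_dose) > 0L) {
    stopf("non-positive ED20 in row(s): %s", paste(tab$code[bad_dose], collapse = ", "))
  }
  mism <- which(index_from_ed20(tab$ed20_mg_kg) != tab$index)
  if (length(mism) > 0L && check != "none") {
    msg <- sprintf("index inconsistent with ED20 for row(s): %s",
                   paste(tab$code[mism], collapse = ", "))
    if (check == "error") stopf("%s", msg) else warnf("%s", msg)
  }
  if ("iop_cluster" %in% names(tab) && !all(tab$iop_cluster %in% c(0L, 1L))) {
    stopf("iop_cluster must be binary 0/1 in '%s'", path)
  }
  tab
}

#' Packaged activity table (27 benzimidazole derivatives)
#'
#' The published hypotensive/IOP table for the 27-compound series: binary
#' IOP cluster, ED20 in mg/kg and umol/kg, ordinal index and level.
#'
#' @return data frame with 27 rows.
#' @export
iop_activity_fixture <- function() {
  load_activity_table(system.file("extdata", "activity_series27.csv",
                                  package = "iopqsar", mustWork = TRUE))
}

#' Packaged pharmacophore tables
#'
#' The published presence/absence pharmacophore tables (descriptor slots
#' kept verbatim as printed, ASCII-normalized; `pa`, `pi`, `pr` numeric).
#'
#' @param which `"presence"` or `"absence"`.
#' @return data frame with columns `sd1`, `ld`, `sd2`, `bd`, `pa`, `pi`, `pr`.
#' @export
pharmacophore_fixture <- function(which = c("presence", "absence")) {
  which <- match.arg(which)
  f <- sprintf("pharmacophores_%s.csv", which)
  utils::read.csv(system.file("extdata", f, package = "iopqsar", mustWork = TRUE),
                  stringsAsFactors = FALSE,
                  colClasses = c(sd1 = "character", ld = "character",
                                 sd2 = "character", bd = "character"))
}
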