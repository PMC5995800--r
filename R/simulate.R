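# Synthetic data with known structure.
#
# Three seeded generators emulate the statistical structure the pipeline
# assumes, so every stage can be exercised against planted ground truth:
#
#  * gen_library()     - benzimidazole-like compound libraries from a small
#                        scaffold/substituent grammar, with a marker
#                        fragment planted at class-specific rates;
#  * gen_iop_matrix()  - six IOP-lowering indicators with a class-shifted
#                        mean (the k-means input);
#  * gen_hypotensive() - ED20-based activity tables whose log-dose is
#                        monotonically linked to the IOP class (the ANN
#                        input), with the ordinal index derived from the
#                        dose so the table is internally consistent.
#
# Default class sizes (9 active / 18 inactive) mirror the 27-compound
# series the pipeline was built around.

# scaffold cores with one substitution site (ring labels 1-2 reserved;
# substituents use 3+): benzimidazole, N-methylbenzimidazole and a fused
# tricyclic (pyrimido-benzimidazole) core
.SCAFFOLDS <- c(
  "c1ccc2[nH]c(%s)nc2c1",
  "Cn1c(%s)nc2ccccc21",
  "c1cc(%s)c2c(c1)nc1n2cccn1"
)

.SUBSTITUENTS <- c("", "C", "CC", "CCC", "CC(C)C", "CCO", "OC",
                   "N(C)C", "CCN(C)C", "CCN(CC)CC", "c3ccccc3", "Cc3ccccc3")

#' Default planted fragment
#'
#' A thiomethyl fragment: sulfur occurs nowhere in the scaffold/substituent
#' grammar, so the `">S"` atom token marks the fragment's descriptors
#' unambiguously.
#'
#' @return list with `smiles`, `marker` token, `p_active`, `p_inactive`.
#' @export
default_fragment <- function() {
  list(smiles = "SC", marker = ">S", p_active = 0.8, p_inactive = 0.1)
}

.assemble_smiles <- function(template, substituent) {
  if (substituent == "") {
    sub("\\(%s\\)|%s", "", template)
  } else {
    sprintf(template, substituent)
  }
}

#' Generate a synthetic compound library with a planted fragment
#'
#' Scaffolds are drawn from a small benzimidazole-core grammar and
#' decorated with one substituent; the planted fragment is appended to the
#' substituent with probability `fragment$p_active` in the active class and
#' `fragment$p_inactive` in the inactive class. Chemically invalid
#' assemblies are resampled a bounded number of times (the grammar is
#' constructed so this should not trigger).
#'
#' @param n_active,n_inactive compounds per class.
#' @param fragment planted-fragment description, see [default_fragment()].
#' @param seed RNG seed (mandatory).
#' @param max_retries resampling bound per compound.
#' @return list with `molecules` (parsed `ql_molecule` list), `smiles`,
#'   `ids`, `labels` (1 active / 0 inactive), `planted` (logical),
#'   `marker` token.
#' @export
gen_library <- function(n_active, n_inactive, fragment = default_fragment(),
                        seed, max_retries = 5L) {
  if (missing(seed)) stopf("`seed` is required")
  stopifnot(n_active >= 1L, n_inactive >= 1L,
            fragment$p_active >= 0, fragment$p_active <= 1,
            fragment$p_inactive >= 0, fragment$p_inactive <= 1)
  n <- n_active + n_inactive
  labels <- c(rep(1L, n_active), rep(0L, n_inactive))
  ids <- sprintf("SIM%04d", seq_len(n))

  draws <- with_seed(seed, {
    list(template = sample(.SCAFFOLDS, n, replace = TRUE),
         substituent = sample(.SUBSTITUENTS, n, replace = TRUE),
         planted = stats::runif(n) < ifelse(labels == 1L, fragment$p_active,
                                            fragment$p_inactive),
         retry_seeds = sample.int(.Machine$integer.max - 1L, n))
  })

  smiles <- character(n)
  molecules <- vector("list", n)
  for (i in seq_len(n)) {
    template <- draws$template[i]
    substituent <- draws$substituent[i]
    for (attempt in seq_len(max_retries + 1L)) {
      sub_i <- if (draws$planted[i]) paste0(substituent, fragment$smiles) else substituent
      smi <- .assemble_smiles(template, sub_i)
      mol <- tryCatch(parse_smiles(smi, id = ids[i]), error = function(e) e)
      if (!inherits(mol, "error")) break
      if (attempt > max_retries) {
        stopf("could not assemble a valid structure for %s after %d retries (last: %s)",
              ids[i], max_retries, smi)
      }
      redraw <- with_seed(draws$retry_seeds[i] + attempt,
                          list(t = sample(.SCAFFOLDS, 1L), s = sample(.SUBSTITUENTS, 1L)))
      template <- redraw$t
      substituent <- redraw$s
    }
    smiles[i] <- smi
    molecules[[i]] <- mol
  }
  list(molecules = molecules, smiles = smiles, ids = ids,
       labels = labels, planted = draws$planted, marker = fragment$marker)
}

#' Generate a six-indicator IOP response matrix
#'
#' Each indicator is drawn from a normal distribution whose mean is shifted
#' upward by `effect_size * noise_sd` for active compounds (larger values =
#' stronger IOP lowering).
#'
#' @param labels binary class vector (1 active / 0 inactive).
#' @param effect_size standardized class difference per indicator.
#' @param noise_sd within-class standard deviation.
#' @param seed RNG seed (mandatory).
#' @param codes optional row codes; defaults to `SIM0001`, ...
#' @return numeric matrix, rows = compounds, 6 indicator columns.
#' @export
gen_iop_matrix <- function(labels, effect_size = 3, noise_sd = 1, seed, codes = NULL) {
  if (missing(seed)) stopf("`seed` is required")
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), noise_sd > 0)
  n <- length(labels)
  if (is.null(codes)) codes <- sprintf("SIM%04d", seq_len(n))
  x <- with_seed(seed, {
    matrix(stats::rnorm(n * 6L,
                        mean = rep(labels * effect_size * noise_sd, 6L),
                        sd = noise_sd),
           nrow = n, ncol = 6L)
  })
  dimnames(x) <- list(codes, paste0("iop", 1:6))
  x
}

#' Generate a hypotensive activity table linked to the IOP class
#'
#' log(ED20) is normal with the active-class mean shifted downward (more
#' potent) by `link_strength` within-class standard deviations; the ordinal
#' index is derived from the dose via [index_from_ed20()]; the umol/kg dose
#' comes from a drawn molecular weight in [200, 550] g/mol (drawn, not
#' computed from any structure, keeping this generator independent of the
#' chemistry module); the ordinal level is drawn with class weights that
#' coincide when `link_strength = 0`.
#'
#' @param labels binary class vector (1 active / 0 inactive).
#' @param link_strength monotone class-dose association in SD units of
#'   log(ED20); 0 = no association.
#' @param seed RNG seed (mandatory).
#' @param codes optional compound codes.
#' @param median_ed20 inactive-class median ED20 in mg/kg (default 15).
#' @param sd_log within-class SD of log(ED20) (default 0.6).
#' @return data frame with columns `code`, `iop_cluster`, `ed20_mg_kg`,
#'   `index`, `ed20_umol_kg`, `level`, `mw`.
#' @export
gen_hypotensive <- function(labels, link_strength = 2, seed, codes = NULL,
                            median_ed20 = 15, sd_log = 0.6) {
  if (missing(seed)) stopf("`seed` is required")
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), link_strength >= 0, median_ed20 > 0, sd_log > 0)
  n <- length(labels)
  if (is.null(codes)) codes <- sprintf("SIM%04d", seq_len(n))
  out <- with_seed(seed, {
    log_ed20 <- stats::rnorm(n, mean = log(median_ed20) - link_strength * sd_log * labels,
                             sd = sd_log)
    ed20 <- pmax(round(exp(log_ed20), 2L), 0.01)
    mw <- stats::runif(n, 200, 550)
    shift <- tanh(link_strength)
    lv <- vapply(labels, function(l) {
      w <- exp((if (l == 1L) shift else -shift) * (0:2))
      sample(0:2, 1L, prob = w / sum(w))
    }, integer(1))
    data.frame(code = codes, iop_cluster = labels,
               ed20_mg_kg = ed20,
               index = index_from_ed20(ed20),
               ed20_umol_kg = mgkg_to_umolkg(ed20, mw),
               level = lv, mw = mw,
               stringsAsFactors = FALSE)
  })
  out
}

#' Predictor matrix of an activity table
#'
#' The four hypotensive predictors in the order the network expects.
#'
#' @param activity data frame from [gen_hypotensive()],
#'   [load_activity_table()] or [iop_activity_fixture()].
#' @return numeric matrix with columns ed20_mg_kg, index, ed20_umol_kg,
#'   level.
#' @export
hypotensive_predictors <- function(activity) {
  cols <- c("ed20_mg_kg", "index", "ed20_umol_kg", "level")
  stopifnot(all(cols %in% names(activity)))
  as.matrix(activity[, cols])
}
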