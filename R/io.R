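# Readers, writers and pipeline configuration.
#
# All tabular artifacts are UTF-8 CSV with a header row and "." decimal
# separator; models serialize to JSON at full floating-point precision so
# a reloaded model reproduces its forward pass bit for bit.

#' Write descriptor profiles as long-format CSV
#'
#' Columns: `molecule_id`, `sd1`, `ld`, `sd2`, `bd`, `count`.
#'
#' @param profiles named list of `ql_profile` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(molecule_id = attr(p, "id"), sd1 = p$sd1, ld = p$ld,
               sd2 = p$sd2, bd = p$bd, count = p$count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read descriptor profiles from long-format CSV
#' @param path CSV written by [write_profiles_csv()].
#' @return named list of `ql_profile` objects.
#' @export
read_profiles_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = c(molecule_id = "character", sd1 = "character",
                                        sd2 = "character", bd = "character"))
  for (col in c("sd1", "sd2", "bd")) tab[[col]][is.na(tab[[col]])] <- ""
  ids <- unique(tab$molecule_id)
  out <- lapply(ids, function(id) {
    p <- tab[tab$molecule_id == id, c("sd1", "ld", "sd2", "bd", "count")]
    rownames(p) <- NULL
    attr(p, "id") <- id
    class(p) <- c("ql_profile", "data.frame")
    p
  })
  stats::setNames(out, ids)
}

#' Write an enrichment table as CSV
#'
#' Mirrors the published table layout (`sd1, ld, sd2, bd, pa, pi, pr`)
#' plus the label and the underlying counts; `pr` is written in
#' scientific notation at full precision.
#'
#' @param enr a `ql_enrichment` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment_csv <- function(enr, path) {
  out <- as.data.frame(enr)
  out$pr <- sprintf("%.10E", out$pr)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an enrichment table written by [write_enrichment_csv()]
#' @param path CSV path.
#' @return data frame with numeric `pa`, `pi`, `pr`.
#' @export
read_enrichment_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = c(sd1 = "character", sd2 = "character",
                                        bd = "character"))
  for (col in intersect(c("sd1", "sd2", "bd", "label"), names(tab))) {
    tab[[col]][is.na(tab[[col]])] <- ""
  }
  tab$pr <- as.numeric(tab$pr)
  tab
}

#' Serialize a perceptron model to JSON
#'
#' @param model an `iopqsar_mlp`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mlp_json <- function(model, path) {
  stopifnot(inherits(model, "iopqsar_mlp"))
  payload <- unclass(model)
  # 17 significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Load a perceptron model from JSON
#' @param path path written by [write_mlp_json()].
#' @return an `iopqsar_mlp`.
#' @export
read_mlp_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$par <- as.numeric(payload$par)
  payload$mu <- as.numeric(payload$mu)
  payload$sd <- as.numeric(payload$sd)
  structure(payload, class = "iopqsar_mlp")
}

#' Write an ensemble summary as CSV
#' @param ens an `iopqsar_ensemble`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ens, path) {
  stopifnot(inherits(ens, "iopqsar_ensemble"))
  s <- ens$summary[order(ens$summary$rank, na.last = TRUE), ]
  utils::write.csv(s, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run; all randomness flows from
#' the single `seed`. The object round-trips through JSON unchanged.
#'
#' @param smiles path to a SMILES file (one record per line).
#' @param activity path to a hypotensive activity CSV.
#' @param iop_matrix optional path to a code + 6-indicator CSV; when given,
#'   activity classes come from k-means on it, otherwise from the activity
#'   table's `iop_cluster` column.
#' @param out_dir output directory.
#' @param max_length,mode,alpha enrichment settings.
#' @param kmeans_restarts random restarts for the clustering.
#' @param n_networks,n_retain ensemble protocol sizes.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(smiles = NULL, activity = NULL, iop_matrix = NULL,
                            out_dir = ".", max_length = 5L,
                            mode = "occurrence", alpha = 0.05,
                            kmeans_restarts = 50L,
                            n_networks = 1000L, n_retain = 50L, seed = 1L) {
  structure(
    list(smiles = smiles, activity = activity, iop_matrix = iop_matrix,
         out_dir = out_dir, max_length = as.integer(max_length), mode = mode,
         alpha = alpha, kmeans_restarts = as.integer(kmeans_restarts),
         n_networks = as.integer(n_networks), n_retain = as.integer(n_retain),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path JSON path.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` (for writing).
#' @export
read_config_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, payload[!vapply(payload, is.null, logical(1))])
}

#' Run the pipeline end to end
#'
#' Reads molecules and activity data, derives the binary IOP class (k-means
#' over the indicator matrix when provided, otherwise the table's
#' `iop_cluster` column), screens the library for pharmacophores, runs the
#' ensemble protocol on the four hypotensive predictors, and validates the
#' best model. Writes `enrichment.csv`, `ensemble_summary.csv`,
#' `best_model.json`, `validation.json` and `config.json` to
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return list with `enrichment`, `labels`, `ensemble`, `validation`,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$activity)) stopf("config$activity is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  activity <- load_activity_table(config$activity)

  if (!is.null(config$iop_matrix)) {
    iop <- utils::read.csv(config$iop_matrix, stringsAsFactors = FALSE)
    rownames(iop) <- iop$code
    iop$code <- NULL
    cl <- cluster_activity(as.matrix(iop), seed = config$seed,
                           restarts = config$kmeans_restarts)
    labels <- cl$labels[match(activity$code, names(cl$labels))]
    if (any(is.na(labels))) stopf("IOP matrix and activity table codes disagree")
  } else {
    if (!"iop_cluster" %in% names(activity)) {
      stopf("no iop_matrix given and activity table has no iop_cluster column")
    }
    labels <- activity$iop_cluster
  }

  enrichment <- NULL
  if (!is.null(config$smiles)) {
    molecules <- read_smiles_file(config$smiles)
    if (length(molecules) != nrow(activity)) {
      stopf("SMILES file and activity table disagree on compound count")
    }
    enrichment <- screen_library(molecules, labels, max_length = config$max_length,
                                 mode = config$mode, alpha = config$alpha)
    write_enrichment_csv(enrichment, file.path(config$out_dir, "enrichment.csv"))
  }

  X <- hypotensive_predictors(activity)
  ens <- run_ensemble(X, labels, n_networks = config$n_networks,
                      n_retain = config$n_retain, master_seed = config$seed)
  write_ensemble_csv(ens, file.path(config$out_dir, "ensemble_summary.csv"))
  write_mlp_json(ens$best_model, file.path(config$out_dir, "best_model.json"))

  val <- validate_model(ens$best_model, X, labels)
  jsonlite::write_json(unclass(val), file.path(config$out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_config_json(config, file.path(config$out_dir, "config.json"))

  invisible(list(enrichment = enrichment, labels = labels,
                 ensemble = ens, validation = val))
}
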