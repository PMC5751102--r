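# End-to-end pipeline stages: featurize -> train/evaluate -> predict.
#
# Each stage takes a plain-list config (JSON-serializable), writes
# machine-readable outputs (TSV/JSON) when an output directory is given,
# and returns its results invisibly for programmatic use. The resolved
# config is written next to the outputs for provenance.

#' @keywords internal
merge_params <- function(params) {
  if (inherits(params, "ab_params")) return(params)
  if (is.null(params)) return(ab_params())
  do.call(ab_params, params)
}

#' @keywords internal
write_provenance <- function(config, out_dir, stage) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(out_dir, paste0(stage, "_config.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' Featurize one parsed structure
#'
#' Runs the full per-structure chain: ASA on the antibody alone, disulfide
#' anchors, epitope labeling (when an ADA chain is present), residue
#' classification and descriptor assembly for every surface and epitope
#' residue.
#'
#' @param model An `ab_structure`.
#' @param params An [ab_params()] object.
#' @param light_chain,heavy_chain Optional chain ids for benchmark-point
#'   selection (see [select_benchmark_points()]).
#' @param anchors_override Optional `list(p1 =, p2 =)` benchmark override.
#' @param n_points Shrake-Rupley sampling density.
#' @return List with `features` (data frame from [feature_table()]),
#'   `classmap`, `asa`, `anchors`, `epitope` and `regions`.
#' @export
featurize_structure <- function(model, params = ab_params(),
                                light_chain = NULL, heavy_chain = NULL,
                                anchors_override = NULL, n_points = 960L) {
  iab <- iab_model(model)
  asa <- compute_asa(iab, params, n_points = n_points)
  bonds <- detect_disulfides(iab, params)
  anchors <- select_benchmark_points(iab, bonds, light_chain, heavy_chain,
                                     override = anchors_override)
  epitope <- if (length(chains_with_role(model, "ADA"))) {
    label_epitope_residues(model, params)
  } else character()
  classmap <- classify_residues(model, asa$residue_rasa, epitope, params)
  feats <- feature_table(model, classmap, anchors, asa, params = params)
  list(features = feats, classmap = classmap, asa = asa, anchors = anchors,
       epitope = epitope,
       regions = group_epitope_regions(epitope, model))
}

#' Featurize a set of structures
#'
#' @param config List with `inputs`: a list of entries, each with `pdb`
#'   (path or text), `structure_id`, `roles` (named chain-role vector) and
#'   optional `light_chain`/`heavy_chain`; optional `params` (list of
#'   [ab_params()] overrides), `n_points`, and `out_dir` to write
#'   `features.tsv`, per-structure class maps, epitope regions JSON and
#'   the resolved config.
#' @return Invisibly, a list with the pooled `features` data frame and the
#'   per-structure results.
#' @export
run_featurize <- function(config) {
  params <- merge_params(config$params)
  n_points <- if (is.null(config$n_points)) 960L else as.integer(config$n_points)
  if (!length(config$inputs)) stop("config$inputs is empty")

  per <- lapply(config$inputs, function(inp) {
    model <- parse_structure(inp$pdb, roles = inp$roles,
                             structure_id = if (is.null(inp$structure_id))
                               "structure" else inp$structure_id)
    featurize_structure(model, params,
                        light_chain = inp$light_chain,
                        heavy_chain = inp$heavy_chain,
                        anchors_override = inp$anchors_override,
                        n_points = n_points)
  })
  features <- do.call(rbind, lapply(per, `[[`, "features"))

  if (!is.null(config$out_dir)) {
    write_provenance(config[setdiff(names(config), "inputs")],
                     config$out_dir, "featurize")
    utils::write.table(features, file.path(config$out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    regions <- lapply(per, `[[`, "regions")
    names(regions) <- vapply(per, function(p) p$features$structure_id[1L], "")
    jsonlite::write_json(regions, file.path(config$out_dir, "regions.json"),
                         auto_unbox = FALSE)
  }
  invisible(list(features = features, per_structure = per))
}

#' Train and cross-validate the epitope classifier
#'
#' Fits the pooled ridge-logistic model on a feature table and evaluates
#' it by seeded stratified ten-fold cross-validation, pooled and per
#' structure.
#'
#' @param config List with `features` (data frame or path to a
#'   features.tsv), optional `params`, `lambda` and `out_dir` (writes
#'   `model.json`, `report.tsv` and the resolved config).
#' @return Invisibly, list with `model`, `report_pooled` and
#'   `report_per_structure`.
#' @export
run_train_eval <- function(config) {
  params <- merge_params(config$params)
  feats <- config$features
  if (is.character(feats)) {
    feats <- utils::read.table(feats, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  if (length(unique(feats$class)) < 2L) {
    stop("feature table contains a single class; cannot train")
  }
  dataset <- as_labeled_dataset(feats)
  lambda <- if (is.null(config$lambda)) 1e-4 else config$lambda
  model <- fit_epitope_model(dataset, seed = params$rng_seed, lambda = lambda)
  pooled <- cross_validate(dataset, params, mode = "pooled", lambda = lambda)
  per_struct <- if (length(unique(dataset$structure_id)) > 1L) {
    tryCatch(cross_validate(dataset, params, mode = "per_structure",
                            lambda = lambda),
             error = function(e) NULL)
  } else NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_provenance(config[setdiff(names(config), "features")],
                     config$out_dir, "train")
    write_model_json(model, file.path(config$out_dir, "model.json"))
    rep_tab <- pooled$per_structure
    rep_tab <- rbind(rep_tab,
                     data.frame(structure_id = "POOLED",
                                n = nrow(dataset$x), n_pos = sum(dataset$y),
                                auc = pooled$pooled["auc"],
                                accuracy = pooled$pooled["accuracy"]))
    utils::write.table(rep_tab, file.path(config$out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(model = model, report_pooled = pooled,
                 report_per_structure = per_struct))
}

#' Predict epitope residues with a trained model
#'
#' Applies a serialized (or in-memory) model to a featurized antibody,
#' emitting per-residue probabilities and labels; predicted positives are
#' grouped into spatial regions when the structure is supplied.
#'
#' @param config List with `model` (an `epitope_model` or path to a
#'   model.json), `features` (data frame or path), optional `model_obj`
#'   structure (`ab_structure`) for region grouping, `threshold`
#'   (default 0.5), `link_distance` and `out_dir`.
#' @return Invisibly, list with `predictions` (data frame: structure_id,
#'   key, probability, predicted) and `regions`.
#' @export
run_predict <- function(config) {
  model <- config$model
  if (is.character(model)) model <- read_model_json(model)
  stopifnot(inherits(model, "epitope_model"))
  feats <- config$features
  if (is.character(feats)) {
    feats <- utils::read.table(feats, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  dataset <- as_labeled_dataset(feats)
  threshold <- if (is.null(config$threshold)) 0.5 else config$threshold
  prob <- predict(model, dataset$x)
  pred <- data.frame(structure_id = dataset$structure_id, key = dataset$key,
                     probability = prob, predicted = as.integer(prob >= threshold),
                     stringsAsFactors = FALSE)
  regions <- NULL
  if (!is.null(config$structure)) {
    link <- if (is.null(config$link_distance)) 10 else config$link_distance
    regions <- group_epitope_regions(pred$key[pred$predicted == 1L],
                                     config$structure, link)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(pred, file.path(config$out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(regions)) {
      jsonlite::write_json(regions, file.path(config$out_dir, "predicted_regions.json"))
    }
  }
  invisible(list(predictions = pred, regions = regions))
}
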