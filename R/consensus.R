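# Feature assembly and the Random-Forest consensus ddG regressor.

#' Featurization configuration
#'
#' @param alpha Calibration between -T*ddS_vib and its ddG contribution.
#' @param anm_cutoff,anm_gamma ANM parameters (supplies the fluctuation
#'   ratio).
#' @param encom_parameters Sequence-dependent field parameters (supplies
#'   ddS_vib and the elastic ddG term).
#' @param signature_radius,signature_bins Cutoff-scan signature geometry.
#' @param sasa_points Sphere sample points for accessibility/depth.
#' @return A config list for [featurize_mutation()].
#' @export
featurize_config <- function(alpha = 1, anm_cutoff = 15, anm_gamma = 1,
                             encom_parameters = encom_params(),
                             signature_radius = 10,
                             signature_bins = c(2, 4, 6, 8, 10),
                             sasa_points = 240) {
  list(alpha = alpha, anm_cutoff = anm_cutoff, anm_gamma = anm_gamma,
       encom_parameters = encom_parameters,
       signature_radius = signature_radius,
       signature_bins = signature_bins, sasa_points = sasa_points)
}

#' Assemble the feature vector for one mutation
#'
#' Runs the full evidence pipeline on one (structure, mutation) pair:
#' mutant modelling, sequence-dependent normal-mode entropy change
#' (`dds_vib`, `enm_ddg`), ANM fluctuation ratio at the mutated site,
#' cutoff-scan signature of the wild-type residue environment,
#' pharmacophore count deltas, relative solvent accessibility, residue
#' depth, secondary-structure one-hot and the direction flag.
#'
#' @param wt Wild-type `protein_structure` (for reverse records, the
#'   modelled mutant structure plays the wild-type role).
#' @param mutation A `mutation_spec` (identity mutations permitted for
#'   self-checks).
#' @param config List from [featurize_config()].
#' @param direction `"forward"` or `"reverse"` flag copied into the vector.
#' @param mut Optional pre-built mutant structure.
#' @return One-row tibble with a stable, schema-versioned column order.
#' @export
featurize_mutation <- function(wt, mutation, config = featurize_config(),
                               direction = "forward", mut = NULL) {
  stage <- "mutant modelling"
  out <- tryCatch({
    if (is.null(mut)) mut <- build_mutant(wt, mutation)
    stage <- "normal-mode dynamics (encom)"
    dyn_encom <- mutation_dynamics(wt, mutation, forcefield = "encom",
                                   mut = mut, alpha = config$alpha,
                                   encom_parameters = config$encom_parameters)
    stage <- "normal-mode dynamics (anm)"
    dyn_anm <- mutation_dynamics(wt, mutation, forcefield = "anm", mut = mut,
                                 anm_cutoff = config$anm_cutoff,
                                 anm_gamma = config$anm_gamma)
    stage <- "graph-based signature"
    sig <- cutoff_scan_signature(wt, mutation$chain, mutation$resno,
                                 mutation$icode,
                                 radius = config$signature_radius,
                                 bin_edges = config$signature_bins)
    names(sig) <- paste0("sig_", gsub("[:@]", "_", names(sig)))
    stage <- "pharmacophore delta"
    delta <- mutation_pharmacophore_delta(mutation$wild_aa, mutation$mutant_aa)
    names(delta) <- paste0("dpharm_", names(delta))
    stage <- "environment features"
    rsa <- relative_solvent_accessibility(wt, mutation$chain, mutation$resno,
                                          mutation$icode,
                                          n_points = config$sasa_points)
    depth <- residue_depth(wt, mutation$chain, mutation$resno, mutation$icode,
                           n_points = config$sasa_points)
    ss <- secondary_structure(wt, mutation$chain, mutation$resno,
                              mutation$icode)
    dplyr::bind_cols(
      tibble::tibble(dds_vib = dyn_encom$dds_vib,
                     enm_ddg = dyn_encom$enm_ddg,
                     msf_ratio_site = dyn_anm$msf_ratio_site),
      tibble::as_tibble_row(as.list(sig)),
      tibble::as_tibble_row(as.list(delta)),
      tibble::tibble(rsa = rsa, depth = depth,
                     ss_helix = as.integer(ss == "helix"),
                     ss_strand = as.integer(ss == "strand"),
                     ss_coil = as.integer(ss == "coil"),
                     direction_reverse = as.integer(direction == "reverse")))
  }, error = function(e) {
    stop(sprintf("featurization failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  out
}

#' Random-Forest hyperparameters
#'
#' @param n_trees Number of trees, default 500.
#' @param mtry Features per split; default `sqrt(p)` chosen at fit time.
#' @param nodesize Minimum terminal node size (depth is otherwise
#'   unlimited), default 5.
#' @return Hyperparameter list.
#' @export
consensus_hyperparams <- function(n_trees = 500, mtry = NULL, nodesize = 5) {
  list(n_trees = n_trees, mtry = mtry, nodesize = nodesize)
}

MODEL_FORMAT_VERSION <- 1L

non_feature_cols <- c("ddg_exp", "direction", "group_key", "pdb_id", "chain",
                      "mutation", "wild_aa", "mutant_aa", "resno", "icode")

feature_columns <- function(data) setdiff(names(data), non_feature_cols)

fit_forest <- function(x, y, hp, seed) {
  mtry <- if (is.null(hp$mtry)) max(1, floor(sqrt(ncol(x)))) else hp$mtry
  set.seed(seed)
  randomForest::randomForest(x = as.data.frame(x), y = y,
                             ntree = hp$n_trees, mtry = mtry,
                             nodesize = hp$nodesize, importance = TRUE)
}

#' Train the consensus ddG regressor
#'
#' Fits a Random Forest to the feature columns of `data` (every column not
#' in the bookkeeping set `ddg_exp`/`direction`/`group_key`/identifier
#' columns is a feature), reporting grouped 10-fold cross-validation metrics
#' computed with [make_splits()] and [evaluate_predictions()], then refits
#' on the full table.
#'
#' @param data Tibble with feature columns plus `ddg_exp` (kcal/mol,
#'   stabilizing positive) and optionally `group_key`/`direction`.
#' @param hyperparams From [consensus_hyperparams()].
#' @param k Cross-validation folds, default 10.
#' @param seed Integer seed controlling fold assignment and forest fits.
#' @return A `consensus_model`: fitted forest, feature schema and hash,
#'   hyperparameters, seed, CV `metrics_report` and out-of-fold predictions.
#' @export
train_consensus <- function(data, hyperparams = consensus_hyperparams(),
                            k = 10, seed = 1L) {
  if (!"ddg_exp" %in% names(data)) stop("data must contain ddg_exp")
  if (nrow(data) < 50) stop("need >= 50 rows to train")
  y <- data$ddg_exp
  if (any(!is.finite(y))) stop("NaN/Inf targets")
  feats <- feature_columns(data)
  x <- data[, feats]
  if (!all(vapply(x, is.numeric, TRUE))) stop("non-numeric feature column")
  const <- vapply(x, function(col) stats::sd(col) == 0, TRUE)
  if (any(const)) {
    warning("all-constant feature(s): ", paste(feats[const], collapse = ", "))
  }
  if (!"group_key" %in% names(data)) {
    data$group_key <- sprintf("row%08d", seq_len(nrow(data)))
  }
  folds <- make_splits(data, mode = "kfold", k = k, seed = seed)
  cv_pred <- numeric(nrow(data))
  for (f in sort(unique(folds))) {
    test <- folds == f
    fit <- fit_forest(x[!test, ], y[!test], hyperparams, seed + f)
    cv_pred[test] <- stats::predict(fit, newdata = as.data.frame(x[test, ]))
  }
  cv_metrics <- evaluate_predictions(cv_pred, data)
  forest <- fit_forest(x, y, hyperparams, seed)
  structure(list(forest = forest, schema = feats,
                 schema_hash = rlang::hash(feats),
                 hyperparams = hyperparams, seed = seed, n_train = nrow(data),
                 cv_metrics = cv_metrics, cv_predictions = cv_pred,
                 format_version = MODEL_FORMAT_VERSION),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("<consensus_model> %d features, %d trees, trained on %d rows\n",
              length(x$schema), x$hyperparams$n_trees, x$n_train))
  cat(sprintf("  10-fold CV: r = %.3f, RMSE = %.3f kcal/mol\n",
              x$cv_metrics$pearson_r, x$cv_metrics$rmse))
  invisible(x)
}

#' Predict ddG for feature rows
#'
#' @param model A `consensus_model`.
#' @param features Tibble containing (at least) the model's feature columns.
#' @return Tibble: `ddg_pred` (kcal/mol) and `stability_class`.
#' @export
predict_ddg <- function(model, features) {
  missing_cols <- setdiff(model$schema, names(features))
  if (length(missing_cols) > 0 ||
      rlang::hash(model$schema) != model$schema_hash) {
    stop(sprintf("feature schema mismatch (model hash %s vs data hash %s); missing: %s",
                 model$schema_hash,
                 rlang::hash(intersect(names(features), model$schema)),
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as.data.frame(features[, model$schema])
  pred <- unname(stats::predict(model$forest, newdata = x))
  tibble::tibble(ddg_pred = pred, stability_class = classify_stability(pred))
}

#' Serialize a consensus model
#' @param model A `consensus_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format_version = model$format_version, model = model), path)
  invisible(path)
}

#' Load a serialized consensus model
#' @param path File written by [save_model()].
#' @return A `consensus_model` with bit-identical predictions.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || is.null(obj$format_version)) {
    stop("not a consensus model archive")
  }
  if (obj$format_version != MODEL_FORMAT_VERSION) {
    stop(sprintf("model format version %s not supported (expected %d)",
                 obj$format_version, MODEL_FORMAT_VERSION))
  }
  obj$model
}

#' Tidy a consensus model: per-feature importance
#'
#' @param x A `consensus_model`.
#' @param ... Unused.
#' @return Tibble `feature`, `importance` (increase in node purity),
#'   descending.
#' @method tidy consensus_model
#' @export
tidy.consensus_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(feature = rownames(imp),
                 importance = imp[, "IncNodePurity"]) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-row model summary
#'
#' @param x A `consensus_model`.
#' @param ... Unused.
#' @return Tibble: `n_train`, `n_features`, `n_trees`, `cv_pearson_r`,
#'   `cv_rmse`, `cv_pearson_r_trimmed`, `cv_rmse_trimmed`.
#' @method glance consensus_model
#' @export
glance.consensus_model <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, n_features = length(x$schema),
                 n_trees = x$hyperparams$n_trees,
                 cv_pearson_r = x$cv_metrics$pearson_r,
                 cv_rmse = x$cv_metrics$rmse,
                 cv_pearson_r_trimmed = x$cv_metrics$pearson_r_trimmed,
                 cv_rmse_trimmed = x$cv_metrics$rmse_trimmed)
}
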