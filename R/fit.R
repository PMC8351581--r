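#' Train a moonlighting-protein prediction pipeline
#'
#' The central fitting function. Computes the chosen descriptor class
#' for every training sequence, selects hyperparameters by grid-searched
#' stratified k-fold cross-validation (mean AUPRC as the selection
#' metric, preprocessing refitted within every fold), then refits the
#' complete chain — information-gain selection, min-max normalization,
#' PCA to `n_components`, classifier — on the full training set.
#'
#' @param records a [protein_records()] data frame of training
#'   sequences, or a [labeled_set()] (in which case `labels` is taken
#'   from it).
#' @param labels binary 0/1 labels (1 = moonlighting).
#' @param descriptor a [descriptor_spec()]; default TPC, the class that
#'   dominates the feature-class ranking.
#' @param algorithm one of `"XGBoost"` (default), `"SVM"`, `"RF"`,
#'   `"DT"`, `"KNN"`.
#' @param grid hyperparameter grid (`NULL` = [default_grid()]).
#' @param k CV folds (default 5).
#' @param seed integer seed for folds and classifier randomness.
#' @param threshold decision threshold (default 0.5; a sequence is
#'   called moonlighting when its score is >= the threshold).
#' @param ig_threshold,fallback_fraction,n_components preprocessing
#'   parameters.
#' @return object of class `pmp_model` with the fitted states, the
#'   cross-validation report of the winning grid point (`$cv`), and the
#'   selected hyperparameters.
#' @seealso [predict.pmp_model()], [save_model()], [rank_feature_classes()]
#' @examples
#' \donttest{
#' set.seed(1)
#' dat <- generate_proteins(synthetic_config(n_pos = 20, n_neg = 20,
#'   length_range = c(35, 80), effect = 8, mode = "motif-spike", seed = 7))
#' fit <- pmp_train(dat, descriptor = descriptor_spec("GTPC"),
#'                  algorithm = "DT", grid = list(list(max_depth = 5)),
#'                  seed = 1)
#' predict(fit, dat$records[1:3, ])
#' }
#' @export
pmp_train <- function(records, labels = NULL,
                      descriptor = descriptor_spec("TPC"),
                      algorithm = "XGBoost", grid = NULL, k = 5L,
                      seed = 1L, threshold = 0.5, ig_threshold = 0.05,
                      fallback_fraction = 0.80, n_components = 10L) {
  if (inherits(records, "labeled_set")) {
    labels <- records$labels
    records <- records$records
  }
  stopifnot(inherits(records, "protein_records"), !is.null(labels))
  labels <- as.integer(labels)
  algorithm <- match_algorithm(algorithm)
  x <- build_feature_matrix(records, descriptor)
  gs <- grid_search_cv(x, labels, algorithm = algorithm, grid = grid,
                       k = k, seed = seed, threshold = threshold,
                       ig_threshold = ig_threshold,
                       fallback_fraction = fallback_fraction,
                       n_components = n_components)
  states <- fit_preprocess(x, labels, ig_threshold = ig_threshold,
                           fallback_fraction = fallback_fraction,
                           n_components = n_components)
  clf <- fit_classifier(algorithm, states$transformed, labels,
                        gs$best_params, seed = sub_seed(seed, 0L))
  structure(list(descriptor = descriptor,
                 selector = states$selector,
                 scaler = states$scaler,
                 projection = states$projection,
                 classifier = clf,
                 algorithm = algorithm,
                 best_params = gs$best_params,
                 threshold = threshold,
                 seed = seed,
                 cv = gs$report,
                 grid_metrics = gs$grid_metrics,
                 n_train = length(labels),
                 version = 1L),
            class = "pmp_model")
}

#' @export
print.pmp_model <- function(x, ...) {
  cat("Moonlighting-protein prediction model\n",
      "  descriptor:  ", x$descriptor$class_name, " (",
      descriptor_length(x$descriptor), " features, ",
      length(x$selector$retained), " retained, ",
      ncol(x$projection$rotation), " components)\n",
      "  classifier:  ", x$algorithm, " [", params_string(x$best_params),
      "]\n  threshold:   ", x$threshold,
      "\n  trained on:  ", x$n_train, " sequences (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' @export
summary.pmp_model <- function(object, ...) {
  print(object)
  cat("\nCross-validation of the selected grid point:\n")
  print(object$cv)
  invisible(object)
}

# Descriptor -> select -> scale -> project for new records; returns the
# projected matrix for records long enough, NA rows flagged otherwise.
#' @noRd
model_scores <- function(object, records) {
  need <- descriptor_min_length(object$descriptor)
  ok <- nchar(records$sequence) >= need
  scores <- rep(NA_real_, nrow(records))
  note <- rep("", nrow(records))
  note[!ok] <- paste0("sequence shorter than ", need, " residues required by ",
                      object$descriptor$class_name)
  if (any(ok)) {
    x <- build_feature_matrix(records[ok, , drop = FALSE], object$descriptor)
    z <- apply_projection(object$projection,
                          apply_scaler(object$scaler,
                                       apply_selector(object$selector, x)))
    scores[ok] <- predict_classifier(object$classifier, z)
  }
  list(scores = scores, note = note)
}

#' Score new sequences with a fitted model
#'
#' Applies the fitted chain descriptor -> selection -> normalization ->
#' projection -> classifier to each record and thresholds the resulting
#' probability: `score >= threshold` is called `"moonlighting"`. Records
#' shorter than the descriptor minimum are reported individually (NA
#' score, diagnostic note) without aborting the batch. Scores do not
#' depend on batch composition.
#'
#' @param object a fitted `pmp_model`.
#' @param records a [protein_records()] data frame (or a `labeled_set`).
#' @param threshold overrides the model's decision threshold.
#' @param ... unused.
#' @return data frame with columns `id`, `score`, `label`, `note`.
#' @export
predict.pmp_model <- function(object, records, threshold = NULL, ...) {
  if (inherits(records, "labeled_set")) records <- records$records
  stopifnot(inherits(records, "protein_records"))
  threshold <- threshold %||% object$threshold
  if (!nrow(records)) {
    return(data.frame(id = character(0), score = numeric(0),
                      label = character(0), note = character(0),
                      stringsAsFactors = FALSE))
  }
  sc <- model_scores(object, records)
  label <- ifelse(is.na(sc$scores), NA_character_,
                  ifelse(sc$scores >= threshold, "moonlighting",
                         "non-moonlighting"))
  data.frame(id = records$id, score = sc$scores, label = label,
             note = sc$note, stringsAsFactors = FALSE)
}

#' Save / load a fitted model archive
#'
#' Serializes the complete pipeline (descriptor spec, fitted selector,
#' scaler, projection, classifier, hyperparameters, threshold, seed) to
#' a single versioned file. XGBoost boosters are stored in their
#' portable raw form so a reloaded model scores identically.
#'
#' @param model a `pmp_model`.
#' @param path file path for the archive.
#' @return `path` (save) or the restored `pmp_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pmp_model"))
  if (model$algorithm == "XGBoost") {
    model$classifier$fit <- xgboost::xgb.save.raw(model$classifier$fit)
    model$classifier$serialized <- TRUE
  }
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "pmp_model")) stop("not a model archive: ", path)
  if (isTRUE(model$classifier$serialized)) {
    model$classifier$fit <- xgboost::xgb.load.raw(model$classifier$fit)
    model$classifier$serialized <- NULL
  }
  model
}
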