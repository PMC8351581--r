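#' @noRd
params_string <- function(params) {
  paste(names(params), vapply(params, function(v) paste(v, collapse = "/"),
                              character(1)),
        sep = "=", collapse = ", ")
}

# Assemble an EvaluationReport from pooled out-of-fold predictions.
#' @noRd
cv_report <- function(scores, labels, fold, threshold = 0.5) {
  overall <- compute_metrics(scores, labels, threshold = threshold)
  per_fold <- do.call(rbind, lapply(sort(unique(fold)), function(f) {
    cbind(fold = f, metrics_row(compute_metrics(scores[fold == f],
                                                labels[fold == f],
                                                threshold = threshold)))
  }))
  structure(list(overall = overall, per_fold = per_fold,
                 fold_means = colMeans(per_fold[, -1, drop = FALSE]),
                 folds = fold, scores = scores, labels = labels,
                 threshold = threshold),
            class = "pmp_cv_report")
}

#' @export
print.pmp_cv_report <- function(x, digits = 4, ...) {
  cat("Cross-validated evaluation (", length(unique(x$folds)),
      " folds, pooled):\n", sep = "")
  print(x$overall, digits = digits)
  cat("Fold means: ",
      paste(names(x$fold_means),
            format(round(x$fold_means, digits)), collapse = "  "), "\n")
  invisible(x)
}

#' Grid search with stratified k-fold cross-validation
#'
#' Evaluates every hyperparameter combination by k-fold CV. Within each
#' fold the full preprocessing chain (information-gain selection,
#' min-max normalization, PCA) is refitted on the training portion only,
#' so no fold leaks into its own evaluation. The best grid point
#' maximizes mean per-fold AUPRC (the primary metric), with ties broken
#' by mean AUC and then grid order. The returned report pools the
#' out-of-fold predictions of the winning point.
#'
#' @param matrix numeric feature matrix (samples x features) from
#'   [build_feature_matrix()].
#' @param labels binary 0/1 labels aligned with rows.
#' @param algorithm one of `"XGBoost"`, `"SVM"`, `"RF"`, `"DT"`, `"KNN"`.
#' @param grid list of named parameter lists; `NULL` uses
#'   [default_grid()].
#' @param k number of folds (default 5).
#' @param seed integer seed controlling folds and classifier randomness.
#' @param threshold decision threshold for the threshold metrics.
#' @param ig_threshold,fallback_fraction,n_components preprocessing
#'   parameters (see [fit_selector()], [fit_projection()]).
#' @return object of class `pmp_grid_search`: list with `best_params`,
#'   `report` (a `pmp_cv_report`), `grid_metrics` (mean AUPRC/AUC per
#'   grid point), `algorithm`, `folds`.
#' @export
grid_search_cv <- function(matrix, labels, algorithm, grid = NULL,
                           k = 5L, seed = 1L, threshold = 0.5,
                           ig_threshold = 0.05, fallback_fraction = 0.80,
                           n_components = 10L) {
  algorithm <- match_algorithm(algorithm)
  labels <- as.integer(labels)
  stopifnot(nrow(matrix) == length(labels))
  grid <- grid %||% default_grid(algorithm)
  if (!length(grid)) stop("grid must be non-empty")
  fold <- make_folds(labels, k = k, seed = seed)
  n <- length(labels)
  scores <- matrix(NA_real_, nrow = n, ncol = length(grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    states <- fit_preprocess(matrix[tr, , drop = FALSE], labels[tr],
                             ig_threshold = ig_threshold,
                             fallback_fraction = fallback_fraction,
                             n_components = n_components)
    xtr <- states$transformed
    xte <- apply_preprocess(states, matrix[!tr, , drop = FALSE])
    for (g in seq_along(grid)) {
      clf <- fit_classifier(algorithm, xtr, labels[tr], grid[[g]],
                            seed = sub_seed(seed, f * 1000L + g))
      scores[!tr, g] <- predict_classifier(clf, xte)
    }
  }
  per_point <- t(vapply(seq_along(grid), function(g) {
    au <- vapply(seq_len(k), function(f) {
      m <- compute_metrics(scores[fold == f, g], labels[fold == f],
                           threshold = threshold)
      c(m$auprc, m$auc)
    }, numeric(2))
    rowMeans(au)
  }, numeric(2)))
  colnames(per_point) <- c("mean_auprc", "mean_auc")
  best <- order(-per_point[, "mean_auprc"], -per_point[, "mean_auc"],
                seq_along(grid))[1L]
  structure(list(best_params = grid[[best]],
                 best_index = best,
                 report = cv_report(scores[, best], labels, fold,
                                    threshold = threshold),
                 grid_metrics = data.frame(
                   point = vapply(grid, params_string, character(1)),
                   per_point),
                 algorithm = algorithm, folds = fold, seed = seed),
            class = "pmp_grid_search")
}

#' @export
print.pmp_grid_search <- function(x, ...) {
  cat("Grid search (", x$algorithm, ", ", nrow(x$grid_metrics),
      " points):\n  best: ", params_string(x$best_params), "\n", sep = "")
  print(x$report)
  invisible(x)
}

# Compact SVM grid used when scoring each feature class separately.
#' @noRd
ranking_grid <- function() {
  lapply(c(0.1, 1, 10, 100),
         function(C) list(kernel = "radial", cost = C, gamma = "scale"))
}

#' Rank the 16 descriptor classes by cross-validated SVM performance
#'
#' Builds one classifier per feature class: each class's feature matrix
#' is pushed through the full preprocessing chain and evaluated with a
#' grid-searched SVM under stratified k-fold CV. Classes are ranked by
#' AUPRC (mean over folds), descending.
#'
#' @param records a [protein_records()] data frame.
#' @param labels binary 0/1 labels.
#' @param specs list of [descriptor_spec()]s (default: all 16 classes at
#'   their default parameters).
#' @param seed integer seed.
#' @param grid SVM grid; `NULL` uses a compact radial grid over cost.
#' @param k folds (default 5).
#' @return object of class `pmp_ranking`: a data frame with one row per
#'   feature class (class, mean AUPRC/AUC over folds, pooled threshold
#'   metrics, best SVM parameters), sorted by AUPRC.
#' @export
rank_feature_classes <- function(records, labels, specs = NULL,
                                 seed = 1L, grid = NULL, k = 5L) {
  specs <- specs %||% lapply(descriptor_classes(), descriptor_spec)
  grid <- grid %||% ranking_grid()
  rows <- lapply(specs, function(spec) {
    x <- build_feature_matrix(records, spec)
    gs <- grid_search_cv(x, labels, algorithm = "SVM", grid = grid,
                         k = k, seed = seed)
    fm <- gs$report$fold_means
    ov <- gs$report$overall
    data.frame(class = spec$class_name,
               n_features = descriptor_length(spec),
               auprc = unname(fm["auprc"]), auc = unname(fm["auc"]),
               sensitivity = ov$sensitivity, specificity = ov$specificity,
               mcc = ov$mcc, f1 = ov$f1,
               best_params = params_string(gs$best_params),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$auprc, -tab$auc), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("pmp_ranking", "data.frame")
  tab
}

#' @export
print.pmp_ranking <- function(x, digits = 4, ...) {
  cat("Feature-class ranking (", nrow(x),
      " classes, by cross-validated AUPRC):\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = TRUE)
  invisible(x)
}
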