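PMP_ALGORITHMS <- c("XGBoost", "SVM", "RF", "DT", "KNN")

#' Default hyperparameter grids for the five algorithms
#'
#' Small, standard grids: SVM (rbf/linear kernels, cost, gamma), XGBoost
#' (rounds, depth, learning rate), random forest (trees, mtry rule),
#' decision tree (depth), k-nearest neighbours (k). Every grid point is
#' a named list of parameters.
#'
#' @param algorithm one of `"XGBoost"`, `"SVM"`, `"RF"`, `"DT"`, `"KNN"`.
#' @return list of named parameter lists.
#' @export
default_grid <- function(algorithm) {
  algorithm <- match_algorithm(algorithm)
  switch(algorithm,
    SVM = {
      g <- list()
      for (C in c(0.1, 1, 10, 100)) {
        for (gamma in list(1e-3, 1e-2, 1e-1, "scale")) {
          g[[length(g) + 1L]] <- list(kernel = "radial", cost = C,
                                      gamma = gamma)
        }
      }
      for (C in c(0.1, 1, 10, 100)) {
        g[[length(g) + 1L]] <- list(kernel = "linear", cost = C)
      }
      g
    },
    XGBoost = {
      g <- list()
      for (nrounds in c(100, 300)) {
        for (depth in c(3, 5, 7)) {
          for (eta in c(0.05, 0.1, 0.3)) {
            g[[length(g) + 1L]] <- list(nrounds = nrounds,
                                        max_depth = depth, eta = eta)
          }
        }
      }
      g
    },
    RF = {
      g <- list()
      for (ntree in c(100, 500)) {
        for (mf in c("sqrt", "log2")) {
          g[[length(g) + 1L]] <- list(ntree = ntree, max_features = mf)
        }
      }
      g
    },
    DT = lapply(list(3, 5, 10, "none"), function(d) list(max_depth = d)),
    KNN = lapply(c(3, 5, 7, 9), function(k) list(k = k)))
}

#' @noRd
match_algorithm <- function(algorithm) {
  hit <- PMP_ALGORITHMS[tolower(PMP_ALGORITHMS) == tolower(algorithm)]
  if (!length(hit)) {
    stop("unknown algorithm '", algorithm, "'; valid: ",
         paste(PMP_ALGORITHMS, collapse = ", "))
  }
  hit
}

#' @noRd
resolve_gamma <- function(gamma, x) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(x))
    if (!is.finite(v) || v == 0) v <- 1
    1 / (ncol(x) * v)
  } else as.numeric(gamma)
}

# Train one classifier; returns a self-contained object for
# predict_classifier(). SVM probabilities use e1071's built-in Platt
# calibration (fitted by internal CV on the training fold).
#' @noRd
fit_classifier <- function(algorithm, x, y, params, seed = 1L) {
  algorithm <- match_algorithm(algorithm)
  y <- factor(as.integer(y), levels = c(0L, 1L))
  fit <- switch(algorithm,
    SVM = with_seed(seed, {
      args <- list(x = x, y = y, kernel = params$kernel,
                   cost = params$cost, probability = TRUE, scale = FALSE)
      if (!is.null(params$gamma)) {
        args$gamma <- resolve_gamma(params$gamma, x)
      }
      do.call(e1071::svm, args)
    }),
    XGBoost = {
      dtrain <- xgboost::xgb.DMatrix(data = x,
                                     label = as.integer(as.character(y)))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = params$max_depth,
                      eta = params$eta, nthread = 1L, seed = seed,
                      eval_metric = "logloss"),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    },
    RF = with_seed(seed, {
      mtry <- switch(params$max_features,
                     sqrt = max(1L, floor(sqrt(ncol(x)))),
                     log2 = max(1L, floor(log2(ncol(x)))))
      randomForest::randomForest(x = x, y = y, ntree = params$ntree,
                                 mtry = min(mtry, ncol(x)))
    }),
    DT = {
      depth <- if (identical(params$max_depth, "none")) 30L else
        as.integer(params$max_depth)
      df <- data.frame(.y = y, x, check.names = TRUE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = depth))
    },
    KNN = list(train = x, cl = y, k = as.integer(params$k)))
  structure(list(algorithm = algorithm, params = params, fit = fit,
                 seed = seed, n_features = ncol(x)),
            class = "pmp_classifier")
}

# Positive-class probability for new rows.
#' @noRd
predict_classifier <- function(object, x) {
  stopifnot(inherits(object, "pmp_classifier"))
  switch(object$algorithm,
    SVM = {
      p <- attr(stats::predict(object$fit, x, probability = TRUE),
                "probabilities")
      unname(p[, "1"])
    },
    XGBoost = {
      as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(data = x)))
    },
    RF = unname(stats::predict(object$fit, x, type = "prob")[, "1"]),
    DT = {
      df <- data.frame(x, check.names = TRUE)
      unname(stats::predict(object$fit, df, type = "prob")[, "1"])
    },
    KNN = with_seed(object$seed, {
      pred <- class::knn(train = object$fit$train, test = x,
                         cl = object$fit$cl, k = object$fit$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    }))
}
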