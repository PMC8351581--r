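# Equal-frequency discretization used by the information-gain filter.
# Bin edges are type-1 (order-statistic) quantiles, so bin membership
# depends only on ranks: IG is invariant under strictly monotone
# transformations of the feature. Duplicate edges (heavy ties) merge.
#' @noRd
discretize_eqfreq <- function(x, bins) {
  b <- min(bins, length(unique(x)))
  if (b <= 1L) return(rep(1L, length(x)))
  edges <- unique(stats::quantile(x, probs = seq_len(b - 1L) / b,
                                  type = 1, names = FALSE))
  findInterval(x, edges, left.open = TRUE) + 1L
}

#' @noRd
entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information gain of a feature with respect to binary labels
#'
#' Measures, in bits, the reduction in label entropy obtained by
#' conditioning on the feature after equal-frequency discretization:
#' `IG = H(Y) - H(Y | bin(X))`. Always in `[0, H(Y)]`.
#'
#' @param values numeric feature values, one per sample.
#' @param labels binary 0/1 labels.
#' @param bins maximum number of bins (default 10; the effective count is
#'   `min(bins, distinct values)`, and empty bins merge).
#' @return information gain in bits.
#' @examples
#' information_gain(c(1, 2, 3, 4), c(0, 0, 1, 1), bins = 2)  # 1 bit
#' @export
information_gain <- function(values, labels, bins = 10L) {
  labels <- as.integer(labels)
  if (length(values) != length(labels) || length(values) < 2L) {
    stop("need >= 2 aligned values and labels")
  }
  if (length(unique(labels)) < 2L) {
    stop("information gain requires both classes present")
  }
  if (bins < 2L) stop("bins must be >= 2")
  bin <- discretize_eqfreq(values, bins)
  hy <- entropy_bits(table(labels))
  tab <- table(bin, labels)
  nb <- rowSums(tab)
  hy_given <- sum(nb / sum(nb) * apply(tab, 1, entropy_bits))
  max(0, hy - hy_given)
}

#' Fit the information-gain feature selector
#'
#' Scores every feature by [information_gain()] and retains those with
#' IG strictly above `threshold`. If no feature clears the threshold the
#' selector falls back to the top `fallback_fraction` of features ranked
#' by IG (`ceiling(fraction * p)` of them; ties broken by canonical
#' column order). Fit on training data only and replayed on new data
#' with [apply_selector()].
#'
#' @param matrix numeric feature matrix (samples x features).
#' @param labels binary 0/1 labels aligned with rows.
#' @param threshold IG cut-off in bits (default 0.05).
#' @param fallback_fraction fraction retained when nothing clears the
#'   threshold (default 0.80).
#' @param bins discretization bins passed to [information_gain()].
#' @return object of class `pmp_selector` with elements `scores`,
#'   `retained`, `threshold`, `fallback_fraction`, `fallback_used`.
#' @export
fit_selector <- function(matrix, labels, threshold = 0.05,
                         fallback_fraction = 0.80, bins = 10L) {
  if (!is.matrix(matrix) || !nrow(matrix) || !ncol(matrix)) {
    stop("matrix must be a non-empty numeric matrix")
  }
  if (is.null(colnames(matrix))) stop("matrix must have feature names")
  scores <- apply(matrix, 2, information_gain, labels = labels, bins = bins)
  keep <- scores > threshold
  fallback_used <- !any(keep)
  if (fallback_used) {
    k <- ceiling(fallback_fraction * ncol(matrix))
    # stable: order by descending score, ties by canonical column order
    ord <- order(-scores, seq_along(scores))
    keep <- seq_along(scores) %in% ord[seq_len(k)]
  }
  structure(list(scores = scores,
                 retained = colnames(matrix)[keep],
                 threshold = threshold,
                 fallback_fraction = fallback_fraction,
                 fallback_used = fallback_used),
            class = "pmp_selector")
}

#' @rdname fit_selector
#' @param selector a fitted `pmp_selector`.
#' @export
apply_selector <- function(selector, matrix) {
  stopifnot(inherits(selector, "pmp_selector"))
  missing <- setdiff(selector$retained, colnames(matrix))
  if (length(missing)) {
    stop("matrix lacks selected feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  matrix[, selector$retained, drop = FALSE]
}

#' Min-max normalization fitted on training data
#'
#' Records each feature's training minimum and maximum;
#' [apply_scaler()] maps `x` to `(x - min) / (max - min)`. Constant
#' features map to 0. Out-of-range values on new data are not clipped,
#' so test values may fall outside `[0, 1]`.
#'
#' @param matrix numeric feature matrix (samples x features).
#' @return object of class `pmp_scaler`.
#' @export
fit_scaler <- function(matrix) {
  if (!is.matrix(matrix) || !nrow(matrix)) stop("matrix must be non-empty")
  structure(list(min = apply(matrix, 2, min),
                 max = apply(matrix, 2, max)),
            class = "pmp_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `pmp_scaler`.
#' @export
apply_scaler <- function(scaler, matrix) {
  stopifnot(inherits(scaler, "pmp_scaler"))
  if (!identical(colnames(matrix), names(scaler$min))) {
    stop("feature names do not match the fitted scaler")
  }
  span <- scaler$max - scaler$min
  span[span == 0] <- Inf   # constant features -> 0
  sweep(sweep(matrix, 2, scaler$min, "-"), 2, span, "/")
}

#' Principal-component projection fitted on training data
#'
#' Centers the matrix and projects onto the leading
#' `min(n_components, features, samples - 1)` principal components.
#' Components are orthonormal and explained variances non-increasing.
#'
#' @param matrix numeric feature matrix (samples x features).
#' @param n_components maximum number of components (default 10).
#' @return object of class `pmp_projection` with elements `center`,
#'   `rotation`, `sdev`.
#' @export
fit_projection <- function(matrix, n_components = 10L) {
  if (!is.matrix(matrix) || nrow(matrix) < 2L) {
    stop("projection requires >= 2 samples")
  }
  k <- min(n_components, ncol(matrix), nrow(matrix) - 1L)
  pc <- stats::prcomp(matrix, center = TRUE, scale. = FALSE, rank. = k)
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev[seq_len(k)]),
            class = "pmp_projection")
}

#' @rdname fit_projection
#' @param projection a fitted `pmp_projection`.
#' @export
apply_projection <- function(projection, matrix) {
  stopifnot(inherits(projection, "pmp_projection"))
  if (!identical(colnames(matrix), names(projection$center))) {
    stop("feature names do not match the fitted projection")
  }
  scores <- sweep(matrix, 2, projection$center, "-") %*% projection$rotation
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

# Fit select -> scale -> project on training rows and return both the
# states and the transformed train/test matrices.
#' @noRd
fit_preprocess <- function(matrix, labels, ig_threshold = 0.05,
                           fallback_fraction = 0.80, n_components = 10L,
                           bins = 10L) {
  sel <- fit_selector(matrix, labels, threshold = ig_threshold,
                      fallback_fraction = fallback_fraction, bins = bins)
  xs <- apply_selector(sel, matrix)
  sca <- fit_scaler(xs)
  xn <- apply_scaler(sca, xs)
  proj <- fit_projection(xn, n_components = n_components)
  list(selector = sel, scaler = sca, projection = proj,
       transformed = apply_projection(proj, xn))
}

#' @noRd
apply_preprocess <- function(states, matrix) {
  apply_projection(states$projection,
                   apply_scaler(states$scaler,
                                apply_selector(states$selector, matrix)))
}
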