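.pmp_cache <- new.env(parent = emptyenv())

#' The 16 supported sequence descriptor classes
#'
#' @return character vector of class names in canonical order.
#' @export
descriptor_classes <- function() {
  c("TPC", "CKSAAP", "CKSAAGP", "KSCTriad", "DDE", "CTDC", "CTDT", "CTDD",
    "Moran", "Geary", "NMBroto", "QSOrder", "SOCNumber", "PAAC", "APAAC",
    "GTPC")
}

#' Specify a sequence descriptor class and its parameters
#'
#' Names one of the 16 descriptor families and fixes its tunable
#' parameters, which fully determine the output dimensionality:
#' * `k_max` — largest gap for the k-spaced pair/triad classes
#'   (CKSAAP, CKSAAGP, KSCTriad);
#' * `nlag` — number of lags for the autocorrelation and sequence-order
#'   classes (Moran, Geary, NMBroto, SOCNumber, QSOrder);
#' * `lambda` — number of sequence-order correlation tiers for the
#'   pseudo compositions (PAAC, APAAC);
#' * `weight` — pseudo-composition / quasi-order weight (default 0.05
#'   for PAAC/APAAC, 0.1 for QSOrder).
#'
#' @param class_name one of [descriptor_classes()].
#' @param k_max integer >= 0, default 5.
#' @param nlag integer >= 1, default 30.
#' @param lambda integer >= 1, default 30.
#' @param weight positive real, class-specific default.
#' @return object of class `descriptor_spec`.
#' @examples
#' descriptor_spec("TPC")
#' descriptor_spec("CKSAAP", k_max = 3)
#' @export
descriptor_spec <- function(class_name, k_max = 5L, nlag = 30L,
                            lambda = 30L, weight = NULL) {
  class_name <- match.arg(class_name, descriptor_classes())
  k_max <- as.integer(k_max); nlag <- as.integer(nlag)
  lambda <- as.integer(lambda)
  if (k_max < 0L) stop("k_max must be >= 0")
  if (nlag < 1L) stop("nlag must be >= 1")
  if (lambda < 1L) stop("lambda must be >= 1")
  weight <- weight %||% switch(class_name, QSOrder = 0.1, 0.05)
  if (!is.numeric(weight) || weight <= 0) stop("weight must be positive")
  structure(list(class_name = class_name,
                 params = list(k_max = k_max, nlag = nlag,
                               lambda = lambda, weight = weight)),
            class = "descriptor_spec")
}

#' @export
print.descriptor_spec <- function(x, ...) {
  cat("Descriptor: ", x$class_name, " (", descriptor_length(x),
      " features)\n", sep = "")
  invisible(x)
}

#' Output dimensionality of a descriptor
#'
#' @param spec a [descriptor_spec()].
#' @return integer number of features.
#' @export
descriptor_length <- function(spec) {
  stopifnot(inherits(spec, "descriptor_spec"))
  p <- spec$params
  switch(spec$class_name,
    TPC       = 8000L,
    GTPC      = 125L,
    CKSAAP    = 400L * (p$k_max + 1L),
    CKSAAGP   = 25L * (p$k_max + 1L),
    KSCTriad  = 343L * (p$k_max + 1L),
    DDE       = 400L,
    CTDC      = 21L,
    CTDT      = 21L,
    CTDD      = 105L,
    Moran     = ,
    Geary     = ,
    NMBroto   = nrow(AA_AUTOCORR_PROPS) * p$nlag,
    SOCNumber = 2L * p$nlag,
    QSOrder   = 40L + 2L * p$nlag,
    PAAC      = 20L + p$lambda,
    APAAC     = 20L + 2L * p$lambda)
}

#' Minimum sequence length required by a descriptor
#'
#' @param spec a [descriptor_spec()].
#' @return integer minimum number of residues.
#' @export
descriptor_min_length <- function(spec) {
  stopifnot(inherits(spec, "descriptor_spec"))
  p <- spec$params
  switch(spec$class_name,
    TPC = , GTPC = 3L,
    CKSAAP = , CKSAAGP = p$k_max + 2L,
    KSCTriad = 2L * p$k_max + 3L,
    DDE = , CTDT = 2L,
    CTDC = , CTDD = 1L,
    Moran = , Geary = , NMBroto = , SOCNumber = , QSOrder = p$nlag + 1L,
    PAAC = , APAAC = p$lambda + 1L)
}

# ---- feature-name generators -------------------------------------------

#' @noRd
descriptor_feature_names <- function(spec) {
  p <- spec$params
  cn <- spec$class_name
  g5 <- names(AA_GROUPS5)
  c7 <- names(AA_CONJOINT7)
  pref <- function(x) paste0(cn, ":", x)
  switch(cn,
    TPC = pref(paste0(rep(AA, each = 400L), rep(rep(AA, each = 20L), 20L),
                      rep(AA, 400L))),
    GTPC = pref(paste(rep(g5, each = 25L), rep(rep(g5, each = 5L), 5L),
                      rep(g5, 25L), sep = ".")),
    CKSAAP = pref(paste0(rep(paste0(rep(AA, each = 20L), rep(AA, 20L)),
                             p$k_max + 1L),
                         ".gap", rep(0:p$k_max, each = 400L))),
    CKSAAGP = pref(paste0(rep(paste(rep(g5, each = 5L), rep(g5, 5L),
                                    sep = "."), p$k_max + 1L),
                          ".gap", rep(0:p$k_max, each = 25L))),
    KSCTriad = pref(paste0(rep(paste(rep(c7, each = 49L),
                                     rep(rep(c7, each = 7L), 7L),
                                     rep(c7, 49L), sep = "."), p$k_max + 1L),
                           ".gap", rep(0:p$k_max, each = 343L))),
    DDE = pref(paste0(rep(AA, each = 20L), rep(AA, 20L))),
    CTDC = pref(paste0(rep(names(CTD_PROPERTIES), each = 3L), ".",
                       rep(c("g1", "g2", "g3"), 7L))),
    CTDT = pref(paste0(rep(names(CTD_PROPERTIES), each = 3L), ".",
                       rep(c("g1g2", "g1g3", "g2g3"), 7L))),
    CTDD = pref(paste0(rep(names(CTD_PROPERTIES), each = 15L), ".",
                       rep(rep(c("g1", "g2", "g3"), each = 5L), 7L), ".",
                       rep(c("p0", "p25", "p50", "p75", "p100"), 21L))),
    Moran = , Geary = , NMBroto =
      pref(paste0(rep(rownames(AA_AUTOCORR_PROPS), each = p$nlag),
                  ".lag", rep(seq_len(p$nlag), nrow(AA_AUTOCORR_PROPS)))),
    SOCNumber = pref(paste0(rep(c("pcd", "grantham"), each = p$nlag),
                            ".lag", rep(seq_len(p$nlag), 2L))),
    QSOrder = pref(c(paste0("pcd.", AA), paste0("grantham.", AA),
                     paste0("pcd.lag", seq_len(p$nlag)),
                     paste0("grantham.lag", seq_len(p$nlag)))),
    PAAC = pref(c(AA, paste0("lambda", seq_len(p$lambda)))),
    APAAC = pref(c(AA, paste0("lambda", rep(seq_len(p$lambda), each = 2L),
                              ".", rep(c("h1", "h2"), p$lambda)))))
}

# ---- standardization helpers -------------------------------------------

# z-score over the 20 residues with population (1/20) variance
#' @noRd
standardize20 <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  (x - m) / s
}

#' @noRd
autocorr_zprops <- function() {
  if (is.null(.pmp_cache$zprops)) {
    .pmp_cache$zprops <- t(apply(AA_AUTOCORR_PROPS, 1, standardize20))
  }
  .pmp_cache$zprops
}

#' @noRd
paac_zprops <- function() {
  if (is.null(.pmp_cache$paac_z)) {
    .pmp_cache$paac_z <- t(apply(AA_PAAC_PROPS, 1, standardize20))
  }
  .pmp_cache$paac_z
}

#' @noRd
distance_matrices <- function() {
  if (is.null(.pmp_cache$dist)) {
    .pmp_cache$dist <- list(pcd = pcd_distance_matrix(),
                            grantham = grantham_distance_matrix())
  }
  .pmp_cache$dist
}

# ---- per-class computations (all take an index vector over AA) ----------

#' @noRd
.desc_tpc <- function(idx) {
  n <- length(idx)
  codes <- (idx[1:(n - 2L)] - 1L) * 400L + (idx[2:(n - 1L)] - 1L) * 20L +
    idx[3:n]
  tabulate(codes, nbins = 8000L) / (n - 2L)
}

#' @noRd
.desc_gtpc <- function(idx) {
  n <- length(idx)
  g <- group_map(AA_GROUPS5)[idx]
  codes <- (g[1:(n - 2L)] - 1L) * 25L + (g[2:(n - 1L)] - 1L) * 5L + g[3:n]
  tabulate(codes, nbins = 125L) / (n - 2L)
}

#' @noRd
.desc_cksaap <- function(idx, k_max) {
  n <- length(idx)
  out <- numeric(0)
  for (k in 0:k_max) {
    m <- n - k - 1L
    codes <- (idx[1:m] - 1L) * 20L + idx[(k + 2L):n]
    out <- c(out, tabulate(codes, nbins = 400L) / m)
  }
  out
}

#' @noRd
.desc_cksaagp <- function(idx, k_max) {
  n <- length(idx)
  g <- group_map(AA_GROUPS5)[idx]
  out <- numeric(0)
  for (k in 0:k_max) {
    m <- n - k - 1L
    codes <- (g[1:m] - 1L) * 5L + g[(k + 2L):n]
    out <- c(out, tabulate(codes, nbins = 25L) / m)
  }
  out
}

#' @noRd
.desc_ksctriad <- function(idx, k_max) {
  n <- length(idx)
  cls <- group_map(AA_CONJOINT7)[idx]
  out <- numeric(0)
  for (k in 0:k_max) {
    m <- n - 2L * k - 2L
    i <- seq_len(m)
    codes <- (cls[i] - 1L) * 49L + (cls[i + k + 1L] - 1L) * 7L +
      cls[i + 2L * k + 2L]
    out <- c(out, tabulate(codes, nbins = 343L) / m)
  }
  out
}

#' @noRd
.desc_dde <- function(idx) {
  n <- length(idx)
  codes <- (idx[1:(n - 1L)] - 1L) * 20L + idx[2:n]
  dc <- tabulate(codes, nbins = 400L) / (n - 1L)
  cf <- AA_CODON_COUNTS / 61
  tm <- as.vector(t(outer(cf, cf)))        # r-major order: rep(cf, each=20)*rep(cf,20)
  tv <- tm * (1 - tm) / (n - 1L)
  (dc - tm) / sqrt(tv)
}

#' @noRd
.desc_ctdc <- function(idx) {
  n <- length(idx)
  unlist(lapply(CTD_PROPERTIES, function(prop) {
    g <- group_map(prop)[idx]
    tabulate(g, nbins = 3L) / n
  }), use.names = FALSE)
}

#' @noRd
.desc_ctdt <- function(idx) {
  n <- length(idx)
  unlist(lapply(CTD_PROPERTIES, function(prop) {
    g <- group_map(prop)[idx]
    a <- g[1:(n - 1L)]; b <- g[2:n]
    c(sum((a == 1L & b == 2L) | (a == 2L & b == 1L)),
      sum((a == 1L & b == 3L) | (a == 3L & b == 1L)),
      sum((a == 2L & b == 3L) | (a == 3L & b == 2L))) / (n - 1L)
  }), use.names = FALSE)
}

# Distribution: residue positions (as % of length) at which the first,
# 25%, 50%, 75% and last occurrence of each group is reached; 0 if the
# group is absent. Quartile ranks use ceiling, clamped to [1, n_g].
#' @noRd
.desc_ctdd <- function(idx) {
  n <- length(idx)
  unlist(lapply(CTD_PROPERTIES, function(prop) {
    g <- group_map(prop)[idx]
    unlist(lapply(1:3, function(j) {
      pos <- which(g == j)
      if (!length(pos)) return(numeric(5L))
      ng <- length(pos)
      ranks <- pmin(pmax(c(1L, ceiling(0.25 * ng), ceiling(0.5 * ng),
                           ceiling(0.75 * ng), ng), 1L), ng)
      100 * pos[ranks] / n
    }), use.names = FALSE)
  }), use.names = FALSE)
}

#' @noRd
.desc_autocorr <- function(idx, nlag, kind) {
  n <- length(idx)
  z <- autocorr_zprops()
  out <- numeric(nrow(z) * nlag)
  pos <- 0L
  for (p in seq_len(nrow(z))) {
    x <- z[p, idx]
    xbar <- mean(x)
    xc <- x - xbar
    ss <- sum(xc^2)
    for (d in seq_len(nlag)) {
      m <- n - d
      val <- switch(kind,
        moran = if (ss == 0) 0 else
          (sum(xc[1:m] * xc[(d + 1L):n]) / m) / (ss / n),
        geary = if (ss == 0) 0 else
          (sum((x[1:m] - x[(d + 1L):n])^2) / (2 * m)) / (ss / (n - 1L)),
        nmbroto = sum(x[1:m] * x[(d + 1L):n]) / m)
      pos <- pos + 1L
      out[pos] <- val
    }
  }
  out
}

# sequence-order coupling numbers: tau_d = sum of squared residue
# distances at lag d, for each of the two distance matrices
#' @noRd
.soc_taus <- function(idx, nlag) {
  n <- length(idx)
  dm <- distance_matrices()
  lapply(dm, function(d) {
    vapply(seq_len(nlag), function(lag) {
      m <- n - lag
      sum(d[cbind(idx[1:m], idx[(lag + 1L):n])]^2)
    }, numeric(1))
  })
}

#' @noRd
.desc_socnumber <- function(idx, nlag) {
  taus <- .soc_taus(idx, nlag)
  c(taus$pcd, taus$grantham)
}

#' @noRd
.desc_qsorder <- function(idx, nlag, weight) {
  taus <- .soc_taus(idx, nlag)
  f <- tabulate(idx, nbins = 20L)
  n <- length(idx)
  den_p <- n + weight * sum(taus$pcd)
  den_g <- n + weight * sum(taus$grantham)
  c(f / den_p, f / den_g,
    weight * taus$pcd / den_p, weight * taus$grantham / den_g)
}

#' @noRd
.desc_paac <- function(idx, lambda, weight) {
  n <- length(idx)
  z <- paac_zprops()
  theta <- vapply(seq_len(lambda), function(d) {
    m <- n - d
    i <- seq_len(m)
    mean((z[1, idx[i]] - z[1, idx[i + d]])^2 +
         (z[2, idx[i]] - z[2, idx[i + d]])^2 +
         (z[3, idx[i]] - z[3, idx[i + d]])^2) / 3
  }, numeric(1))
  f <- tabulate(idx, nbins = 20L) / n
  den <- 1 + weight * sum(theta)
  c(f / den, weight * theta / den)
}

#' @noRd
.desc_apaac <- function(idx, lambda, weight) {
  n <- length(idx)
  z <- paac_zprops()
  tau <- numeric(2L * lambda)
  for (d in seq_len(lambda)) {
    m <- n - d
    i <- seq_len(m)
    tau[2L * d - 1L] <- sum(z[1, idx[i]] * z[1, idx[i + d]]) / m
    tau[2L * d]      <- sum(z[2, idx[i]] * z[2, idx[i + d]]) / m
  }
  f <- tabulate(idx, nbins = 20L) / n
  den <- 1 + weight * sum(tau)
  c(f / den, weight * tau / den)
}

# ---- public API ---------------------------------------------------------

#' Tripeptide composition of a protein sequence
#'
#' Frequency of each of the 8000 ordered amino-acid triples among the
#' `N - 2` overlapping tripeptides of a length-`N` sequence:
#' `f(r,s,t) = N_rst / (N - 2)`. Entries sum to 1.
#'
#' @param record a single sequence string or a one-row
#'   [protein_records()] data frame.
#' @return named numeric vector of length 8000.
#' @examples
#' v <- compute_tpc("ACDA")
#' v[v > 0]
#' @export
compute_tpc <- function(record) {
  compute_descriptor(record, descriptor_spec("TPC"))
}

#' Compute one descriptor class for a single sequence
#'
#' Dispatches on `spec$class_name` to one of the 16 descriptor
#' computations. Feature naming is deterministic (`class:feature`), and
#' output dimensionality is a pure function of the spec.
#'
#' @param record a single sequence string or a one-row
#'   [protein_records()] data frame.
#' @param spec a [descriptor_spec()].
#' @return named numeric vector of length [descriptor_length()].
#' @examples
#' compute_descriptor("ACDEFGHIKL", descriptor_spec("CTDC"))[1:6]
#' @export
compute_descriptor <- function(record, spec) {
  stopifnot(inherits(spec, "descriptor_spec"))
  if (inherits(record, "protein_records")) {
    stopifnot(nrow(record) == 1L)
    id <- record$id
    sequence <- record$sequence
  } else {
    stopifnot(is.character(record), length(record) == 1L)
    id <- "<sequence>"
    sequence <- record
  }
  idx <- aa_to_index(sequence)
  need <- descriptor_min_length(spec)
  if (length(idx) < need) {
    stop("record ", id, " has length ", length(idx), " but ",
         spec$class_name, " requires at least ", need, " residues")
  }
  p <- spec$params
  v <- switch(spec$class_name,
    TPC       = .desc_tpc(idx),
    GTPC      = .desc_gtpc(idx),
    CKSAAP    = .desc_cksaap(idx, p$k_max),
    CKSAAGP   = .desc_cksaagp(idx, p$k_max),
    KSCTriad  = .desc_ksctriad(idx, p$k_max),
    DDE       = .desc_dde(idx),
    CTDC      = .desc_ctdc(idx),
    CTDT      = .desc_ctdt(idx),
    CTDD      = .desc_ctdd(idx),
    Moran     = .desc_autocorr(idx, p$nlag, "moran"),
    Geary     = .desc_autocorr(idx, p$nlag, "geary"),
    NMBroto   = .desc_autocorr(idx, p$nlag, "nmbroto"),
    SOCNumber = .desc_socnumber(idx, p$nlag),
    QSOrder   = .desc_qsorder(idx, p$nlag, p$weight),
    PAAC      = .desc_paac(idx, p$lambda, p$weight),
    APAAC     = .desc_apaac(idx, p$lambda, p$weight))
  stats::setNames(v, descriptor_feature_names(spec))
}

#' Build a samples-by-features descriptor matrix
#'
#' Applies one descriptor class to every record, producing a numeric
#' matrix with one row per record (input order preserved, row names =
#' record ids) and the class's canonical feature columns. Records shorter
#' than the class minimum raise one aggregated error; nothing is silently
#' dropped.
#'
#' @param records a [protein_records()] data frame.
#' @param spec a [descriptor_spec()].
#' @return numeric matrix with dimnames.
#' @export
build_feature_matrix <- function(records, spec) {
  stopifnot(inherits(records, "protein_records"),
            inherits(spec, "descriptor_spec"))
  need <- descriptor_min_length(spec)
  short <- nchar(records$sequence) < need
  if (any(short)) {
    stop(spec$class_name, " requires >= ", need, " residues; too short: ",
         paste(records$id[short], collapse = ", "))
  }
  out <- matrix(0, nrow = nrow(records), ncol = descriptor_length(spec),
                dimnames = list(records$id, descriptor_feature_names(spec)))
  for (i in seq_len(nrow(records))) {
    out[i, ] <- compute_descriptor(records$sequence[i], spec)
  }
  if (!all(is.finite(out))) stop("non-finite descriptor values produced")
  out
}

#' Write / read a feature matrix as tab-separated text
#'
#' The first column holds sample ids, the header row feature names.
#'
#' @param matrix numeric matrix with dimnames, as from
#'   [build_feature_matrix()].
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_feature_matrix <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
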