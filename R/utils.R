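#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals never perturb user-level randomness.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific 31-bit sub-seed from a user seed.
#' @noRd
sub_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + 7919 * stream) %% 2147483647
}

#' Bundle sequence records with binary labels and optional species tags
#'
#' The container passed between the data-preparation utilities, the
#' synthetic generator and the model-fitting functions.
#'
#' @param records a `protein_records` data frame (see [protein_records()]).
#' @param labels integer vector of 0/1 labels, one per record
#'   (1 = moonlighting / positive class).
#' @param species optional character vector of species tags, one per record.
#' @return an object of class `labeled_set`: a list with elements
#'   `records`, `labels` and `species`.
#' @examples
#' recs <- protein_records(c("p1", "p2"), c("MKVLA", "ACDEF"))
#' labeled_set(recs, c(1, 0))
#' @export
labeled_set <- function(records, labels, species = NULL) {
  stopifnot(inherits(records, "protein_records"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(records)) {
    stop("labels must align with records (", nrow(records), " records, ",
         length(labels), " labels)")
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (!is.null(species)) {
    species <- as.character(species)
    if (length(species) != nrow(records)) {
      stop("species must align with records")
    }
  }
  structure(list(records = records, labels = labels, species = species),
            class = "labeled_set")
}

#' @export
print.labeled_set <- function(x, ...) {
  cat("Labeled protein set: ", nrow(x$records), " sequences (",
      sum(x$labels == 1L), " positive, ", sum(x$labels == 0L), " negative)\n",
      sep = "")
  if (!is.null(x$species)) {
    cat("Species: ", paste(unique(x$species), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
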