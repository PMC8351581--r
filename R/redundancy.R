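# Pairwise sequence identity.
# "kmer" mode: containment of shared 5-mers,
#   |K(a) n K(b)| / min(|K(a)|, |K(b)|) — a fast alignment-free proxy for
#   clustering identity; exact duplicates score 1, k-mer-disjoint pairs 0.
# "alignment" mode: global pairwise alignment identity (PID over the
#   shorter sequence), closer to CD-HIT semantics but quadratic-cost.
#' @noRd
kmer_set <- function(sequence, k = 5L) {
  n <- nchar(sequence)
  if (n < k) return(sequence)
  unique(substring(sequence, 1:(n - k + 1L), k:n))
}

#' @noRd
pair_identity <- function(a, b, mode = "kmer", k = 5L,
                          ka = NULL, kb = NULL) {
  if (mode == "kmer") {
    ka <- ka %||% kmer_set(a, k)
    kb <- kb %||% kmer_set(b, k)
    length(intersect(ka, kb)) / min(length(ka), length(kb))
  } else {
    aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                         Biostrings::AAString(b),
                                         type = "global")
    Biostrings::pid(aln, type = "PID3") / 100
  }
}

#' Greedy within-set sequence redundancy reduction
#'
#' CD-HIT-style greedy clustering: sequences are visited longest first
#' (ties by id) and each becomes a new cluster representative unless its
#' identity to an existing representative reaches `identity_threshold`,
#' in which case it joins that cluster and is dropped. Every retained
#' pair therefore has identity below the threshold. Labels and species
#' tags follow the representatives.
#'
#' @param set a [labeled_set()].
#' @param identity_threshold identity cut-off in (0, 1], default 0.7.
#' @param mode `"kmer"` (default, shared 5-mer containment) or
#'   `"alignment"` (global alignment identity).
#' @param k k-mer size for `"kmer"` mode.
#' @return the reduced `labeled_set`, with a `clusters` attribute: a
#'   list mapping each representative id to its member ids.
#' @export
reduce_redundancy <- function(set, identity_threshold = 0.7,
                              mode = c("kmer", "alignment"), k = 5L) {
  stopifnot(inherits(set, "labeled_set"))
  mode <- match.arg(mode)
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  recs <- set$records
  ord <- order(-nchar(recs$sequence), recs$id)
  kept <- integer(0)
  ksets <- list()
  clusters <- list()
  for (i in ord) {
    ki <- if (mode == "kmer") kmer_set(recs$sequence[i], k) else NULL
    rep_hit <- 0L
    for (j in seq_along(kept)) {
      idy <- pair_identity(recs$sequence[kept[j]], recs$sequence[i],
                           mode = mode, k = k, ka = ksets[[j]], kb = ki)
      if (idy >= identity_threshold) { rep_hit <- j; break }
    }
    if (rep_hit == 0L) {
      kept <- c(kept, i)
      ksets[[length(kept)]] <- ki
      clusters[[recs$id[i]]] <- recs$id[i]
    } else {
      rep_id <- recs$id[kept[rep_hit]]
      clusters[[rep_id]] <- c(clusters[[rep_id]], recs$id[i])
    }
  }
  kept <- sort(kept)   # preserve input order among representatives
  out <- labeled_set(
    protein_records(recs$id[kept], recs$sequence[kept],
                    descriptions = recs$description[kept]),
    set$labels[kept],
    species = if (!is.null(set$species)) set$species[kept]
  )
  attr(out, "clusters") <- clusters
  out
}

#' Cross-set redundancy reduction
#'
#' Removes from `test` every sequence whose identity to any `train`
#' sequence reaches the threshold (the cd-hit-2d role: an independent
#' test set must not overlap the training set). `train` is unchanged.
#'
#' @param test,train [labeled_set()]s.
#' @inheritParams reduce_redundancy
#' @return the filtered `test` set.
#' @export
reduce_cross_redundancy <- function(test, train, identity_threshold = 0.7,
                                    mode = c("kmer", "alignment"), k = 5L) {
  stopifnot(inherits(test, "labeled_set"), inherits(train, "labeled_set"))
  mode <- match.arg(mode)
  if (!nrow(test$records)) return(test)
  train_k <- if (mode == "kmer") {
    lapply(train$records$sequence, kmer_set, k = k)
  }
  keep <- vapply(seq_len(nrow(test$records)), function(i) {
    ki <- if (mode == "kmer") kmer_set(test$records$sequence[i], k)
    for (j in seq_len(nrow(train$records))) {
      idy <- pair_identity(test$records$sequence[i],
                           train$records$sequence[j],
                           mode = mode, k = k, ka = ki,
                           kb = if (mode == "kmer") train_k[[j]])
      if (idy >= identity_threshold) return(FALSE)
    }
    TRUE
  }, logical(1))
  labeled_set(
    protein_records(test$records$id[keep], test$records$sequence[keep],
                    descriptions = test$records$description[keep]),
    test$labels[keep],
    species = if (!is.null(test$species)) test$species[keep]
  )
}

#' Species-wise train/test split
#'
#' Within each species, a seeded shuffle assigns
#' `round(train_fraction * n)` sequences (round half up) to the training
#' set and the remainder to the test set; the union is a partition of
#' the input.
#'
#' @param set a [labeled_set()] with species tags.
#' @param train_fraction fraction per species assigned to training
#'   (default 2/3).
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both `labeled_set`s.
#' @export
species_split <- function(set, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(inherits(set, "labeled_set"))
  if (is.null(set$species)) stop("species tags are required for the split")
  n <- nrow(set$records)
  take <- logical(n)
  with_seed(seed, {
    for (sp in unique(set$species)) {
      idx <- which(set$species == sp)
      n_train <- floor(train_fraction * length(idx) + 0.5)  # round half up
      take[sample(idx)[seq_len(n_train)]] <- TRUE
    }
  })
  subset_ls <- function(w) {
    labeled_set(protein_records(set$records$id[w], set$records$sequence[w],
                                descriptions = set$records$description[w]),
                set$labels[w], species = set$species[w])
  }
  list(train = subset_ls(take), test = subset_ls(!take))
}

#' Write a cluster report in cd-hit-like .clstr text format
#'
#' @param set a reduced `labeled_set` carrying the `clusters` attribute
#'   produced by [reduce_redundancy()], or that attribute itself.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(set, path) {
  clusters <- if (is.list(set) && is.null(attr(set, "clusters")) &&
                  !inherits(set, "labeled_set")) set else
    attr(set, "clusters")
  if (is.null(clusters)) stop("no cluster information found")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(clusters)) {
    writeLines(sprintf(">Cluster %d", i - 1L), con)
    members <- clusters[[i]]
    rep_id <- names(clusters)[i]
    for (j in seq_along(members)) {
      mark <- if (members[j] == rep_id) "*" else "at 100.00%"
      writeLines(sprintf("%d\t>%s... %s", j - 1L, members[j], mark), con)
    }
  }
  invisible(path)
}
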