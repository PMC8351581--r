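#' Construct a set of protein sequence records
#'
#' A `protein_records` object is a data frame with columns `id`,
#' `description` and `sequence`; it is the atomic input unit of the
#' descriptor and modelling functions. Sequences are uppercased and must
#' use only the 20 canonical amino-acid letters; ids must be unique.
#'
#' @param ids character vector of unique, non-empty identifiers.
#' @param sequences character vector of amino-acid sequences.
#' @param descriptions optional full header lines (defaults to `ids`).
#' @return a data frame of class `protein_records`.
#' @examples
#' protein_records("p1", "MKVLA")
#' @export
protein_records <- function(ids, sequences, descriptions = ids) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences)) {
    stop("ids and sequences must have equal length")
  }
  if (length(ids) && (anyNA(ids) || any(!nzchar(ids)))) {
    stop("record ids must be non-empty")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- grepl(sprintf("[^%s]", paste(AA, collapse = "")), sequences)
  if (any(bad)) {
    stop("non-canonical residues in record(s): ",
         paste(ids[bad], collapse = ", "), " (sanitize or use read_fasta)")
  }
  if (any(!nzchar(sequences))) {
    stop("empty sequence in record(s): ",
         paste(ids[!nzchar(sequences)], collapse = ", "))
  }
  structure(
    data.frame(id = ids, description = as.character(descriptions),
               sequence = sequences, stringsAsFactors = FALSE),
    class = c("protein_records", "data.frame")
  )
}

#' Remove non-canonical residues from a protein sequence
#'
#' Uppercases the sequence and removes every character that is not one of
#' the 20 canonical amino-acid letters (ambiguity codes X/B/Z/J, the rare
#' residues U/O, stops `*`, gaps and whitespace). Idempotent.
#'
#' @param sequence character vector of sequences.
#' @return character vector of cleaned sequences.
#' @examples
#' sanitize_sequence("mkX-v*")  # "MKV"
#' @export
sanitize_sequence <- function(sequence) {
  gsub(sprintf("[^%s]", paste(AA, collapse = "")), "",
       toupper(as.character(sequence)))
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a [protein_records()]
#' set. The record id is the header text up to the first whitespace; the
#' full header is kept as `description`. Sequences are uppercased and,
#' under the default policy, residues outside the 20-letter alphabet are
#' dropped with a warning; `strict = TRUE` rejects such records instead.
#'
#' @param path path to a FASTA file.
#' @param strict reject records containing non-canonical residues instead
#'   of dropping the offending residues.
#' @return a `protein_records` data frame, one row per FASTA entry in
#'   file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKVLA"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set) %||% character(0)
  ids <- sub("\\s.*$", "", headers)
  raw <- as.character(set)
  if (length(ids) && (anyNA(ids) || any(!nzchar(ids)))) {
    stop("FASTA entry with empty header in ", path)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  clean <- sanitize_sequence(raw)
  changed <- nchar(clean) != nchar(toupper(raw))
  if (any(changed)) {
    if (strict) {
      stop("non-canonical residues in record(s): ",
           paste(ids[changed], collapse = ", "))
    }
    warning("dropped non-canonical residues in record(s): ",
            paste(ids[changed], collapse = ", "))
  }
  empty <- !nzchar(clean)
  if (any(empty)) {
    stop("sequence empty after sanitization in record(s): ",
         paste(ids[empty], collapse = ", "))
  }
  protein_records(ids, clean, descriptions = headers)
}

#' Write protein records to a FASTA file
#'
#' Writes standard FASTA wrapped at 60 columns. `read_fasta()` of the
#' output reproduces ids and sequences exactly.
#'
#' @param records a `protein_records` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(inherits(records, "protein_records"))
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$description
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
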