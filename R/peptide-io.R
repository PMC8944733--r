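#' Peptide sets
#'
#' A `peptide_set` is a data frame with one row per peptide and columns `id`
#' (unique character), `sequence` (uppercase, 20-letter amino-acid alphabet)
#' and `annotations` (list of character tag vectors: activity names,
#' provenance, toxicity flags and the like).
#'
#' @param id character vector of unique peptide identifiers.
#' @param sequence character vector of amino-acid sequences (uppercased on
#'   construction).
#' @param annotations optional list of character vectors, one per peptide.
#' @param noncanonical policy for residues outside the 20-letter canonical
#'   alphabet: `"error"` rejects the record, `"mask"` replaces them with `X`
#'   (such records are excluded from descriptor computation).
#' @return A `peptide_set` data frame.
#' @examples
#' peptide_set(c("p1", "p2"), c("CNGRC", "WCAMS"))
#' @export
peptide_set <- function(id, sequence, annotations = NULL,
                        noncanonical = c("error", "mask")) {
  noncanonical <- match.arg(noncanonical)
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("'id' and 'sequence' must have the same length")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate peptide ids: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(sequence)))
    stop("empty sequence for id(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(.canonical_aa(), collapse = "")), sequence)
  if (any(bad)) {
    if (noncanonical == "error")
      stop("non-canonical residues in id(s): ",
           paste(id[bad], collapse = ", "))
    sequence[bad] <- gsub(sprintf("[^%s]", paste(.canonical_aa(), collapse = "")),
                          "X", sequence[bad])
  }
  if (is.null(annotations)) annotations <- rep(list(character(0)), length(id))
  if (length(annotations) != length(id))
    stop("'annotations' must have one element per peptide")
  annotations <- lapply(annotations, as.character)
  out <- data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
  out$annotations <- annotations
  class(out) <- c("peptide_set", "data.frame")
  out
}

#' @export
print.peptide_set <- function(x, ...) {
  cat(sprintf("peptide_set with %d sequence(s)\n", nrow(x)))
  if (nrow(x) > 0) {
    show <- utils::head(x, 6)
    for (i in seq_len(nrow(show))) {
      tags <- show$annotations[[i]]
      cat(sprintf("  %s  %s%s\n", show$id[i], show$sequence[i],
                  if (length(tags)) paste0("  [", paste(tags, collapse = "|"), "]") else ""))
    }
    if (nrow(x) > 6) cat(sprintf("  ... and %d more\n", nrow(x) - 6))
  }
  invisible(x)
}

#' Residue counts of a peptide set
#' @param records a `peptide_set`.
#' @return Integer vector of sequence lengths, named by id.
#' @export
peptide_lengths <- function(records) {
  stats::setNames(nchar(records$sequence), records$id)
}

#' Read a peptide FASTA file
#'
#' Headers may carry pipe-delimited annotation tags after the identifier
#' (`>starPep_07237|Tumor Homing|Antimicrobial`); with
#' `annotation_parse = TRUE` the tags are split into the `annotations`
#' column, otherwise the whole header is kept as the id. Sequences may be
#' line-wrapped. Records are uppercased on read.
#'
#' @param path path to a FASTA file.
#' @param annotation_parse parse pipe-delimited header tags (default `TRUE`).
#' @param noncanonical policy for non-canonical residues, see [peptide_set()].
#' @return A [peptide_set()] in file order.
#' @export
read_fasta <- function(path, annotation_parse = TRUE,
                       noncanonical = c("error", "mask")) {
  noncanonical <- match.arg(noncanonical)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0)
    return(peptide_set(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop(sprintf("malformed FASTA in '%s': line %d does not start a record",
                 path, nonblank[1]))
  aa <- tryCatch(
    Biostrings::readAAStringSet(path, format = "fasta"),
    error = function(e) stop(sprintf("malformed FASTA in '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  headers <- names(aa)
  seqs <- as.character(aa)
  if (any(!nzchar(seqs))) {
    empty <- headers[!nzchar(seqs)]
    stop(sprintf("malformed FASTA in '%s': empty sequence for record(s) %s",
                 path, paste(shQuote(empty), collapse = ", ")))
  }
  if (annotation_parse) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    ids <- vapply(parts, `[[`, character(1), 1)
    tags <- lapply(parts, function(p) trimws(p[-1][nzchar(trimws(p[-1]))]))
  } else {
    ids <- headers
    tags <- NULL
  }
  peptide_set(trimws(ids), seqs, tags, noncanonical = noncanonical)
}

#' Write a peptide set to FASTA
#'
#' Annotation tags are serialized pipe-delimited after the id; sequences are
#' written unwrapped. `read_fasta(write_fasta(x))` round-trips ids, sequences
#' and annotations.
#'
#' @param records a `peptide_set`.
#' @param path output file path.
#' @param annotations include annotation tags in headers (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, annotations = TRUE) {
  stopifnot(inherits(records, "peptide_set"))
  if (nrow(records) == 0) {
    cat("", file = path)
    return(invisible(path))
  }
  headers <- records$id
  if (annotations) {
    tags <- vapply(records$annotations, function(t)
      if (length(t)) paste0("|", paste(t, collapse = "|")) else "", character(1))
    headers <- paste0(headers, tags)
  }
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, path, width = max(nchar(records$sequence)) + 1L)
  invisible(path)
}

#' Filter peptides by length and annotation tags
#'
#' The screening front gate: retain peptides whose length lies in
#' `[min_len, max_len]` (inclusive) and whose annotations are disjoint from
#' `exclude_tags`. Input order is preserved; the operation is idempotent.
#'
#' @param records a `peptide_set`.
#' @param min_len,max_len inclusive residue-count bounds.
#' @param exclude_tags character vector of tags; any overlap removes the
#'   record (tag comparison is case-insensitive).
#' @return The filtered `peptide_set`.
#' @examples
#' ps <- peptide_set(c("a", "b"), c("KLA", "KLAKLAK"),
#'                   annotations = list("toxic", character(0)))
#' filter_records(ps, 3, 25, exclude_tags = "toxic")
#' @export
filter_records <- function(records, min_len = 3L, max_len = 25L,
                           exclude_tags = character(0)) {
  stopifnot(inherits(records, "peptide_set"))
  if (min_len < 1 || min_len > max_len)
    stop("need 1 <= min_len <= max_len")
  len <- nchar(records$sequence)
  keep <- len >= min_len & len <= max_len
  if (length(exclude_tags)) {
    ex <- tolower(exclude_tags)
    tagged <- vapply(records$annotations,
                     function(t) any(tolower(t) %in% ex), logical(1))
    keep <- keep & !tagged
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# rows of a peptide_set by id
.subset_ids <- function(records, ids) {
  out <- records[match(ids, records$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
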