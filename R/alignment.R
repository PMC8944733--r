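#' Alignment parameters
#'
#' Parameters for the Smith-Waterman (local) or Needleman-Wunsch (global)
#' peptide alignments used throughout the workflow. The default is local
#' alignment with BLOSUM62, gap open 10 and gap extension 1 (a gap of length
#' L costs `gap_open + L * gap_extend`).
#'
#' The identity score of an alignment is the number of identical aligned
#' columns divided by a normalizing length. With
#' `normalization = "shortest"` (default) the denominator is the length of
#' the shorter sequence, so a peptide recovered exactly as a fragment of a
#' longer one scores 1 and spurious short local matches between unrelated
#' peptides are penalized. `"alignment"` divides by the aligned columns
#' (gaps included) of the optimal local alignment instead.
#'
#' @param gap_open non-negative gap opening penalty.
#' @param gap_extend non-negative gap extension penalty (must not exceed
#'   `gap_open`).
#' @param substitution_matrix a matrix name from Biostrings (e.g.
#'   `"BLOSUM62"`) or a named substitution matrix covering the 20 canonical
#'   residues.
#' @param mode `"local"` (Smith-Waterman) or `"global"` (Needleman-Wunsch).
#' @param normalization `"shortest"` or `"alignment"`, see Details.
#' @return An `align_params` object.
#' @examples
#' align_params()
#' @export
align_params <- function(gap_open = 10, gap_extend = 1,
                         substitution_matrix = "BLOSUM62",
                         mode = c("local", "global"),
                         normalization = c("shortest", "alignment")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be non-negative")
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  if (is.character(substitution_matrix)) {
    name <- substitution_matrix
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    substitution_matrix <- get(name, envir = env)
  } else {
    name <- "custom"
  }
  aa <- .canonical_aa()
  if (!all(aa %in% rownames(substitution_matrix)) ||
      !all(aa %in% colnames(substitution_matrix)))
    stop("substitution matrix must cover the 20 canonical residues")
  if (!isTRUE(all.equal(unname(substitution_matrix[aa, aa]),
                        unname(t(substitution_matrix[aa, aa])))))
    stop("substitution matrix must be symmetric")
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 matrix_name = name, substitution_matrix = substitution_matrix,
                 mode = mode, normalization = normalization,
                 lookup = .sub_lookup(substitution_matrix)),
            class = "align_params")
}

#' @export
print.align_params <- function(x, ...) {
  cat(sprintf("alignment: %s, %s, gap open %g / extend %g, identity over %s\n",
              x$mode, x$matrix_name, x$gap_open, x$gap_extend,
              if (x$normalization == "shortest") "shorter-sequence length"
              else "aligned columns"))
  invisible(x)
}

# 26x26 score lookup indexed by (char - 'A'); letters absent from the
# substitution matrix fall back to its 'X' column when present
.sub_lookup <- function(m) {
  lk <- matrix(0, 26, 26)
  letters26 <- LETTERS
  has <- intersect(letters26, rownames(m))
  for (a in has) for (b in has)
    lk[match(a, letters26), match(b, letters26)] <- m[a, b]
  if ("X" %in% rownames(m)) {
    miss <- setdiff(letters26, has)
    for (a in miss) for (b in letters26) {
      bb <- if (b %in% has) b else "X"
      lk[match(a, letters26), match(b, letters26)] <- m["X", bb]
      lk[match(b, letters26), match(a, letters26)] <- m[bb, "X"]
    }
  }
  lk
}

.identity_from_counts <- function(n_id, aln_len, len_a, len_b, normalization) {
  if (normalization == "shortest") {
    n_id / pmin(len_a, len_b)
  } else {
    ifelse(aln_len > 0, n_id / aln_len, 0)
  }
}

.as_sequences <- function(x) {
  if (inherits(x, "peptide_set")) x$sequence
  else if (is.character(x)) toupper(x)
  else stop("expected a peptide_set or character sequences")
}

#' Pairwise identity score
#'
#' Aligns two peptides and returns their identity score, a number in
#' \[0, 1\] equal to the count of identical aligned columns of the optimal
#' alignment divided by the normalizing length (see [align_params()]). A
#' local alignment with no positive-scoring region has identity 0.
#'
#' @param a,b sequences (character) or single-row `peptide_set`s.
#' @param params an [align_params()] object.
#' @return A list of class `identity_score` with elements `value`,
#'   `n_identities`, `alignment_length` and `score`.
#' @examples
#' seq_identity("CNGRC", "CNGRCGGKLA")$value  # exact fragment: 1
#' @export
seq_identity <- function(a, b, params = align_params()) {
  a <- .as_sequences(a); b <- .as_sequences(b)
  stopifnot(length(a) == 1, length(b) == 1)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  r <- .align_pair_cpp(a, b, params$lookup, params$gap_open, params$gap_extend,
                       params$mode == "local")
  structure(list(value = .identity_from_counts(r[["n_id"]], r[["aln_len"]],
                                               nchar(a), nchar(b),
                                               params$normalization),
                 n_identities = as.integer(r[["n_id"]]),
                 alignment_length = as.integer(r[["aln_len"]]),
                 score = r[["score"]]),
            class = "identity_score")
}

#' @export
print.identity_score <- function(x, ...) {
  cat(sprintf("identity %.4f (%d identities / %d aligned columns, score %g)\n",
              x$value, x$n_identities, x$alignment_length, x$score))
  invisible(x)
}

#' All-vs-all identity matrix
#'
#' @param records a `peptide_set` (or character vector of sequences).
#' @param params an [align_params()] object.
#' @return Symmetric numeric matrix of identity scores with unit diagonal,
#'   dimnames = peptide ids.
#' @export
identity_matrix <- function(records, params = align_params()) {
  seqs <- .as_sequences(records)
  ids <- if (inherits(records, "peptide_set")) records$id else
    if (!is.null(names(records))) names(records) else as.character(seq_along(seqs))
  if (length(seqs) < 1) stop("need at least one record")
  if (any(!nzchar(seqs))) stop("empty sequence")
  r <- .align_pairwise_cpp(seqs, params$lookup, params$gap_open,
                           params$gap_extend, params$mode == "local")
  len <- nchar(seqs)
  lmin <- outer(len, len, pmin)
  m <- if (params$normalization == "shortest") r$n_id / lmin
       else ifelse(r$aln_len > 0, r$n_id / r$aln_len, 0)
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  m
}

#' Identity of many targets against many queries
#'
#' @param targets,queries `peptide_set`s or character vectors.
#' @param params an [align_params()] object.
#' @return Numeric matrix, rows = targets, columns = queries.
#' @export
cross_identity_matrix <- function(targets, queries, params = align_params()) {
  ts <- .as_sequences(targets); qs <- .as_sequences(queries)
  if (!length(ts) || !length(qs)) stop("empty input")
  if (any(!nzchar(ts)) || any(!nzchar(qs))) stop("empty sequence")
  r <- .align_cross_cpp(ts, qs, params$lookup, params$gap_open,
                        params$gap_extend, params$mode == "local")
  lmin <- outer(nchar(ts), nchar(qs), pmin)
  m <- if (params$normalization == "shortest") r$n_id / lmin
       else ifelse(r$aln_len > 0, r$n_id / r$aln_len, 0)
  rid <- if (inherits(targets, "peptide_set")) targets$id else names(ts)
  cid <- if (inherits(queries, "peptide_set")) queries$id else names(qs)
  dimnames(m) <- list(rid, cid)
  m
}

#' Identity-based redundancy filter
#'
#' Greedy sweep: records are visited in priority order (input order by
#' default, or descending by `priority` scores) and a record is kept iff its
#' identity to every already-kept record is `<= cutoff`, with exact
#' full-identity duplicates (identity 1) always treated as redundant.
#' Matches the "remove sequences with higher than X% similarity" convention;
#' at `cutoff = 1` only exact duplicates are removed.
#'
#' @param records a `peptide_set`.
#' @param cutoff identity cutoff in (0, 1\]; strictly greater identities are
#'   redundant.
#' @param params an [align_params()] object.
#' @param priority optional numeric scores (higher first); ties keep input
#'   order.
#' @return The retained `peptide_set`, in input order.
#' @export
redundancy_filter <- function(records, cutoff = 0.98, params = align_params(),
                              priority = NULL) {
  stopifnot(inherits(records, "peptide_set"))
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  n <- nrow(records)
  if (n <= 1) return(records)
  ord <- if (is.null(priority)) seq_len(n)
         else order(-priority, seq_len(n))
  m <- identity_matrix(records, params)
  kept <- integer(0)
  for (i in ord) {
    prior <- m[i, kept]
    if (all(prior <= cutoff) && all(prior < 1)) kept <- c(kept, i)
  }
  out <- records[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}
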