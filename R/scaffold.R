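#' Centrality-ranked scaffold extraction
#'
#' Greedy representative selection: peptides are swept in descending
#' centrality order (ties broken lexicographically by id) and a peptide is
#' kept iff its identity to every already-kept peptide is strictly below the
#' cutoff. The most central peptide is always kept, and every removed
#' peptide is blocked by a kept, more central one at identity >= cutoff —
#' the output is a non-redundant representative set.
#'
#' @param records a `peptide_set`.
#' @param centrality a `centrality_table` covering all record ids.
#' @param identity_cutoff cutoff in (0, 1\].
#' @param params an [align_params()] object.
#' @return The kept `peptide_set`, in sweep (centrality) order.
#' @export
scaffold_extract <- function(records, centrality, identity_cutoff = 0.30,
                             params = align_params()) {
  stopifnot(inherits(records, "peptide_set"),
            inherits(centrality, "centrality_table"))
  if (identity_cutoff <= 0 || identity_cutoff > 1)
    stop("identity_cutoff must be in (0, 1]")
  missing <- setdiff(records$id, centrality$id)
  if (length(missing))
    stop("missing centrality for record(s): ", paste(missing, collapse = ", "))
  score <- centrality$normalized[match(records$id, centrality$id)]
  ord <- order(-score, records$id)
  m <- identity_matrix(records, params)
  kept <- integer(0)
  for (i in ord) {
    if (all(m[i, kept] < identity_cutoff)) kept <- c(kept, i)
  }
  out <- records[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only nodes near the top centrality
#'
#' The "+10 percent" pruning variant: retains records whose normalized
#' centrality is at least `(1 - drop_fraction)` times the maximum over the
#' input set.
#'
#' @param records a `peptide_set`.
#' @param centrality a `centrality_table` covering all record ids.
#' @param drop_fraction fraction in \[0, 1).
#' @return The retained `peptide_set`, input order preserved.
#' @export
prune_by_top_centrality <- function(records, centrality, drop_fraction = 0.10) {
  stopifnot(inherits(records, "peptide_set"))
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must be in [0, 1)")
  score <- centrality$normalized[match(records$id, centrality$id)]
  if (anyNA(score))
    stop("missing centrality for record(s): ",
         paste(records$id[is.na(score)], collapse = ", "))
  keep <- score >= (1 - drop_fraction) * max(score)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a similarity searching model from query sets
#'
#' Takes the union (by id) of one or more query peptide sets — e.g. the
#' harmonic-centrality scaffold, the weighted-degree scaffold and the CSN
#' outliers — and packages them with an identity threshold into an SSM, the
#' binary classifier used for searching.
#'
#' @param name model name.
#' @param sets list of `peptide_set`s; duplicates collapse by id.
#' @param theta identity threshold in \[0, 1\]; a target scoring
#'   `>= theta` against any query is predicted positive.
#' @param params an [align_params()] object.
#' @param provenance optional free-form list recorded in the model.
#' @return An object of class `ssm`; see [ssm_fit()] for the methods.
#' @export
build_query_model <- function(name, sets, theta = 0.60,
                              params = align_params(), provenance = list()) {
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  if (inherits(sets, "peptide_set")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, logical(1), "peptide_set")))
  all_ids <- unlist(lapply(sets, `[[`, "id"))
  if (!length(all_ids)) stop("empty query union")
  combined <- do.call(rbind, lapply(sets, function(s) s[, c("id", "sequence")]))
  first <- !duplicated(combined$id)
  conflicting <- tapply(combined$sequence, combined$id,
                        function(s) length(unique(s)) > 1)
  if (any(conflicting))
    stop("same id with different sequences across sets: ",
         paste(names(conflicting)[conflicting], collapse = ", "))
  queries <- peptide_set(combined$id[first], combined$sequence[first])
  provenance$set_sizes <- vapply(sets, nrow, integer(1))
  structure(list(name = name, queries = queries, theta = theta,
                 params = params, provenance = provenance),
            class = "ssm")
}
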