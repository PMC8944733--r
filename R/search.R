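#' Group-fusion (MAX-SIM) similarity scores
#'
#' Scores every target against all queries of an SSM and fuses by the MAX
#' rule: the fused score of a target is its maximum identity over the query
#' set, and the best query is the arg-max (ties: lowest query id).
#'
#' @param model an `ssm` ([build_query_model()] / [ssm_fit()]).
#' @param targets a `peptide_set`.
#' @return Data frame of class `search_hits` with columns `target_id`,
#'   `fused_score`, `best_query_id`, sorted as the targets; rank with
#'   `order(-fused_score)`.
#' @export
fused_scores <- function(model, targets) {
  stopifnot(inherits(model, "ssm"), inherits(targets, "peptide_set"))
  if (nrow(targets) == 0) stop("empty targets")
  m <- cross_identity_matrix(targets, model$queries, model$params)
  qids <- model$queries$id
  qorder <- order(qids)
  m_sorted <- m[, qorder, drop = FALSE]
  best_col <- max.col(m_sorted, ties.method = "first")
  out <- data.frame(target_id = targets$id,
                    fused_score = apply(m, 1, max),
                    best_query_id = qids[qorder][best_col],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("search_hits", "data.frame")
  out
}

#' Classify search hits at an identity threshold
#'
#' A hit is predicted positive iff its fused score is greater than or equal
#' to `theta` (inclusive boundary).
#'
#' @param hits a `search_hits` data frame from [fused_scores()].
#' @param theta identity threshold in \[0, 1\].
#' @return `hits` with an added `predicted` factor (`"positive"` /
#'   `"negative"`).
#' @export
classify_hits <- function(hits, theta) {
  stopifnot(inherits(hits, "search_hits"))
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  hits$predicted <- factor(ifelse(hits$fused_score >= theta,
                                  "positive", "negative"),
                           levels = c("positive", "negative"))
  hits
}

#' Hierarchical prospective screening
#'
#' The repurposing funnel applied to a candidate database: (1) length and
#' annotation-tag filtering, (2) redundancy removal at a local-identity
#' cutoff, (3) multi-query MAX-SIM search with the SSM and classification at
#' its threshold, (4) removal of perfect matches (fused score 1, i.e.
#' already-known sequences). Stage in/out counts are recorded so the funnel
#' can be audited.
#'
#' @param db a `peptide_set` to screen.
#' @param model an `ssm`.
#' @param min_len,max_len length bounds for stage 1 (defaults 3 and 25).
#' @param exclude_tags annotation tags removed at stage 1 (default the
#'   tumor-homing and toxicity tags, so known/undesired actives drop out).
#' @param redundancy_cutoff identity cutoff of stage 2 (default 0.95).
#' @param drop_perfect drop hits with fused score equal to 1 after rounding
#'   to 6 decimals (default `TRUE`).
#' @return Data frame of class `screen_hits`: the positive hits ranked by
#'   decreasing fused score, with attribute `stage_log` (data frame of
#'   per-stage record counts).
#' @export
prospective_screen <- function(db, model, min_len = 3L, max_len = 25L,
                               exclude_tags = c("Tumor Homing", "toxic"),
                               redundancy_cutoff = 0.95,
                               drop_perfect = TRUE) {
  stopifnot(inherits(db, "peptide_set"), inherits(model, "ssm"))
  log <- data.frame(stage = character(0), n_in = integer(0), n_out = integer(0))
  note <- function(stage, n_in, n_out)
    rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out))

  s1 <- filter_records(db, min_len, max_len, exclude_tags)
  log <- note("length_tag_filter", nrow(db), nrow(s1))
  s2 <- if (nrow(s1) > 1) redundancy_filter(s1, redundancy_cutoff, model$params)
        else s1
  log <- note("redundancy_filter", nrow(s1), nrow(s2))
  if (nrow(s2) == 0) {
    out <- data.frame(target_id = character(0), fused_score = numeric(0),
                      best_query_id = character(0), predicted = factor(character(0)))
    class(out) <- c("screen_hits", "data.frame")
    attr(out, "stage_log") <- log
    return(out)
  }
  hits <- classify_hits(fused_scores(model, s2), model$theta)
  s3 <- hits[hits$predicted == "positive", , drop = FALSE]
  log <- note("similarity_search", nrow(s2), nrow(s3))
  if (drop_perfect) {
    s4 <- s3[round(s3$fused_score, 6) != 1, , drop = FALSE]
    log <- note("drop_perfect_matches", nrow(s3), nrow(s4))
  } else s4 <- s3
  s4 <- s4[order(-s4$fused_score, s4$target_id), , drop = FALSE]
  rownames(s4) <- NULL
  class(s4) <- c("screen_hits", "search_hits", "data.frame")
  attr(s4, "stage_log") <- log
  s4
}

#' Nearest known neighbors of screening hits
#'
#' "Visual mining": each hit is embedded into the reference CSN (descriptor
#' similarity computed over the union of reference and hit peptides at the
#' reference threshold) and its up-to-k directly attached reference
#' neighbors with highest similarity are reported. Hits sharing at least
#' `flag_shared` of their neighbors are flagged as redundant candidates.
#'
#' @param hits a `peptide_set` of screening hits.
#' @param reference a `peptide_set` of known actives (the reference CSN
#'   nodes).
#' @param t similarity threshold of the reference CSN (default 0.60).
#' @param k neighbors per hit (default 3).
#' @param flag_shared minimum number of shared neighbors that flags a pair
#'   of hits as redundant (default 2).
#' @param descriptors optional descriptor subset passed to
#'   [peptide_descriptors()].
#' @return Data frame with one row per (hit, neighbor): `hit_id`,
#'   `neighbor_id`, `similarity`, `rank`; attribute `flagged` lists hit id
#'   pairs sharing `>= flag_shared` neighbors.
#' @export
nearest_known_neighbors <- function(hits, reference, t = 0.60, k = 3L,
                                    flag_shared = 2L, descriptors = NULL) {
  stopifnot(inherits(hits, "peptide_set"), inherits(reference, "peptide_set"))
  if (k < 1) stop("k must be >= 1")
  combined <- peptide_set(c(reference$id, hits$id),
                          c(reference$sequence, hits$sequence))
  d <- minmax_normalize(peptide_descriptors(combined, descriptors))
  sim <- .pairwise_similarity(d)
  ref_idx <- seq_len(nrow(reference))
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    s <- sim[nrow(reference) + i, ref_idx]
    attached <- which(s >= t)
    if (!length(attached)) return(NULL)
    ord <- attached[order(-s[attached], reference$id[attached])]
    ord <- ord[seq_len(min(k, length(ord)))]
    data.frame(hit_id = hits$id[i], neighbor_id = reference$id[ord],
               similarity = as.numeric(s[ord]), rank = seq_along(ord),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(hit_id = character(0), neighbor_id = character(0),
                      similarity = numeric(0), rank = integer(0))
  rownames(out) <- NULL
  nb <- split(out$neighbor_id, out$hit_id)
  flagged <- list()
  ids <- names(nb)
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) for (j in seq(i + 1, length(ids))) {
      if (length(intersect(nb[[i]], nb[[j]])) >= flag_shared)
        flagged[[length(flagged) + 1]] <- c(ids[i], ids[j])
    }
  }
  attr(out, "flagged") <- flagged
  out
}
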