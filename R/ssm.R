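#' Fit a similarity searching model from a set of active peptides
#'
#' The model-building pipeline: starting from a pool of known actives
#' (e.g. tumor-homing peptides), (1) near-duplicates are removed at a high
#' local-identity cutoff, (2) physicochemical descriptors are computed and
#' min-max normalized, (3) the chemical space network is built at the
#' working similarity threshold, (4) degree-0 nodes are split off as
#' outliers and Louvain communities are detected on the connected part,
#' (5) each requested centrality measure is computed and a centrality-ranked
#' scaffold extraction retains its non-redundant representatives, and
#' (6) the union of the scaffold sets and the outliers becomes the query set
#' of an SSM with identity threshold `theta`.
#'
#' The fitted object classifies new peptides by group fusion: a target is
#' predicted active iff its maximum Smith-Waterman identity over the queries
#' is at least `theta` (see [predict.ssm()]).
#'
#' @param records a `peptide_set` of active peptides (>= 2).
#' @param csn_threshold similarity threshold of the CSN (default 0.60).
#' @param theta identity threshold of the fitted classifier (default 0.60).
#' @param scaffold_cutoff identity cutoff of the scaffold extraction
#'   (default 0.60).
#' @param dedup_cutoff near-duplicate removal cutoff (default 0.98).
#' @param centralities centrality measures whose scaffold sets enter the
#'   query union (default harmonic + weighted degree).
#' @param include_outliers add the CSN outliers to the query union
#'   (default `TRUE`).
#' @param params an [align_params()] object.
#' @param descriptors optional descriptor subset (see
#'   [peptide_descriptors()]).
#' @param rng_seed Louvain seed.
#' @param name model name (auto-generated by default).
#' @return An object of class `ssm` with elements `name`, `queries`,
#'   `theta`, `params`, `provenance`, `network` (the CSN with communities),
#'   `centrality` (list of centrality tables) and `stage_log`.
#' @examples
#' fam <- generate_families(synthetic_spec(n_families = 2, family_size = 4,
#'                                         n_unrelated = 4, rng_seed = 1))
#' fit <- ssm_fit(fam$records)
#' fit
#' @export
ssm_fit <- function(records, csn_threshold = 0.60, theta = 0.60,
                    scaffold_cutoff = 0.60, dedup_cutoff = 0.98,
                    centralities = c("harmonic", "weighted_degree"),
                    include_outliers = TRUE, params = align_params(),
                    descriptors = NULL, rng_seed = 42L, name = NULL) {
  stopifnot(inherits(records, "peptide_set"))
  if (nrow(records) < 2) stop("need at least 2 records to fit an SSM")
  log <- list()
  dedup <- redundancy_filter(records, dedup_cutoff, params)
  log$dedup <- c(n_in = nrow(records), n_out = nrow(dedup))

  desc <- minmax_normalize(peptide_descriptors(dedup, descriptors))
  net <- build_csn(desc, csn_threshold)
  parts <- split_giant_outliers(net)
  log$csn <- c(n_nodes = igraph::vcount(net),
               n_edges = igraph::ecount(net),
               n_outliers = length(parts$outliers))

  sets <- list()
  cent_tables <- list()
  if (igraph::vcount(parts$connected) > 0 &&
      igraph::ecount(parts$connected) > 0) {
    connected <- detect_communities(parts$connected, rng_seed)
    conn_records <- .subset_ids(dedup, igraph::V(connected)$name)
    for (meas in centralities) {
      ct <- compute_centrality(connected, meas)
      cent_tables[[meas]] <- ct
      sc <- scaffold_extract(conn_records, ct, scaffold_cutoff, params)
      sets[[meas]] <- sc
      log[[paste0("scaffold_", meas)]] <-
        c(n_in = nrow(conn_records), n_out = nrow(sc))
    }
  } else {
    connected <- parts$connected
  }
  if (include_outliers && length(parts$outliers))
    sets$outliers <- .subset_ids(dedup, parts$outliers)
  if (!length(sets)) stop("empty query union: no scaffold sets or outliers")

  if (is.null(name))
    name <- sprintf("CSN-%.2f-Sc%.2f-%s%s-%.2f", csn_threshold,
                    scaffold_cutoff, paste(substr(centralities, 1, 1),
                                           collapse = "+"),
                    if (include_outliers) "+s" else "", theta)
  model <- build_query_model(name, sets, theta, params,
                             provenance = list(
                               csn_threshold = csn_threshold,
                               scaffold_cutoff = scaffold_cutoff,
                               dedup_cutoff = dedup_cutoff,
                               centralities = centralities,
                               include_outliers = include_outliers,
                               rng_seed = rng_seed))
  log$query_union <- c(n_sets = length(sets), n_queries = nrow(model$queries))
  model$network <- connected
  model$outliers <- parts$outliers
  model$centrality <- cent_tables
  model$stage_log <- log
  model
}

#' @export
print.ssm <- function(x, ...) {
  cat(sprintf("similarity searching model '%s'\n", x$name))
  cat(sprintf("  %d queries, identity threshold %.2f\n",
              nrow(x$queries), x$theta))
  print(x$params)
  invisible(x)
}

#' @method summary ssm
#' @export
summary.ssm <- function(object, ...) {
  cat(sprintf("similarity searching model '%s'\n", object$name))
  cat(sprintf("  queries: %d (theta = %.2f)\n", nrow(object$queries),
              object$theta))
  if (!is.null(object$stage_log)) {
    cat("  pipeline stages:\n")
    for (nm in names(object$stage_log))
      cat(sprintf("    %-22s %s\n", nm,
                  paste(names(object$stage_log[[nm]]),
                        object$stage_log[[nm]], sep = "=", collapse = "  ")))
  }
  if (!is.null(object$provenance$set_sizes))
    cat("  query set sizes before union:",
        paste(object$provenance$set_sizes, collapse = ", "), "\n")
  invisible(object)
}

#' Predict activity of new peptides with a fitted SSM
#'
#' @param object an `ssm`.
#' @param newdata a `peptide_set` of target peptides.
#' @param theta identity threshold (defaults to the model's).
#' @param type `"class"` returns classified hits (fused score, best query,
#'   predicted label); `"score"` returns the fused scores only.
#' @param ... unused.
#' @return A classified `search_hits` data frame (`type = "class"`) or a
#'   named numeric vector of fused scores (`type = "score"`).
#' @export
predict.ssm <- function(object, newdata, theta = object$theta,
                        type = c("class", "score"), ...) {
  type <- match.arg(type)
  hits <- fused_scores(object, newdata)
  if (type == "score")
    return(stats::setNames(hits$fused_score, hits$target_id))
  classify_hits(hits, theta)
}

#' Plot a fitted SSM
#'
#' Draws the connected component of the underlying CSN, colored by Louvain
#' community, with query nodes emphasized; falls back to a fused-score
#' histogram of the queries against themselves when the network is absent.
#'
#' @param x an `ssm`.
#' @param ... passed to [igraph::plot.igraph()].
#' @method plot ssm
#' @export
plot.ssm <- function(x, ...) {
  net <- x$network
  if (!is.null(net) && igraph::vcount(net) > 0) {
    memb <- igraph::vertex_attr(net, "community")
    cols <- if (!is.null(memb)) grDevices::rainbow(max(memb))[memb] else "grey70"
    is_query <- igraph::V(net)$name %in% x$queries$id
    plot(net, vertex.color = cols, vertex.size = ifelse(is_query, 8, 4),
         vertex.label = NA, vertex.frame.color = ifelse(is_query, "black", NA),
         main = x$name, ...)
  } else {
    m <- identity_matrix(x$queries, x$params)
    graphics::hist(m[upper.tri(m)], breaks = 20,
                   main = x$name, xlab = "pairwise query identity")
  }
  invisible(x)
}

#' End-to-end pipelines
#'
#' `build_model_pipeline()` reads an actives FASTA, fits the SSM and writes
#' the artifacts (query FASTA, GraphML of the CSN, stage log and
#' configuration sidecar) into `out_dir`. `evaluate_pipeline()` performs the
#' retrospective validation of a model on labeled positive/negative sets.
#'
#' @param fasta path to the actives FASTA file (or a `peptide_set`).
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @param ... passed to [ssm_fit()].
#' @return `build_model_pipeline()`: the fitted `ssm` (invisibly carries
#'   output paths in `$files`).
#' @export
build_model_pipeline <- function(fasta, out_dir = NULL, ...) {
  records <- if (inherits(fasta, "peptide_set")) fasta else read_fasta(fasta)
  model <- ssm_fit(records, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(queries = file.path(out_dir, "queries.fasta"),
                  graphml = file.path(out_dir, "csn.graphml"),
                  log = file.path(out_dir, "stage_log.tsv"),
                  config = file.path(out_dir, "config.txt"))
    write_fasta(model$queries, files$queries)
    if (!is.null(model$network) && igraph::vcount(model$network) > 0)
      export_graphml(model$network, files$graphml)
    log_df <- do.call(rbind, lapply(names(model$stage_log), function(nm)
      data.frame(stage = nm,
                 key = names(model$stage_log[[nm]]),
                 value = unname(model$stage_log[[nm]]))))
    utils::write.table(log_df, files$log, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    prov <- model$provenance
    writeLines(c(sprintf("name=%s", model$name),
                 sprintf("theta=%g", model$theta),
                 sprintf("gap_open=%g", model$params$gap_open),
                 sprintf("gap_extend=%g", model$params$gap_extend),
                 sprintf("matrix=%s", model$params$matrix_name),
                 sprintf("normalization=%s", model$params$normalization),
                 vapply(names(prov), function(k)
                   sprintf("%s=%s", k, paste(prov[[k]], collapse = ",")),
                   character(1))),
               files$config)
    model$files <- files
  }
  model
}

#' @rdname build_model_pipeline
#' @param model an `ssm`.
#' @param positives,negatives `peptide_set`s (or FASTA paths) of labeled
#'   benchmark peptides.
#' @param theta identity threshold (defaults to the model's).
#' @return `evaluate_pipeline()`: a `metrics_report` with the confusion
#'   matrix attached as attribute `confusion`.
#' @export
evaluate_pipeline <- function(model, positives, negatives,
                              theta = model$theta) {
  stopifnot(inherits(model, "ssm"))
  if (!inherits(positives, "peptide_set")) positives <- read_fasta(positives)
  if (!inherits(negatives, "peptide_set")) negatives <- read_fasta(negatives)
  targets <- peptide_set(c(positives$id, negatives$id),
                         c(positives$sequence, negatives$sequence))
  truth <- rep(c("positive", "negative"), c(nrow(positives), nrow(negatives)))
  hits <- classify_hits(fused_scores(model, targets), theta)
  cm <- confusion(hits$predicted, truth)
  rep <- classification_metrics(cm)
  attr(rep, "confusion") <- cm
  rep
}
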