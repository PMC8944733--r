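#' Build a chemical space network
#'
#' Nodes are peptides; the Euclidean distance between their min-max
#' normalized descriptor rows is itself min-max normalized over all unordered
#' pairs of the input set, and similarity = 1 - normalized distance. An edge
#' connects every pair with similarity >= the threshold `t`; isolated nodes
#' stay in the graph (they are the CSN outliers/singletons).
#'
#' @param descriptor_matrix a normalized descriptor matrix
#'   ([minmax_normalize()]) with >= 2 rows.
#' @param t similarity threshold in \[0, 1\].
#' @return An undirected weighted [igraph::igraph] graph of class
#'   `csn` with edge attribute `weight` (the similarity) and graph
#'   attribute `threshold`.
#' @examples
#' ps <- peptide_set(letters[1:4],
#'                   c("CNGRC", "CNGRV", "KLAKLAK", "KLAKLAG"))
#' d <- minmax_normalize(peptide_descriptors(ps))
#' build_csn(d, t = 0.8)
#' @export
build_csn <- function(descriptor_matrix, t = 0.60) {
  if (nrow(descriptor_matrix) < 2) stop("need at least 2 records")
  if (!isTRUE(attr(descriptor_matrix, "normalized")))
    stop("descriptor matrix must be min-max normalized first")
  if (t < 0 || t > 1) stop("threshold must be in [0, 1]")
  sim <- .pairwise_similarity(descriptor_matrix)
  ids <- rownames(descriptor_matrix)
  adj <- sim >= t
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- ids
  ends <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- sim[cbind(ends[, 1], ends[, 2])]
  g <- igraph::set_graph_attr(g, "threshold", t)
  class(g) <- c("csn", class(g))
  g
}

# similarity = 1 - min-max normalized Euclidean distance over unordered pairs
.pairwise_similarity <- function(descriptor_matrix) {
  d <- as.matrix(stats::dist(descriptor_matrix))
  off <- d[upper.tri(d)]
  rng <- range(off)
  s <- if (rng[1] == rng[2]) matrix(1, nrow(d), ncol(d))
       else 1 - (d - rng[1]) / (rng[2] - rng[1])
  dimnames(s) <- dimnames(d)
  s
}

#' Global network metrics of a CSN
#'
#' Density is reported on the full node set (isolated nodes included);
#' diameter and average path length are unweighted hop distances on the
#' largest connected component; the average clustering coefficient (ACC) is
#' the mean local clustering coefficient with degree < 2 nodes contributing
#' 0. Community count and modularity are reported when the graph carries a
#' `community` vertex attribute (see [detect_communities()]), else `NA`.
#'
#' @param net an igraph graph (typically from [build_csn()]).
#' @return A one-row data frame: `n_nodes`, `n_edges`, `density`,
#'   `n_communities`, `modularity`, `average_degree`,
#'   `average_clustering_coefficient`, `diameter`, `average_path_length`,
#'   `n_triangles`, `n_singletons`.
#' @export
network_metrics <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) stop("empty network")
  e <- igraph::ecount(net)
  deg <- igraph::degree(net)
  local_cc <- igraph::transitivity(net, type = "localundirected", isolates = "zero")
  comp <- igraph::components(net)
  giant <- igraph::induced_subgraph(
    net, which(comp$membership == which.max(comp$csize)))
  memb <- igraph::vertex_attr(net, "community")
  if (!is.null(memb)) {
    ncomm <- length(unique(memb))
    mod <- .modularity_safe(net, memb)
  } else {
    ncomm <- NA_real_
    mod <- NA_real_
  }
  data.frame(
    n_nodes = n, n_edges = e,
    density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
    n_communities = ncomm, modularity = mod,
    average_degree = 2 * e / n,
    average_clustering_coefficient = mean(local_cc),
    diameter = if (igraph::ecount(giant) > 0)
      igraph::diameter(giant, weights = NA) else 0,
    average_path_length = if (igraph::ecount(giant) > 0)
      igraph::mean_distance(giant, weights = NA) else 0,
    n_triangles = sum(igraph::count_triangles(net)) / 3,
    n_singletons = sum(deg == 0))
}

.modularity_safe <- function(net, membership) {
  if (igraph::ecount(net) == 0) return(0)
  igraph::modularity(net, as.integer(factor(membership)),
                     weights = igraph::E(net)$weight)
}

#' Louvain community detection
#'
#' Weighted Louvain modularity optimization; the RNG seed fixes the node
#' sweep so results are reproducible. An edgeless network yields one
#' community per node with modularity 0.
#'
#' @param net an igraph graph.
#' @param rng_seed integer seed (default 42).
#' @return The input graph with a `community` vertex attribute, plus
#'   attributes accessible via [network_metrics()]; the modularity of the
#'   partition is stored as graph attribute `modularity`.
#' @export
detect_communities <- function(net, rng_seed = 42L) {
  if (igraph::ecount(net) == 0) {
    memb <- seq_len(igraph::vcount(net))
    q <- 0
  } else {
    memb <- withr_seed(rng_seed, {
      cl <- igraph::cluster_louvain(net, weights = igraph::E(net)$weight)
      igraph::membership(cl)
    })
    q <- igraph::modularity(net, memb, weights = igraph::E(net)$weight)
  }
  net <- igraph::set_vertex_attr(net, "community", value = as.integer(memb))
  igraph::set_graph_attr(net, "modularity", q)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Split a CSN into its connected part and its outliers
#'
#' Degree-0 nodes are the outliers (singletons); the rest form the "giant"
#' (connected) components kept for centrality analysis.
#'
#' @param net an igraph graph.
#' @return List with `connected` (induced subgraph on all non-isolated
#'   nodes) and `outliers` (character vector of isolated node ids).
#' @export
split_giant_outliers <- function(net) {
  deg <- igraph::degree(net)
  out_ids <- igraph::V(net)$name[deg == 0]
  sub <- igraph::induced_subgraph(net, which(deg > 0))
  list(connected = sub, outliers = out_ids)
}

#' Scan CSN similarity thresholds
#'
#' Builds one CSN per threshold and collects its global metrics; used to pick
#' the working threshold by trading off density, modularity, ACC and the
#' outlier count. Communities are detected at each threshold with the given
#' seed.
#'
#' @param descriptor_matrix normalized descriptor matrix.
#' @param t_values thresholds (default the 17-value grid 0.10-0.90 by 0.05).
#' @param rng_seed Louvain seed.
#' @return Data frame with column `t` followed by the [network_metrics()]
#'   columns, one row per threshold.
#' @export
threshold_scan <- function(descriptor_matrix,
                           t_values = seq(0.10, 0.90, by = 0.05),
                           rng_seed = 42L) {
  if (!length(t_values)) stop("t_values must be non-empty")
  rows <- lapply(t_values, function(t) {
    net <- detect_communities(build_csn(descriptor_matrix, t), rng_seed)
    cbind(t = t, network_metrics(net))
  })
  do.call(rbind, rows)
}

#' Export a CSN to GraphML
#'
#' Writes node ids, the `community` attribute when present, and edge weights;
#' the file re-imports losslessly with [import_graphml()].
#'
#' @param net an igraph graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  cl <- class(net)
  class(net) <- "igraph"
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
import_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
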