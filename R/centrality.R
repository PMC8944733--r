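#' Node centrality of a CSN
#'
#' The four measures used to rank THPs within the connected component of the
#' CSN:
#' \describe{
#'   \item{weighted_degree}{sum of incident edge weights (similarity
#'     strength).}
#'   \item{harmonic}{\eqn{\sum_{v \ne u} 1/d(u,v)} over unweighted
#'     shortest-path hop distances; unreachable pairs contribute 0.}
#'   \item{betweenness}{standard unweighted shortest-path betweenness.}
#'   \item{community_hub_bridge}{\eqn{|C(u)| k_{intra}(u) + NNC(u)
#'     k_{inter}(u)}: community size times intra-community degree plus the
#'     number of distinct neighboring communities times inter-community
#'     degree. Requires community labels (see [detect_communities()]).}
#' }
#' Raw scores are min-max normalized to \[0, 1\] over the input graph
#' (constant scores map to 0).
#'
#' @param net an igraph graph; for `community_hub_bridge` it must carry a
#'   `community` vertex attribute unless `membership` is given.
#' @param measure one of `"weighted_degree"`, `"harmonic"`, `"betweenness"`,
#'   `"community_hub_bridge"`.
#' @param membership optional integer community labels overriding the vertex
#'   attribute.
#' @return Data frame of class `centrality_table` with columns `id`, `raw`,
#'   `normalized` and attribute `measure`.
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C)
#' igraph::E(g)$weight <- 1
#' compute_centrality(g, "harmonic")
#' @export
compute_centrality <- function(net,
                               measure = c("weighted_degree", "harmonic",
                                           "betweenness",
                                           "community_hub_bridge"),
                               membership = NULL) {
  measure <- match.arg(measure)
  if (igraph::vcount(net) == 0) stop("empty network")
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(net))
  raw <- switch(measure,
    weighted_degree = igraph::strength(net, weights = w),
    harmonic = igraph::harmonic_centrality(net, weights = NA,
                                           normalized = FALSE),
    betweenness = igraph::betweenness(net, weights = NA),
    community_hub_bridge = {
      if (is.null(membership))
        membership <- igraph::vertex_attr(net, "community")
      if (is.null(membership))
        stop("community_hub_bridge requires community labels")
      .hub_bridge(net, as.integer(membership))
    })
  ids <- igraph::V(net)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(net)))
  rng <- range(raw)
  normalized <- if (rng[1] == rng[2]) rep(0, length(raw))
                else (raw - rng[1]) / (rng[2] - rng[1])
  out <- data.frame(id = ids, raw = as.numeric(raw),
                    normalized = normalized, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "measure") <- measure
  class(out) <- c("centrality_table", "data.frame")
  out
}

# community hub-bridge: |C(u)| * k_intra(u) + NNC(u) * k_inter(u)
.hub_bridge <- function(net, membership) {
  n <- igraph::vcount(net)
  csize <- table(membership)
  vapply(seq_len(n), function(u) {
    nb <- as.integer(igraph::neighbors(net, u))
    if (!length(nb)) return(0)
    same <- membership[nb] == membership[u]
    k_intra <- sum(same)
    k_inter <- sum(!same)
    nnc <- length(unique(membership[nb][!same]))
    as.numeric(csize[[as.character(membership[u])]]) * k_intra + nnc * k_inter
  }, numeric(1))
}

#' Rank nodes by centrality
#'
#' Descending by normalized score; ties broken lexicographically by id.
#'
#' @param table a `centrality_table` from [compute_centrality()].
#' @return Character vector of node ids, most central first.
#' @export
rank_nodes <- function(table) {
  stopifnot(inherits(table, "centrality_table"))
  table$id[order(-table$normalized, table$id)]
}
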