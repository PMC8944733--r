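make_descmat <- function(coords, ids = NULL) {
  m <- as.matrix(coords)
  rownames(m) <- if (is.null(ids)) paste0("n", seq_len(nrow(m))) else ids
  attr(m, "normalized") <- TRUE
  m
}

test_that("CSN edges come from min-max normalized Euclidean similarity", {
  # 4 points in the plane: two tight pairs far apart -> two 2-cliques
  m <- make_descmat(rbind(c(0, 0), c(0, 0.1), c(1, 1), c(1, 0.9)))
  net <- build_csn(m, t = 0.8)
  expect_equal(igraph::vcount(net), 4)
  adj <- adj_of(net)
  expect_equal(unname(adj),
               rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                     c(0, 0, 0, 1), c(0, 0, 1, 0)))
  # hand computation: dist range is [0.1, sqrt(2)]; the 0.1-pairs map to
  # similarity 1, everything else below 0.8
  expect_equal(sort(igraph::E(net)$weight), c(1, 1))

  # t = 0 -> complete graph; t = 1 -> only globally-closest pairs
  expect_equal(igraph::ecount(build_csn(m, 0)), 6)
  expect_equal(igraph::ecount(build_csn(m, 1)), 2)
  expect_error(build_csn(m[1, , drop = FALSE], 0.5), "at least 2")
  raw <- m; attr(raw, "normalized") <- FALSE
  expect_error(build_csn(raw, 0.5), "normalized")
})

test_that("network metrics match closed forms at small and benchmark scale", {
  k4 <- graph_from_adj(matrix(1, 4, 4) - diag(4))
  mm <- network_metrics(k4)
  expect_equal(mm$density, 1)
  expect_equal(mm$average_clustering_coefficient, 1)
  expect_equal(mm$diameter, 1)
  expect_equal(mm$n_triangles, 4)

  p3 <- graph_from_adj(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  mp <- network_metrics(p3)
  expect_equal(mp$density, 2 / 3)
  expect_equal(mp$average_clustering_coefficient, 0)
  expect_equal(mp$diameter, 2)

  # average degree at the connected-component scale of the THP network
  expect_equal(round(2 * 4452 / 528, 3), 16.864)
})

test_that("density, ACC and diameter agree with brute force on small graphs", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    adj <- random_graph_adj(n, p = 0.5)
    g <- graph_from_adj(adj)
    mm <- network_metrics(g)
    expect_equal(mm$density, oracle_density(adj))
    expect_equal(mm$average_clustering_coefficient, mean(oracle_local_cc(adj)))
    expect_equal(mm$n_singletons, sum(rowSums(adj) == 0))
    d <- oracle_hop_dist(adj)
    comp <- igraph::components(g)
    giant <- which(comp$membership == which.max(comp$csize))
    dg <- d[giant, giant, drop = FALSE]
    if (sum(adj[giant, giant]) > 0)
      expect_equal(mm$diameter, max(dg[is.finite(dg)]))
  }
})

test_that("Louvain communities recover planted structure", {
  # two 5-cliques joined by a single bridge
  adj <- matrix(0, 10, 10)
  adj[1:5, 1:5] <- 1; adj[6:10, 6:10] <- 1
  diag(adj) <- 0
  adj[5, 6] <- adj[6, 5] <- 1
  g <- detect_communities(graph_from_adj(adj), rng_seed = 1)
  memb <- igraph::vertex_attr(g, "community")
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:5])), 1)
  expect_equal(length(unique(memb[6:10])), 1)
  q <- igraph::graph_attr(g, "modularity")
  expect_gt(q, 0.3)
  expect_equal(q, oracle_modularity(adj, memb))

  # disjoint union of 3 triangles: closed-form modularity 2/3
  tri <- matrix(0, 9, 9)
  for (b in c(0, 3, 6)) tri[b + 1:3, b + 1:3] <- 1
  diag(tri) <- 0
  gt <- detect_communities(graph_from_adj(tri), rng_seed = 1)
  expect_equal(length(unique(igraph::vertex_attr(gt, "community"))), 3)
  expect_equal(igraph::graph_attr(gt, "modularity"), 2 / 3)

  # complete graph: a single community, modularity <= 0
  k5 <- detect_communities(graph_from_adj(matrix(1, 5, 5) - diag(5)), 1)
  expect_equal(length(unique(igraph::vertex_attr(k5, "community"))), 1)
  expect_lte(igraph::graph_attr(k5, "modularity"), 0)

  # edgeless graph: one community per node, modularity 0
  g0 <- detect_communities(graph_from_adj(matrix(0, 4, 4)), 1)
  expect_equal(length(unique(igraph::vertex_attr(g0, "community"))), 4)
  expect_equal(igraph::graph_attr(g0, "modularity"), 0)

  # determinism under a fixed seed
  m1 <- igraph::vertex_attr(detect_communities(graph_from_adj(adj), 7), "community")
  m2 <- igraph::vertex_attr(detect_communities(graph_from_adj(adj), 7), "community")
  expect_identical(m1, m2)
})

test_that("giant/outlier split isolates exactly the degree-0 nodes", {
  adj <- matrix(0, 5, 5)
  adj[1:3, 1:3] <- 1; diag(adj) <- 0  # K3 plus 2 isolated nodes
  parts <- split_giant_outliers(graph_from_adj(adj))
  expect_equal(sort(parts$outliers), c("4", "5"))
  expect_equal(igraph::vcount(parts$connected), 3)
  expect_equal(igraph::ecount(parts$connected), 3)

  all_iso <- split_giant_outliers(graph_from_adj(matrix(0, 3, 3)))
  expect_equal(length(all_iso$outliers), 3)
  expect_equal(igraph::vcount(all_iso$connected), 0)
})

test_that("the threshold scan is anti-monotone in edges and density", {
  set.seed(73)
  ps <- peptide_set(paste0("r", 1:30), random_peptides(30, c(6, 20)))
  dm <- minmax_normalize(peptide_descriptors(ps))
  scan <- threshold_scan(dm)
  expect_equal(nrow(scan), 17)
  expect_equal(scan$t, seq(0.10, 0.90, by = 0.05))
  expect_true(all(diff(scan$n_edges) <= 0))
  expect_true(all(diff(scan$density) <= 0))
  # one threshold equals a direct metrics call
  one <- threshold_scan(dm, t_values = 0.5)
  direct <- network_metrics(detect_communities(build_csn(dm, 0.5), 42L))
  expect_equal(one$n_edges, direct$n_edges)
  expect_equal(one$density, direct$density)
})

test_that("GraphML export round-trips nodes, edges, weights and communities", {
  m <- make_descmat(rbind(c(0, 0), c(0, 0.2), c(0.9, 1), c(1, 1), c(0.5, 0.5)))
  net <- detect_communities(build_csn(m, 0.5), 1)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, f)
  back <- import_graphml(f)
  expect_equal(sort(igraph::V(back)$name), sort(igraph::V(net)$name))
  eo <- igraph::as_data_frame(net, "edges")
  eb <- igraph::as_data_frame(back, "edges")
  key <- function(d) {
    pair <- t(apply(d[, 1:2], 1, sort))
    ord <- order(pair[, 1], pair[, 2])
    list(pair = pair[ord, , drop = FALSE], w = d$weight[ord])
  }
  expect_equal(key(eb)$pair, key(eo)$pair)
  expect_equal(key(eb)$w, key(eo)$w)
  expect_equal(igraph::vertex_attr(back, "community")[
                 match(igraph::V(net)$name, igraph::V(back)$name)],
               igraph::vertex_attr(net, "community"))
})
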