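# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive everything from first principles in plain R
# and never call the code paths they verify.

.blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# --- alignment oracles ------------------------------------------------------

# Gotoh three-state dynamic programme transcribed directly from the recursion,
# with the same conventions as the package: gap of length L costs
# gap_open + L * gap_ext; local traceback starts at the best M cell (lowest
# (i, j) on ties), stops at the first zero, prefers diagonal > vertical >
# horizontal. Returns score, identical columns and aligned columns.
oracle_align <- function(a, b, gap_open = 10, gap_ext = 1, local = TRUE,
                         sub = .blosum62) {
  # canonical pair order (shorter first, lexicographic on ties) so the
  # reported identity is symmetric in spite of traceback tie-breaks
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  if (local) {
    M[, 1] <- 0; M[1, ] <- 0
  } else {
    Ix[-1, 1] <- -(gap_open + gap_ext * seq_len(n))
    Iy[1, -1] <- -(gap_open + gap_ext * seq_len(m))
  }
  gi <- gap_open + gap_ext
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- sub[av[i], bv[j]]
    prev <- max(M[i, j], Ix[i, j], Iy[i, j])
    mm <- if (prev > NEG / 2) prev + s else NEG
    M[i + 1, j + 1] <- if (local) max(0, mm) else mm
    Ix[i + 1, j + 1] <- max(if (M[i, j + 1] > NEG / 2) M[i, j + 1] - gi else NEG,
                            if (Ix[i, j + 1] > NEG / 2) Ix[i, j + 1] - gap_ext else NEG)
    Iy[i + 1, j + 1] <- max(if (M[i + 1, j] > NEG / 2) M[i + 1, j] - gi else NEG,
                            if (Iy[i + 1, j] > NEG / 2) Iy[i + 1, j] - gap_ext else NEG)
  }
  if (local) {
    best <- max(M)
    if (best <= 0) return(list(score = 0, n_id = 0L, aln_len = 0L))
    # lowest (row, col) among maxima
    hits <- which(M == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    state <- 1L
    score <- best
  } else {
    fin <- c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
    score <- max(fin)
    state <- which.max(fin)  # prefers M, then Ix, then Iy on ties
    i <- n + 1; j <- m + 1
  }
  n_id <- 0L; alen <- 0L
  while (i > 1 || j > 1) {
    if (state == 1L) {
      s <- sub[av[i - 1], bv[j - 1]]
      prev <- M[i, j] - s
      alen <- alen + 1L
      if (av[i - 1] == bv[j - 1]) n_id <- n_id + 1L
      i <- i - 1; j <- j - 1
      if (local && prev == 0) break
      state <- if (M[i, j] > NEG / 2 && M[i, j] == prev) 1L
               else if (Ix[i, j] > NEG / 2 && Ix[i, j] == prev) 2L else 3L
    } else if (state == 2L) {
      alen <- alen + 1L
      state <- if (M[i - 1, j] > NEG / 2 && M[i - 1, j] - gi == Ix[i, j]) 1L else 2L
      i <- i - 1
    } else {
      alen <- alen + 1L
      state <- if (M[i, j - 1] > NEG / 2 && M[i, j - 1] - gi == Iy[i, j]) 1L else 3L
      j <- j - 1
    }
  }
  list(score = score, n_id = n_id, aln_len = alen)
}

oracle_identity <- function(a, b, normalization = "shortest", ...) {
  r <- oracle_align(a, b, ...)
  if (normalization == "shortest") r$n_id / min(nchar(a), nchar(b))
  else if (r$aln_len > 0) r$n_id / r$aln_len else 0
}

# Exhaustive enumeration of every local alignment (all substring pairs, all
# gapped alignments without terminal gap columns) for very short sequences;
# returns the maximum attainable score. Independent of any DP.
oracle_enumerate_local_score <- function(a, b, gap_open = 10, gap_ext = 1,
                                         sub = .blosum62) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  score_path <- function(cols) {
    # cols: list of c(ai, bj) with 0 meaning gap; score with affine runs
    sc <- 0; run <- 0
    for (cc in cols) {
      if (cc[1] == 0 || cc[2] == 0) {
        run <- run + 1
      } else {
        if (run > 0) { sc <- sc - gap_open - gap_ext * run; run <- 0 }
        sc <- sc + sub[av[cc[1]], bv[cc[2]]]
      }
    }
    if (run > 0) sc <- sc - gap_open - gap_ext * run
    sc
  }
  best <- 0
  paths <- function(i, i2, j, j2, cols) {
    if (i > i2 && j > j2) {
      best <<- max(best, score_path(cols)); return(invisible())
    }
    if (i <= i2 && j <= j2) paths(i + 1, i2, j + 1, j2, c(cols, list(c(i, j))))
    if (i <= i2) paths(i + 1, i2, j, j2, c(cols, list(c(i, 0))))
    if (j <= j2) paths(i, i2, j + 1, j2, c(cols, list(c(0, j))))
  }
  n <- length(av); m <- length(bv)
  for (i in seq_len(n)) for (i2 in i:n)
    for (j in seq_len(m)) for (j2 in j:m)
      paths(i, i2, j, j2, list())
  best
}

# --- graph oracles ----------------------------------------------------------

# All take an adjacency matrix (0/1, symmetric, zero diagonal).

oracle_density <- function(adj) {
  n <- nrow(adj); e <- sum(adj) / 2
  if (n < 2) 0 else 2 * e / (n * (n - 1))
}

oracle_local_cc <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(u) {
    nb <- which(adj[u, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
}

oracle_hop_dist <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf); diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_harmonic <- function(adj) {
  d <- oracle_hop_dist(adj)
  vapply(seq_len(nrow(adj)), function(u) {
    x <- d[u, -u]
    sum(1 / x[is.finite(x) & x > 0])
  }, numeric(1))
}

# betweenness by enumerating all shortest paths (tiny graphs only)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_hop_dist(adj)
  # count shortest paths via DP on hop distance
  nsp <- function(s, t) {
    if (s == t) return(1)
    if (!is.finite(d[s, t])) return(0)
    preds <- which(adj[, t] > 0 & d[s, ] == d[s, t] - 1)
    sum(vapply(preds, function(p) nsp(s, p), numeric(1)))
  }
  nsp_through <- function(s, t, v) {
    if (!is.finite(d[s, t]) || !is.finite(d[s, v]) || !is.finite(d[v, t]))
      return(0)
    if (d[s, v] + d[v, t] != d[s, t]) return(0)
    nsp(s, v) * nsp(v, t)
  }
  vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n))
      if (s < t && s != v && t != v) {
        den <- nsp(s, t)
        if (den > 0) tot <- tot + nsp_through(s, t, v) / den
      }
    tot
  }, numeric(1))
}

oracle_hub_bridge <- function(adj, membership) {
  n <- nrow(adj)
  vapply(seq_len(n), function(u) {
    nb <- which(adj[u, ] > 0)
    if (!length(nb)) return(0)
    same <- membership[nb] == membership[u]
    sum(membership == membership[u]) * sum(same) +
      length(unique(membership[nb][!same])) * sum(!same)
  }, numeric(1))
}

# weighted Newman modularity of a partition from first principles
oracle_modularity <- function(adj_w, membership) {
  m2 <- sum(adj_w)  # 2m for weighted graphs
  if (m2 == 0) return(0)
  k <- rowSums(adj_w)
  q <- 0
  n <- nrow(adj_w)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[i] == membership[j])
      q <- q + adj_w[i, j] - k[i] * k[j] / m2
  q / m2
}

# --- metrics oracle ---------------------------------------------------------

oracle_metrics <- function(TP, TN, FP, FN) {
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  tot <- TP + TN + FP + FN
  ac <- (TP + TN) / tot
  pc <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / tot^2
  list(Ac = ac,
       kappa = (ac - pc) / (1 - pc),
       Sn = TP / (TP + FN), Sp = TN / (TN + FP),
       P_pos = TP / (TP + FP), P_neg = TN / (TN + FN),
       MCC = (TP * TN - FP * FN) /
         sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)),
       FAR_percent = 100 * FP / (FP + TN))
}

# --- misc -------------------------------------------------------------------

random_peptides <- function(n, len_range = c(8, 20), seed = NULL,
                            alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  if (!is.null(seed)) set.seed(seed)
  lens <- len_range[1] +
    sample.int(len_range[2] - len_range[1] + 1, n, replace = TRUE) - 1L
  vapply(lens, function(L) paste(sample(alphabet, L, replace = TRUE),
                                 collapse = ""), character(1))
}

adj_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

random_graph_adj <- function(n, p = 0.5) {
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  adj + t(adj)
}

graph_from_adj <- function(adj, ids = NULL) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- if (is.null(ids)) as.character(seq_len(nrow(adj))) else ids
  igraph::E(g)$weight <- 1
  g
}
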