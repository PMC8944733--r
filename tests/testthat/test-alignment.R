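test_that("identity scores behave on the canonical anchor cases", {
  p <- align_params()
  expect_equal(seq_identity("ACDEFGHIK", "ACDEFGHIK")$value, 1)
  # exact fragment of a longer peptide: full-identity hit
  r <- seq_identity("CNGRC", "CNGRCGGKLA", p)
  expect_equal(r$value, 1)
  expect_equal(r$n_identities, 5L)
  expect_equal(r$alignment_length, 5L)
  # no positive-scoring local alignment under BLOSUM62
  r0 <- seq_identity("AAAA", "WWWW", p)
  expect_equal(r0$value, 0)
  expect_equal(r0$alignment_length, 0L)
  expect_error(seq_identity("", "ACD", p), "empty")
})

test_that("identity is symmetric and bounded on random pairs", {
  p <- align_params()
  set.seed(5)
  seqs <- random_peptides(30, c(4, 25))
  for (k in 1:30) {
    ab <- sample(seqs, 2)
    ia <- seq_identity(ab[1], ab[2], p)$value
    ib <- seq_identity(ab[2], ab[1], p)$value
    expect_equal(ia, ib)
    expect_gte(ia, 0); expect_lte(ia, 1)
  }
})

test_that("Smith-Waterman agrees with the independent dynamic-programming oracle", {
  p <- align_params()
  sub4 <- c("A", "C", "G", "W")  # 4-letter sub-alphabet
  set.seed(17)
  # exhaustive over all pairs up to length 2, sampled pairs up to length 8
  short <- unlist(lapply(1:2, function(L)
    apply(expand.grid(rep(list(sub4), L)), 1, paste, collapse = "")))
  pairs <- expand.grid(a = short, b = short, stringsAsFactors = FALSE)
  sampled <- data.frame(
    a = random_peptides(150, c(1, 8), alphabet = sub4),
    b = random_peptides(150, c(1, 8), alphabet = sub4))
  for (df in list(pairs, sampled)) {
    for (k in seq_len(nrow(df))) {
      got <- seq_identity(df$a[k], df$b[k], p)
      want <- oracle_align(df$a[k], df$b[k])
      expect_equal(got$score, want$score,
                   info = paste(df$a[k], df$b[k]))
      expect_equal(got$n_identities, want$n_id, info = paste(df$a[k], df$b[k]))
      expect_equal(got$alignment_length, want$aln_len,
                   info = paste(df$a[k], df$b[k]))
    }
  }
})

test_that("optimal local score matches exhaustive alignment enumeration", {
  set.seed(23)
  df <- data.frame(a = random_peptides(25, c(1, 4)),
                   b = random_peptides(25, c(1, 4)))
  for (k in seq_len(nrow(df))) {
    got <- seq_identity(df$a[k], df$b[k])$score
    expect_equal(got, oracle_enumerate_local_score(df$a[k], df$b[k]),
                 info = paste(df$a[k], df$b[k]))
  }
})

test_that("local alignment scores match Biostrings pairwiseAlignment", {
  set.seed(31)
  a <- random_peptides(40, c(4, 25))
  b <- random_peptides(40, c(4, 25))
  pa <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = .blosum62,
                                      type = "local", gapOpening = 10,
                                      gapExtension = 1)
  ours <- vapply(seq_along(a),
                 function(i) seq_identity(a[i], b[i])$score, numeric(1))
  expect_equal(ours, Biostrings::score(pa))
})

test_that("identity matrices are symmetric with unit diagonal and match per-pair calls", {
  p <- align_params()
  ps <- peptide_set("solo", "CNGRC")
  expect_equal(identity_matrix(ps, p), matrix(1, 1, 1,
               dimnames = list("solo", "solo")))
  two <- peptide_set(c("a", "b"), c("KLAKLAK", "KLAKLAK"))
  expect_equal(unname(identity_matrix(two, p)), matrix(1, 2, 2))

  set.seed(41)
  ps5 <- peptide_set(paste0("r", 1:5), random_peptides(5, c(10, 10)))
  m <- identity_matrix(ps5, p)
  expect_equal(m, t(m))
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    expect_equal(m[i, j],
                 oracle_identity(ps5$sequence[i], ps5$sequence[j]))
  }
})

test_that("global mode recovers end-to-end identity", {
  p <- align_params(mode = "global", normalization = "alignment")
  r <- seq_identity("CNGRC", "CNGRV", p)
  expect_equal(r$alignment_length, 5L)
  expect_equal(r$value, 4 / 5)
  # global score cross-check against Biostrings
  set.seed(43)
  a <- random_peptides(20, c(5, 15)); b <- random_peptides(20, c(5, 15))
  pa <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = .blosum62,
                                      type = "global", gapOpening = 10,
                                      gapExtension = 1)
  ours <- vapply(seq_along(a),
                 function(i) seq_identity(a[i], b[i], p)$score, numeric(1))
  expect_equal(ours, Biostrings::score(pa))
})

test_that("redundancy filter removes near-duplicates greedily", {
  p <- align_params()
  dup <- peptide_set(c("x1", "x2"), c("KLAKLAKKLAK", "KLAKLAKKLAK"))
  expect_equal(redundancy_filter(dup, 0.98, p)$id, "x1")
  # cutoff 1 removes only exact full-identity duplicates
  expect_equal(redundancy_filter(dup, 1, p)$id, "x1")
  near <- peptide_set(c("y1", "y2"), c("KLAKLAKKLAK", "KLAKLAKKLAG"))
  expect_equal(nrow(redundancy_filter(near, 1, p)), 2L)

  # planted family: 10 single-substitution mutants of a 60-mer seed (mutual
  # identity to the seed 59/60 > 0.98) + 3 unrelated peptides at cutoff
  # 0.98 -> one family representative survives
  set.seed(47)
  seed60 <- strsplit(random_peptides(1, c(60, 60)), "")[[1]]
  fam <- vapply(1:10, function(i) {
    mut <- seed60
    if (i > 1) {
      pos <- sample(30, 1) + 10  # keep the substitution internal
      mut[pos] <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                 mut[pos]), 1)
    }
    paste(mut, collapse = "")
  }, character(1))
  unrelated <- c("WWWPPPWWWGGG", "CCCNNNRRRCCC", "HHHMMMQQQHHH")
  ps <- peptide_set(c(sprintf("f%02d", 1:10), paste0("u", 1:3)),
                    c(fam, unrelated))
  kept <- redundancy_filter(ps, 0.98, p)
  expect_equal(kept$id, c("f01", paste0("u", 1:3)))
  m <- identity_matrix(kept, p)
  expect_true(all(m[upper.tri(m)] <= 0.98))

  # priority order overrides input order
  kept2 <- redundancy_filter(dup, 0.98, p, priority = c(0, 1))
  expect_equal(kept2$id, "x2")
})

test_that("redundancy filter output is anti-monotone in the cutoff", {
  p <- align_params()
  set.seed(53)
  ps <- peptide_set(paste0("r", 1:25), random_peptides(25, c(6, 15)))
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0),
                  function(ct) nrow(redundancy_filter(ps, ct, p)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})
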