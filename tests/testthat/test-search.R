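simple_model <- function(queries, theta = 0.6, ...) {
  build_query_model("test", list(queries), theta = theta, ...)
}

test_that("fused scores are the MAX-SIM over the query set", {
  qs <- peptide_set(c("q1", "q2"), c("CNGRCDGWHE", "KLAKLAKKLA"))
  model <- simple_model(qs)
  # a target identical to a query fuses to 1 with that query as best
  hits <- fused_scores(model, peptide_set("t", "KLAKLAKKLA"))
  expect_equal(hits$fused_score, 1)
  expect_equal(hits$best_query_id, "q2")
  expect_error(fused_scores(model, peptide_set(character(0), character(0))),
               "empty")

  # oracle equivalence on random fixtures: fused = row max of the full
  # target x query identity matrix
  set.seed(97)
  targets <- peptide_set(paste0("t", 1:20), random_peptides(20, c(6, 18)))
  queries <- peptide_set(paste0("q", 1:5), random_peptides(5, c(6, 18)))
  model2 <- simple_model(queries)
  hits2 <- fused_scores(model2, targets)
  full <- sapply(queries$sequence, function(q)
    vapply(targets$sequence, function(t) oracle_identity(t, q), numeric(1)))
  expect_equal(hits2$fused_score, unname(apply(full, 1, max)))
  expect_equal(hits2$best_query_id,
               queries$id[apply(full, 1, which.max)])
})

test_that("adding a query never decreases a fused score", {
  set.seed(101)
  targets <- peptide_set(paste0("t", 1:15), random_peptides(15, c(6, 15)))
  qs <- random_peptides(4, c(6, 15))
  f3 <- fused_scores(simple_model(peptide_set(paste0("q", 1:3), qs[1:3])),
                     targets)$fused_score
  f4 <- fused_scores(simple_model(peptide_set(paste0("q", 1:4), qs)),
                     targets)$fused_score
  expect_true(all(f4 >= f3))
})

test_that("classification uses the inclusive threshold boundary", {
  hits <- structure(
    data.frame(target_id = c("a", "b", "c"),
               fused_score = c(0.60, 0.59, 0.61),
               best_query_id = "q"),
    class = c("search_hits", "data.frame"))
  out <- classify_hits(hits, 0.60)
  expect_equal(as.character(out$predicted),
               c("positive", "negative", "positive"))
  expect_equal(as.character(classify_hits(hits, 0)$predicted),
               rep("positive", 3))
  # positive count anti-monotone in theta
  set.seed(103)
  targets <- peptide_set(paste0("t", 1:25), random_peptides(25, c(6, 15)))
  model <- simple_model(peptide_set(paste0("q", 1:5),
                                    random_peptides(5, c(6, 15))))
  sc <- fused_scores(model, targets)
  npos <- vapply(c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9), function(th)
    sum(classify_hits(sc, th)$predicted == "positive"), numeric(1))
  expect_true(all(diff(npos) <= 0))
})

test_that("prospective screening runs the staged funnel", {
  set.seed(107)
  queries <- peptide_set(paste0("q", 1:3),
                         c("CNGRCDGWHEKL", "KLAKLAKKLAKL", "WGHQTRMNPSDE"))
  model <- simple_model(queries, theta = 0.6)
  # planted database: 5 near-query mutants, 3 exact query copies, unrelated
  # bulk, a too-long peptide and a tagged known active
  near <- vapply(1:5, function(i) {
    s <- strsplit(queries$sequence[(i %% 3) + 1], "")[[1]]
    pos <- sample(12, 2)
    for (p in pos) s[p] <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                   "")[[1]], s[p]), 1)
    paste(s, collapse = "")
  }, character(1))
  exact <- queries$sequence
  unrelated <- random_peptides(50, c(8, 20))
  db <- peptide_set(
    c(paste0("near", 1:5), paste0("copy", 1:3), paste0("u", 1:50),
      "toolong", "known"),
    c(near, exact, unrelated, strrep("A", 30), "CNGRCDGWHEKL"),
    annotations = c(rep(list(character(0)), 58),
                    list(character(0), "Tumor Homing")))
  hits <- prospective_screen(db, model)
  log <- attr(hits, "stage_log")
  expect_equal(log$stage, c("length_tag_filter", "redundancy_filter",
                            "similarity_search", "drop_perfect_matches"))
  expect_equal(log$n_in[1], 60)
  expect_equal(log$n_out[1], 58)  # too-long and tagged records gone
  # the near-query mutants survive; exact copies die at the score-1 rule
  expect_true(all(paste0("near", 1:5) %in% hits$target_id))
  expect_false(any(paste0("copy", 1:3) %in% hits$target_id))
  expect_true(all(round(hits$fused_score, 6) != 1))
  expect_true(all(hits$fused_score >= 0.6))
  # ranked by decreasing fused score
  expect_true(all(diff(hits$fused_score) <= 0))
  # with drop_perfect off the copies rank on top
  hits2 <- prospective_screen(db, model, drop_perfect = FALSE)
  expect_true(all(paste0("copy", 1:3) %in% hits2$target_id))
  expect_equal(nrow(hits2), nrow(hits) + 3)

  # everything filtered out at stage 1 -> empty result with a stage report
  tall <- peptide_set(c("a", "b"), c(strrep("K", 30), strrep("L", 40)))
  empty <- prospective_screen(tall, model)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "stage_log")$n_out[1], 0)
})

test_that("nearest known neighbors reports attached reference nodes", {
  set.seed(109)
  ref <- peptide_set(paste0("ref", 1:6),
                     c("KLAKLAKKLAKL", "KLAKLAKKLAKV", "CNGRCDGWHEKL",
                       "CNGRCDGWHEKV", "WGHQTRMNPSDE", "GGSSGGTTGGAA"))
  # a hit identical in descriptors to ref1 must have it as neighbor 1 at
  # similarity 1
  hits <- peptide_set(c("h1", "h2", "h3"),
                      c("KLAKLAKKLAKL", "KLAKLAKKLALK", "PPPPWWWWHHHH"))
  nb <- nearest_known_neighbors(hits, ref, t = 0.6, k = 3)
  h1 <- nb[nb$hit_id == "h1", ]
  expect_equal(h1$neighbor_id[1], "ref1")
  expect_equal(h1$similarity[1], 1)
  expect_lte(max(table(nb$hit_id)), 3)
  # two hits engineered to share >= 2 neighbors are flagged
  flagged <- attr(nb, "flagged")
  expect_true(any(vapply(flagged, function(p)
    setequal(p, c("h1", "h2")), logical(1))))
})
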