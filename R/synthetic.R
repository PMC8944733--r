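# uniform draw from an inclusive integer range (safe for degenerate ranges)
.sample_range <- function(rng) {
  rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
}

#' Specification for a synthetic peptide-family dataset
#'
#' Describes a seeded synthetic dataset emulating the structure of a curated
#' bioactive-peptide pool: a handful of sequence families (each grown from a
#' seed peptide carrying a short conserved motif, diversified by random
#' point substitutions) plus unrelated random background peptides. Used to
#' exercise every pipeline stage without external data.
#'
#' Defaults reflect a realistic THP-like pool: 6 families of 15 members,
#' lengths 10-25 residues (the working screening band), a 5 percent
#' per-position substitution rate (members stay well above the 60 percent
#' identity working threshold of the search), and 30 unrelated peptides.
#'
#' @param n_families number of families.
#' @param family_size members per family.
#' @param seed_motifs optional character vector of one motif per family;
#'   random 5-mers are drawn when `NULL`.
#' @param length_range two-element integer range of sequence lengths.
#' @param substitution_rate per-position substitution probability in
#'   \[0, 1).
#' @param n_unrelated number of unrelated random peptides.
#' @param rng_seed integer seed; identical specs and seeds give byte-identical
#'   outputs.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_families = 6L, family_size = 15L,
                           seed_motifs = NULL, length_range = c(10L, 25L),
                           substitution_rate = 0.05, n_unrelated = 30L,
                           rng_seed = 42L) {
  if (substitution_rate < 0 || substitution_rate >= 1)
    stop("substitution_rate must be in [0, 1)")
  if (any(c(n_families, family_size, n_unrelated) < 0))
    stop("counts must be non-negative")
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 1)
    stop("invalid length_range")
  if (!is.null(seed_motifs) && length(seed_motifs) != n_families)
    stop("need one seed motif per family")
  structure(list(n_families = as.integer(n_families),
                 family_size = as.integer(family_size),
                 seed_motifs = seed_motifs,
                 length_range = as.integer(length_range),
                 substitution_rate = substitution_rate,
                 n_unrelated = as.integer(n_unrelated),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Generate the synthetic peptide families
#'
#' @param spec a [synthetic_spec()].
#' @return List with `records` (a `peptide_set`) and `family` (character
#'   vector: `"family<i>"` per member, `"unrelated"` for background
#'   peptides), plus `motifs` (the motif of each family).
#' @export
generate_families <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  aa <- .canonical_aa()
  withr_seed(spec$rng_seed, {
    motifs <- spec$seed_motifs
    if (is.null(motifs) && spec$n_families > 0)
      motifs <- vapply(seq_len(spec$n_families), function(i)
        paste(sample(aa, 5, replace = TRUE), collapse = ""), character(1))
    ids <- character(0); seqs <- character(0); fam <- character(0)
    for (f in seq_len(spec$n_families)) {
      motif <- strsplit(motifs[f], "")[[1]]
      len <- max(.sample_range(spec$length_range), length(motif))
      seed <- sample(aa, len, replace = TRUE)
      pos <- .sample_range(c(1L, len - length(motif) + 1L))
      seed[pos:(pos + length(motif) - 1)] <- motif
      for (m in seq_len(spec$family_size)) {
        mut <- seed
        hit <- which(stats::runif(len) < spec$substitution_rate)
        for (p in hit) mut[p] <- sample(setdiff(aa, mut[p]), 1)
        ids <- c(ids, sprintf("fam%02d_m%02d", f, m))
        seqs <- c(seqs, paste(mut, collapse = ""))
        fam <- c(fam, sprintf("family%d", f))
      }
    }
    for (u in seq_len(spec$n_unrelated)) {
      len <- .sample_range(spec$length_range)
      ids <- c(ids, sprintf("unrel_%02d", u))
      seqs <- c(seqs, paste(sample(aa, len, replace = TRUE), collapse = ""))
      fam <- c(fam, "unrelated")
    }
    list(records = peptide_set(ids, seqs), family = fam, motifs = motifs)
  })
}

#' Build a balanced benchmark from positive peptides
#'
#' Negatives are per-sequence residue shuffles of the positives
#' (composition-preserving), so the benchmark is class-balanced and the
#' negative class cannot be separated by amino-acid composition alone.
#' Single-residue positives yield a negative identical to the positive; such
#' degenerate records are flagged.
#'
#' @param positives a `peptide_set` of positive peptides.
#' @param rng_seed integer seed.
#' @return List with `records` (positives then negatives, negatives id-ed
#'   `neg_<original id>`), `truth` (factor `"positive"`/`"negative"`), and
#'   `degenerate` (ids of negatives equal to their source).
#' @export
generate_benchmark <- function(positives, rng_seed = 42L) {
  stopifnot(inherits(positives, "peptide_set"))
  if (nrow(positives) == 0) stop("positives must be non-empty")
  withr_seed(rng_seed, {
    shuffled <- vapply(positives$sequence, function(s)
      paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1))
    neg_ids <- paste0("neg_", positives$id)
    records <- peptide_set(c(positives$id, neg_ids),
                           c(positives$sequence, shuffled))
    truth <- factor(rep(c("positive", "negative"), each = nrow(positives)),
                    levels = c("positive", "negative"))
    degenerate <- neg_ids[shuffled == positives$sequence]
    list(records = records, truth = truth, degenerate = degenerate)
  })
}

#' Split a synthetic pool into a fitting set and held-out positives
#'
#' Keeps the last `n_holdout` members of every family out of the fitting
#' pool; the held-out mutants serve as benchmark positives that the fitted
#' model has never seen, while all unrelated background peptides stay in the
#' fitting pool.
#'
#' @param fam result of [generate_families()].
#' @param n_holdout members held out per family.
#' @return List with `train` and `positives` (`peptide_set`s).
#' @export
family_holdout_split <- function(fam, n_holdout = 5L) {
  records <- fam$records
  hold <- logical(nrow(records))
  for (f in unique(fam$family[fam$family != "unrelated"])) {
    idx <- which(fam$family == f)
    hold[utils::tail(idx, n_holdout)] <- TRUE
  }
  train <- records[!hold, , drop = FALSE]
  pos <- records[hold, , drop = FALSE]
  rownames(train) <- rownames(pos) <- NULL
  list(train = train, positives = pos)
}
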