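---
title: "Methods: chemical space networks and multi-query similarity searching for peptide discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical space networks and multi-query similarity searching for peptide discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thpnet)
```

## The problem

Tumor-homing peptides (THPs) bind selectively to receptors on tumor cells or
tumor vasculature, which makes them attractive vehicles for targeted drug
delivery. Experimentally validated THPs are scarce, while curated pools of
other bioactive peptides — antimicrobial peptides (AMPs) in particular — are
large. `thpnet` implements a network-science route to repurposing: known
THPs are organized into a *chemical space network* (CSN), the most
representative, non-redundant THPs are extracted by network centrality, and
the resulting query set acts as a *similarity searching model* (SSM) — a
binary classifier that labels any candidate peptide by its maximum local
alignment identity to the queries (group fusion, MAX-SIM rule).

The model-building pipeline in `ssm_fit()` is, in order: near-duplicate
removal, descriptor computation and min–max normalization, CSN construction
at a working similarity threshold, isolation of degree-0 outliers, Louvain
community detection, centrality-ranked scaffold extraction per centrality
measure, and union of the scaffold sets with the outliers into the query set.

## The identity score

All sequence comparisons use Smith–Waterman local alignment with BLOSUM62.
Gap penalties are not prescribed by the method's sources, so the package
defaults to gap open 10 and gap extension 1 (a gap of length $L$ costs
$10 + L$), the common Smith–Waterman defaults; both are configurable through
`align_params()` and logged in every artifact.

The *identity score* of a pair is

$$ I(a, b) = \frac{\text{identical aligned columns of the optimal local alignment}}{\min(|a|, |b|)} \in [0, 1]. $$

The choice of denominator deserves comment because it is the one place where
reasonable conventions diverge sharply in behavior. Normalizing by the
aligned columns of the optimal local alignment looks natural, but for short
peptides it makes the MAX-SIM score of *unrelated* sequences saturate: some
3–5 residue exact local match almost always exists against one of a few
hundred queries, and such a match scores identity 1.0 under alignment-length
normalization. A multi-query classifier built that way labels essentially
every peptide positive at any practical threshold, which is irreconcilable
with the near-perfect specificity that retrospective validation of this
method reports on randomly generated negatives. Normalizing by the shorter
sequence length keeps the two properties that matter: a peptide recovered
exactly as a fragment of a longer one still scores 1.0 (so known motifs
embedded in longer sequences are found), and short accidental matches are
penalized in proportion to the peptide length. The package therefore
defaults to `normalization = "shortest"`; `"alignment"` remains available
as an option.

Determinism: the dynamic programme (Gotoh three-state recursion, implemented
in C++) breaks ties by a fixed rule — the local traceback starts at the
best-scoring cell with the lowest (row, column) index, stops at the first
zero, and prefers diagonal over vertical over horizontal predecessors. Since
tie-breaks could otherwise make the reported identity depend on argument
order, every pair is aligned in a canonical order (shorter sequence first,
lexicographic on ties), which makes $I$ symmetric by construction. This is
valid because substitution matrices used here are symmetric (this is
checked when parameters are constructed).

A zero-score local alignment (no positive-scoring region, e.g. poly-A vs
poly-W under BLOSUM62) has an empty optimum and identity 0.

## Descriptors and the CSN

Peptides are placed in a coordinate-free chemical space via ten
physicochemical descriptors: residue count; net charge at pH 7
(Henderson–Hasselbalch over the ionizable groups with the Lehninger pKa
table, termini included); isoelectric point (bisection of the charge curve
to $|q| < 10^{-4}$); average molecular weight (standard residue masses plus
one water, Da); Boman index (mean residue solubility value, kcal/mol);
Eisenberg hydrophobic moment at the 100° α-helical angle; Hopp–Woods mean
hydrophilicity; hydrophobic periodicity (amplitude of the mean-centered
Eisenberg profile's Fourier component at 100°, normalized by the total
absolute centered signal); Ikai aliphatic index; and the Guruprasad
instability index (DIWV dipeptide weights). The formulas are the published
ones and the scales ship inside the package; descriptor-level parity with
any particular desktop tool is deliberately not claimed, which is why
node/edge counts of networks built from externally curated data are treated
as soft targets only. The descriptor set is selectable per call
(`peptide_descriptors(records, descriptors = ...)`).

Each descriptor column is min–max normalized to $[0,1]$; a constant column
carries no distance information and maps to zero. Euclidean distances
between normalized descriptor rows are themselves min–max normalized over
all unordered pairs of the input set, and similarity is one minus that.
This makes similarity *dataset-relative*: the same two peptides can have
different similarities inside different pools. That is intrinsic to the
min–max construction and is documented rather than hidden; all artifacts
record the provenance of the set they were computed on.

The CSN at threshold $t$ connects every pair with similarity $\ge t$. The
default working threshold is 0.60, chosen where density, modularity,
clustering and the outlier count trade off best in threshold scans
(`threshold_scan()` reproduces the 17-point grid 0.10–0.90 by 0.05).
Conventions for the reported metrics: density is computed on the full node
set including isolated nodes; the average clustering coefficient is the mean
local coefficient with degree < 2 nodes contributing 0; diameter and average
path length are unweighted hop distances on the largest connected component.
Louvain community detection optimizes weighted modularity; its randomness is
pinned by a seed (default 42) so partitions are reproducible.

## Centrality and scaffold extraction

Four node centralities are supported: weighted degree (sum of incident
similarities), harmonic and betweenness (both on unweighted hops — the
conventional default, configurable only in the sense that the measures are
independent functions), and community hub-bridge,

$$ C_{HB}(u) = |C(u)| \, k_{intra}(u) + NNC(u) \, k_{inter}(u), $$

community size times intra-community degree plus the number of distinct
neighboring communities times inter-community degree. The hub-bridge
formula is an interpretive choice: the measure is named but not defined in
the method's sources, and the definition here follows the modular-centrality
literature that the original tooling builds on. Scores are min–max
normalized over the connected subnetwork; outliers are handled separately
because singletons always have zero centrality.

Scaffold extraction is a greedy sweep in descending-centrality order (ties
lexicographic by id): a peptide is kept iff its identity to every
already-kept peptide is strictly below the cutoff. The output carries a
checkable certificate — kept pairwise identities all below the cutoff, and
every dropped peptide blocked by a kept, more central one. The "top 10%"
pruning variant (`prune_by_top_centrality()`) interprets "10% lower
centrality than the most central node" as keeping normalized centrality
$\ge 0.9 \cdot \max$; the winning model configuration does not use this
rule, so it is a secondary path.

The redundancy filter used for de-duplication (`redundancy_filter()`)
differs from scaffold extraction in two boundary details, both following the
"remove higher than X%" phrasing: identities strictly above the cutoff are
redundant, and exact full-identity duplicates are always redundant, so a
cutoff of 1 removes only exact duplicates.

## Group fusion and screening

`fused_scores()` assigns each target the maximum identity over the query
set; the arg-max query is reported with ties going to the lowest query id.
Classification is inclusive: fused score $\ge \theta$ is positive, with the
default $\theta = 0.60$. The prospective screening funnel
(`prospective_screen()`) is: length/annotation filtering (3–25 residues,
known-active and toxicity tags excluded), redundancy filtering at 0.95,
MAX-SIM search at $\theta$, and removal of perfect hits — fused scores that
equal 1 after rounding to 6 decimals, a floating-point guard at an
exact-match boundary. Every stage logs its in/out counts. Removal of
literature-known actives is implemented as an annotation-tag exclusion, not
a literature lookup. The "visual mining" step
(`nearest_known_neighbors()`) embeds each hit into the reference CSN and
reports its up-to-3 directly attached reference neighbors by descriptor
similarity (an alignment-identity mode is not provided because neighbor
attachment is defined on the CSN); hits sharing two or more neighbors are
flagged as redundant candidates.

## Evaluation

`classification_metrics()` computes accuracy, Cohen's κ (with
$P_o = Ac$ and the chance-agreement term
$P_c = [(TP{+}FP)(TP{+}FN) + (FN{+}TN)(FP{+}TN)]/N^2$), sensitivity,
specificity, the two precisions, the Matthews correlation coefficient and
the false accept rate FAR% $= 100\,FP/(FP{+}TN)$. Degenerate conventions:
ratio statistics with an empty margin are `NA`; an MCC with a zero
denominator is 0. On balanced classes $P_c = 1/2$ exactly and
$\kappa = 2\,Ac - 1$, a useful algebraic cross-check. Display rounding is 3
decimals for proportions and 2 for percentages; machine output keeps full
precision.

`friedman_rank()` ranks methods within blocks (average ranks on ties) and
computes $\chi^2 = \frac{12}{nk(k+1)} \sum_j R_j^2 - 3n(k+1)$ with $k-1$
degrees of freedom. Post-hoc procedures are intentionally out of scope: the
exact block structure used in the original model comparison is not
recoverable, so the package exposes the test itself and leaves block design
to the analyst.

## The synthetic data generator

`synthetic_spec()` describes a pool emulating the structure that matters to
this pipeline: sequence families (a seed peptide carrying a short conserved
motif, diversified by independent per-position substitutions) plus unrelated
random background peptides. Defaults: 6 families × 15 members, lengths
10–25 residues (the working screening band; family seeds are drawn in the
upper part of this range in expectation), substitution rate 0.05 per
position — members of a family then stay well above the 0.60 identity
threshold while unrelated peptides stay below it — and 30 background
peptides. Negatives for benchmarking (`generate_benchmark()`) are
per-sequence residue shuffles of the positives: composition-preserving, so
the negative class cannot be told apart by amino-acid composition and the
descriptor space alone, making specificity a real test of the alignment
stage. `family_holdout_split()` keeps the last members of each family out
of fitting so sensitivity is measured on sequences the model never saw.

What the generator does *not* emulate: the length and composition biases of
real curated peptide databases, annotation noise, family-size imbalance, and
homology structure between families. Passing the planted-family recovery
test therefore demonstrates that the pipeline machinery is correct — not
that any particular external dataset will reproduce specific counts.

## Problem sizes and budgets

The test suite exercises alignment oracles on exhaustive small alphabets
(all pairs up to length 2 over a 4-letter alphabet, plus a few hundred
sampled pairs up to length 8), graph oracles on all-pairs brute force over
graphs of up to 6 nodes, a 1000-matrix metrics cross-check, and end-to-end
pipelines on pools of about 100–120 peptides. These sizes were chosen so
each property is checked densely where exhaustive checking is feasible and
by seeded sampling where it is not.

## Known limitations

* Similarity is dataset-relative (min–max over the current pool), so models
  fitted on different pools are not directly comparable on the similarity
  scale, only on the identity scale.
* The hub-bridge centrality definition is an interpretation (see above).
* Descriptor parity with external desktop tools is not claimed; network
  node/edge counts on externally curated data are soft targets.
* Exact Smith–Waterman is quadratic per pair; the package targets peptide
  pools (thousands of sequences), not proteome-scale screening.
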