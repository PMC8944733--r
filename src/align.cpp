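#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state recursion) for short
// peptides, local (Smith-Waterman) or global (Needleman-Wunsch) mode.
//
// A gap of length L costs gap_open + L * gap_ext.  Scores are integer-valued
// in practice (BLOSUM62 + integer penalties) so exact equality comparisons in
// the traceback are safe.
//
// Determinism: the local traceback starts at the best-scoring M cell (lowest
// (row, column) on ties), stops at the first zero (shortest optimal
// alignment), and among equal-scoring predecessors prefers
// diagonal > vertical (gap in b) > horizontal (gap in a).

static const double NEG_INF = -1e18;

struct AlnResult {
  double score;
  int n_id;      // identical aligned columns
  int aln_len;   // aligned columns incl. gap columns
};

// sequences as raw chars 'A'..'Z'; sub = 26x26 lookup indexed by char - 'A'.
// The pair is put in canonical order (shorter first, lexicographic on ties)
// before aligning so that traceback tie-breaks cannot make the reported
// identity asymmetric.
static AlnResult align_pair(std::string a, std::string b,
                            const NumericMatrix& sub,
                            double gap_open, double gap_ext, bool local) {
  if (a.size() > b.size() || (a.size() == b.size() && a > b)) std::swap(a, b);
  const int n = a.size(), m = b.size();
  const double gi = gap_open + gap_ext;  // cost of a length-1 gap
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix(M), Iy(M);  // Ix: gap in b (consumes a); Iy: gap in a
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  if (local) {
    for (int i = 1; i <= n; ++i) M[at(i, 0)] = 0.0;
    for (int j = 1; j <= m; ++j) M[at(0, j)] = 0.0;
  } else {
    for (int i = 1; i <= n; ++i) Ix[at(i, 0)] = -(gap_open + gap_ext * i);
    for (int j = 1; j <= m; ++j) Iy[at(0, j)] = -(gap_open + gap_ext * j);
  }

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = sub(a[i - 1] - 'A', b[j - 1] - 'A');
      const double prev = std::max(M[at(i - 1, j - 1)],
                                   std::max(Ix[at(i - 1, j - 1)],
                                            Iy[at(i - 1, j - 1)]));
      double mm = (prev > NEG_INF / 2) ? prev + s : NEG_INF;
      if (local && mm < 0.0) mm = 0.0;
      M[at(i, j)] = mm;

      const double ox = (M[at(i - 1, j)] > NEG_INF / 2) ? M[at(i - 1, j)] - gi : NEG_INF;
      const double ex = (Ix[at(i - 1, j)] > NEG_INF / 2) ? Ix[at(i - 1, j)] - gap_ext : NEG_INF;
      Ix[at(i, j)] = std::max(ox, ex);

      const double oy = (M[at(i, j - 1)] > NEG_INF / 2) ? M[at(i, j - 1)] - gi : NEG_INF;
      const double ey = (Iy[at(i, j - 1)] > NEG_INF / 2) ? Iy[at(i, j - 1)] - gap_ext : NEG_INF;
      Iy[at(i, j)] = std::max(oy, ey);

      if (local && mm > best) { best = mm; bi = i; bj = j; }
    }
  }

  AlnResult res{0.0, 0, 0};
  int i, j, state;  // 0 = M, 1 = Ix (vertical), 2 = Iy (horizontal)
  if (local) {
    res.score = best;
    if (best <= 0.0) return res;  // empty optimal alignment
    i = bi; j = bj; state = 0;
  } else {
    const double fm = M[at(n, m)], fx = Ix[at(n, m)], fy = Iy[at(n, m)];
    res.score = std::max(fm, std::max(fx, fy));
    i = n; j = m;
    state = (fm >= fx && fm >= fy) ? 0 : (fx >= fy ? 1 : 2);
  }

  while (i > 0 || j > 0) {
    if (state == 0) {
      const double s = sub(a[i - 1] - 'A', b[j - 1] - 'A');
      const double prev = M[at(i, j)] - s;
      res.aln_len++;
      if (a[i - 1] == b[j - 1]) res.n_id++;
      --i; --j;
      if (local && prev == 0.0) break;  // alignment starts with this column
      if (M[at(i, j)] > NEG_INF / 2 && M[at(i, j)] == prev) state = 0;
      else if (Ix[at(i, j)] > NEG_INF / 2 && Ix[at(i, j)] == prev) state = 1;
      else state = 2;
    } else if (state == 1) {
      res.aln_len++;
      state = (M[at(i - 1, j)] > NEG_INF / 2 &&
               M[at(i - 1, j)] - gi == Ix[at(i, j)]) ? 0 : 1;
      --i;
    } else {
      res.aln_len++;
      state = (M[at(i, j - 1)] > NEG_INF / 2 &&
               M[at(i, j - 1)] - gi == Iy[at(i, j)]) ? 0 : 2;
      --j;
    }
  }
  return res;
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
NumericVector align_pair_cpp(std::string a, std::string b, NumericMatrix sub,
                             double gap_open, double gap_ext, bool local) {
  AlnResult r = align_pair(a, b, sub, gap_open, gap_ext, local);
  return NumericVector::create(_["score"] = r.score, _["n_id"] = r.n_id,
                               _["aln_len"] = r.aln_len);
}

// All-vs-all, symmetric
// [[Rcpp::export(name = ".align_pairwise_cpp")]]
List align_pairwise_cpp(std::vector<std::string> seqs, NumericMatrix sub,
                        double gap_open, double gap_ext, bool local) {
  const int n = seqs.size();
  NumericMatrix nid(n, n), alen(n, n), score(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      AlnResult r = align_pair(seqs[i], seqs[j], sub, gap_open, gap_ext, local);
      nid(i, j) = nid(j, i) = r.n_id;
      alen(i, j) = alen(j, i) = r.aln_len;
      score(i, j) = score(j, i) = r.score;
    }
  }
  return List::create(_["n_id"] = nid, _["aln_len"] = alen, _["score"] = score);
}

// Rectangular: targets x queries
// [[Rcpp::export(name = ".align_cross_cpp")]]
List align_cross_cpp(std::vector<std::string> targets,
                     std::vector<std::string> queries, NumericMatrix sub,
                     double gap_open, double gap_ext, bool local) {
  const int n = targets.size(), m = queries.size();
  NumericMatrix nid(n, m), alen(n, m), score(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      AlnResult r = align_pair(targets[i], queries[j], sub, gap_open, gap_ext, local);
      nid(i, j) = r.n_id;
      alen(i, j) = r.aln_len;
      score(i, j) = r.score;
    }
  }
  return List::create(_["n_id"] = nid, _["aln_len"] = alen, _["score"] = score);
}
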