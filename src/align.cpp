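#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Canonical pair set used throughout: Watson-Crick plus G-T wobble.
// N (or any other character) never pairs.
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Maximum-cardinality nested base pairing (Nussinov-style DP) with a
// minimum hairpin loop of `min_loop` unpaired nucleotides.  The primary
// objective is the number of pairs; among maximum-cardinality structures
// the number of stacked adjacencies (pair (i,j) directly enclosing pair
// (i+1,j-1)) is maximised, which makes the reported structure stable for
// helical designs instead of an arbitrary member of the optimum set.
// Traceback is deterministic: the leftmost position of an interval is
// paired first, with its leftmost admissible partner.
// Values are encoded as pairs * 256 + stacks (both far below 256 for
// ITS-scale sequences, so lexicographic comparison is plain integer
// comparison and bifurcation values add without carry).
// Returns a 2-column matrix of 1-based pairs (i, j), i < j.
// [[Rcpp::export(name = ".nussinov_pairs")]]
IntegerMatrix nussinov_pairs(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  const int NEG = -1000000;
  // F[i][j]: best over the interval; P[i][j]: best with (i,j) paired.
  std::vector< std::vector<int> > F(n + 2, std::vector<int>(n + 2, 0));
  std::vector< std::vector<int> > P(n + 2, std::vector<int>(n + 2, NEG));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      if (can_pair(seq[i - 1], seq[j - 1])) {
        int inner = F[i + 1][j - 1];
        if (P[i + 1][j - 1] > NEG && P[i + 1][j - 1] + 1 > inner)
          inner = P[i + 1][j - 1] + 1;  // stacking bonus
        P[i][j] = 256 + inner;
      }
      int best = F[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (P[i][k] > NEG) {
          int v = P[i][k] + (k < j ? F[k + 1][j] : 0);
          if (v > best) best = v;
        }
      }
      F[i][j] = best;
    }
  }
  std::vector<int> pi, pj;
  // work stack of (i, j, in_P)
  struct Frame { int i, j; bool inP; };
  std::vector<Frame> stack;
  stack.push_back({1, n, false});
  while (!stack.empty()) {
    Frame fr = stack.back();
    stack.pop_back();
    int i = fr.i, j = fr.j;
    if (fr.inP) {
      pi.push_back(i); pj.push_back(j);
      int inner_target = P[i][j] - 256;
      if (P[i + 1][j - 1] > NEG && P[i + 1][j - 1] + 1 == inner_target)
        stack.push_back({i + 1, j - 1, true});
      else if (j - 1 - (i + 1) >= min_loop + 1)
        stack.push_back({i + 1, j - 1, false});
      continue;
    }
    while (j - i >= min_loop + 1 && F[i][j] > 0) {
      bool paired = false;
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (P[i][k] > NEG &&
            P[i][k] + (k < j ? F[k + 1][j] : 0) == F[i][j]) {
          stack.push_back({i, k, true});
          if (k < j) { i = k + 1; } else { i = j; }
          paired = true;
          break;
        }
      }
      if (!paired) i = i + 1;  // leave i unpaired
    }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    out(r, 0) = pi[r];
    out(r, 1) = pj[r];
  }
  return out;
}

// Global alignment of two profiles given a precomputed column-pair score
// matrix S (rows = columns of profile A, cols = columns of profile B) and a
// linear gap penalty (negative).  Deterministic tie-breaking:
// diagonal > up (gap in B) > left (gap in A).
// Returns 1-based column indices with 0 marking a gap.
// [[Rcpp::export(name = ".profile_align_path")]]
List profile_align_path(NumericMatrix S, double gap) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix D(n + 1, m + 1);
  IntegerMatrix T(n + 1, m + 1);  // 0 diag, 1 up, 2 left
  for (int i = 1; i <= n; ++i) { D(i, 0) = i * gap; T(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { D(0, j) = j * gap; T(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = D(i - 1, j - 1) + S(i - 1, j - 1);
      double u = D(i - 1, j) + gap;
      double l = D(i, j - 1) + gap;
      double best = d; int t = 0;
      if (u > best) { best = u; t = 1; }
      if (l > best) { best = l; t = 2; }
      D(i, j) = best; T(i, j) = t;
    }
  }
  std::vector<int> ai, bj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int t = (i == 0) ? 2 : (j == 0) ? 1 : T(i, j);
    if (t == 0)      { ai.push_back(i); bj.push_back(j); --i; --j; }
    else if (t == 1) { ai.push_back(i); bj.push_back(0); --i; }
    else             { ai.push_back(0); bj.push_back(j); --j; }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bj),
                      _["score"] = D(n, m));
}
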