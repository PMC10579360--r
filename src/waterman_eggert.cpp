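#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Waterman-Eggert local alignment with affine gaps (Gotoh recurrences) and
// declumping: after each reported alignment its aligned residue pairs are
// forbidden as diagonal moves and the matrix is refilled, so successive
// alignments share no residue pair.
//
// Gap cost convention: a maximal gap run of length L costs
// gapOpen + (L - 1) * gapExtend (the first gap residue pays gapOpen).

static inline bool eq(double a, double b) { return std::fabs(a - b) < 1e-6; }

// q, t: 0-based indices into the substitution matrix alphabet.
// Returns a list of alignments; qa/ta hold 1-based residue positions, 0 = gap.
// [[Rcpp::export]]
List we_align_cpp(IntegerVector q, IntegerVector t, IntegerMatrix sub,
                  double gapOpen, double gapExt, int nAlt) {
  const int m = q.size(), n = t.size();
  const double NEG = -1e18;
  std::vector<double> H((m + 1) * (n + 1)), E((m + 1) * (n + 1)),
      F((m + 1) * (n + 1));
  std::vector<char> forb((m + 1) * (n + 1), 0);
  List out(nAlt);
  int found = 0;

#define IDX(i, j) ((i) * (n + 1) + (j))

  for (int rep = 0; rep < nAlt; ++rep) {
    for (int j = 0; j <= n; ++j) { H[IDX(0, j)] = 0; E[IDX(0, j)] = NEG; F[IDX(0, j)] = NEG; }
    for (int i = 1; i <= m; ++i) {
      H[IDX(i, 0)] = 0; E[IDX(i, 0)] = NEG; F[IDX(i, 0)] = NEG;
      for (int j = 1; j <= n; ++j) {
        double e = std::max(H[IDX(i, j - 1)] - gapOpen, E[IDX(i, j - 1)] - gapExt);
        double f = std::max(H[IDX(i - 1, j)] - gapOpen, F[IDX(i - 1, j)] - gapExt);
        double d = forb[IDX(i, j)] ? NEG
                                   : H[IDX(i - 1, j - 1)] + sub(q[i - 1], t[j - 1]);
        double h = 0.0;
        if (d > h) h = d;
        if (e > h) h = e;
        if (f > h) h = f;
        E[IDX(i, j)] = e; F[IDX(i, j)] = f; H[IDX(i, j)] = h;
      }
    }

    // Best cell; ties resolved toward the earliest target column, then the
    // earliest query row, for deterministic output.
    double best = 0.0; int bi = -1, bj = -1;
    for (int j = 1; j <= n; ++j)
      for (int i = 1; i <= m; ++i)
        if (H[IDX(i, j)] > best + 1e-9) { best = H[IDX(i, j)]; bi = i; bj = j; }
    if (bi < 0) break;  // best local score is 0: no (further) alignment

    // Traceback; diagonal moves preferred over gaps, target-consuming gaps
    // over query-consuming ones.
    std::vector<int> qa, ta;
    int i = bi, j = bj;
    char state = 'H';
    while (true) {
      if (state == 'H') {
        if (H[IDX(i, j)] <= 1e-9) break;
        double d = (i > 0 && j > 0 && !forb[IDX(i, j)])
                       ? H[IDX(i - 1, j - 1)] + sub(q[i - 1], t[j - 1])
                       : NEG;
        if (eq(H[IDX(i, j)], d)) {
          qa.push_back(i); ta.push_back(j); --i; --j;
        } else if (eq(H[IDX(i, j)], E[IDX(i, j)])) {
          state = 'E';
        } else {
          state = 'F';
        }
      } else if (state == 'E') {  // gap in query, consumes target
        qa.push_back(0); ta.push_back(j);
        if (eq(E[IDX(i, j)], H[IDX(i, j - 1)] - gapOpen)) { --j; state = 'H'; }
        else --j;
      } else {                    // gap in target, consumes query
        qa.push_back(i); ta.push_back(0);
        if (eq(F[IDX(i, j)], H[IDX(i - 1, j)] - gapOpen)) { --i; state = 'H'; }
        else --i;
      }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(ta.begin(), ta.end());
    for (size_t k = 0; k < qa.size(); ++k)
      if (qa[k] > 0 && ta[k] > 0) forb[IDX(qa[k], ta[k])] = 1;

    out[found++] = List::create(_["score"] = best,
                                _["qa"] = IntegerVector(qa.begin(), qa.end()),
                                _["ta"] = IntegerVector(ta.begin(), ta.end()));
  }
#undef IDX
  if (found == nAlt) return out;
  List trimmed(found);
  for (int k = 0; k < found; ++k) trimmed[k] = out[k];
  return trimmed;
}
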