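#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted KS enrichment score from 0-based hit positions on a ranking.
// absr holds |metric|^p per ranked position; equals the R reference
// implementation (es_from_positions) exactly.
static double es_from_pos(std::vector<int> &pos, const std::vector<double> &absr,
                          int n) {
  int k = pos.size();
  if (k == n) return 1.0;
  std::sort(pos.begin(), pos.end());
  double nr = 0.0;
  for (int i = 0; i < k; ++i) nr += absr[pos[i]];
  double miss = 1.0 / (double)(n - k);
  double cum = 0.0, mx = R_NegInf, mn = R_PosInf;
  for (int i = 0; i < k; ++i) {
    double hw = (nr == 0.0) ? 1.0 / (double)k : absr[pos[i]] / nr;
    double bottom = cum - (double)(pos[i] - i) * miss;
    cum += hw;
    double top = cum - (double)(pos[i] - i) * miss;
    if (top > mx) mx = top;
    if (bottom < mn) mn = bottom;
  }
  return (mx >= -mn) ? mx : mn;
}

// Enrichment scores for every (permutation, gene set) pair.
// metrics: genes x n_perm ranking statistics (one column per permutation);
// tiebreak: per-gene secondary sort key (rank of the gene id);
// idx_list: per set, 0-based row indices of its member genes;
// weight_exponent: hit-weight exponent p.
// Returns an n_perm x n_sets matrix of enrichment scores.
// [[Rcpp::export]]
NumericMatrix perm_es_matrix(NumericMatrix metrics, IntegerVector tiebreak,
                             List idx_list, double weight_exponent) {
  const int n = metrics.nrow();
  const int n_perm = metrics.ncol();
  const int n_sets = idx_list.size();
  std::vector<std::vector<int>> sets(n_sets);
  for (int j = 0; j < n_sets; ++j) {
    IntegerVector ii = idx_list[j];
    sets[j].assign(ii.begin(), ii.end());
  }
  NumericMatrix out(n_perm, n_sets);
  std::vector<int> ord(n), pos_of(n);
  std::vector<double> absr(n);
  std::vector<int> pos;
  for (int b = 0; b < n_perm; ++b) {
    const double *m = &metrics(0, b);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int i, int j) {
      if (m[i] != m[j]) return m[i] > m[j];
      return tiebreak[i] < tiebreak[j];
    });
    for (int r = 0; r < n; ++r) {
      pos_of[ord[r]] = r;
      absr[r] = std::pow(std::fabs(m[ord[r]]), weight_exponent);
    }
    for (int j = 0; j < n_sets; ++j) {
      const std::vector<int> &ii = sets[j];
      pos.resize(ii.size());
      for (size_t t = 0; t < ii.size(); ++t) pos[t] = pos_of[ii[t]];
      out(b, j) = es_from_pos(pos, absr, n);
    }
  }
  return out;
}
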