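#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dynamic-time-warping similarity between two positive frequency sequences.
//
// Local similarity of a pair of samples is 100 * min(f, g) / max(f, g).
// The alignment is a monotone path of cells from (1,1) to (n,m) using
// diagonal, horizontal and vertical unit moves; the score of a path is the
// MEAN local similarity over its cells, and the reported similarity is the
// maximum of that mean over admissible paths. Because the mean depends on
// the path length L, the programme is run per length: S[L][i][j] = best
// total similarity of a length-L path ending at (i,j).
//
// The warp constraint bounds the alignment length: L <= max(n, m) or
// L <= ceil(max_warp * min(n, m)), whichever is larger (and never more than
// n + m - 1). With max_warp = 3 one sequence can absorb at most a threefold
// time stretch against the other.
//
// [[Rcpp::export]]
List dtw_core(NumericVector a, NumericVector b, double max_warp) {
  const int n = a.size(), m = b.size();
  if (n < 2 || m < 2) stop("dtw_core: both sequences need length >= 2");
  for (int i = 0; i < n; ++i)
    if (!(a[i] > 0)) stop("dtw_core: sequence values must be positive");
  for (int j = 0; j < m; ++j)
    if (!(b[j] > 0)) stop("dtw_core: sequence values must be positive");
  if (max_warp < 1) stop("dtw_core: max_warp must be >= 1");

  const int Lmin = std::max(n, m);
  int Lmax = std::max(Lmin, (int)std::ceil(max_warp * std::min(n, m)));
  if (Lmax > n + m - 1) Lmax = n + m - 1;

  std::vector<double> sim((size_t)n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double f = a[i], g = b[j];
      sim[(size_t)i * m + j] = 100.0 * (f < g ? f / g : g / f);
    }

  const double NEG = -1e300;
  std::vector<double> prev((size_t)n * m, NEG), cur((size_t)n * m, NEG);
  // predecessor move per (L, i, j): 0 = diagonal, 1 = from (i-1, j),
  // 2 = from (i, j-1), -1 = unreachable / path start
  std::vector<signed char> pred((size_t)Lmax * n * m, -1);

  prev[0] = sim[0];  // L = 1: path {(1,1)}
  double bestMean = NEG;
  int bestL = -1;

  if (n == 1 && m == 1) { bestMean = sim[0]; bestL = 1; }

  for (int L = 2; L <= Lmax; ++L) {
    std::fill(cur.begin(), cur.end(), NEG);
    // cells reachable with exactly L cells: max(i,j)+1 <= L <= i+j+1
    for (int i = 0; i < n; ++i) {
      if (i + 1 > L) break;
      for (int j = 0; j < m; ++j) {
        if (j + 1 > L) break;
        if (i + j + 1 < L) continue;
        if (i == 0 && j == 0) continue;
        double best = NEG;
        signed char mv = -1;
        if (i > 0 && j > 0 && prev[(size_t)(i - 1) * m + (j - 1)] > best) {
          best = prev[(size_t)(i - 1) * m + (j - 1)]; mv = 0;
        }
        if (i > 0 && prev[(size_t)(i - 1) * m + j] > best) {
          best = prev[(size_t)(i - 1) * m + j]; mv = 1;
        }
        if (j > 0 && prev[(size_t)i * m + (j - 1)] > best) {
          best = prev[(size_t)i * m + (j - 1)]; mv = 2;
        }
        if (mv >= 0) {
          cur[(size_t)i * m + j] = best + sim[(size_t)i * m + j];
          pred[(size_t)(L - 1) * n * m + (size_t)i * m + j] = mv;
        }
      }
    }
    double endv = cur[(size_t)(n - 1) * m + (m - 1)];
    if (endv > NEG / 2 && L >= Lmin) {
      double mean = endv / L;
      if (mean > bestMean) { bestMean = mean; bestL = L; }
    }
    std::swap(prev, cur);
  }

  if (bestL < 0) stop("dtw_core: no admissible warping path");

  // backtrack the optimal path
  IntegerMatrix path(bestL, 2);
  int i = n - 1, j = m - 1;
  for (int L = bestL; L >= 1; --L) {
    path(L - 1, 0) = i + 1;
    path(L - 1, 1) = j + 1;
    if (L == 1) break;
    signed char mv = pred[(size_t)(L - 1) * n * m + (size_t)i * m + j];
    if (mv == 0) { --i; --j; }
    else if (mv == 1) { --i; }
    else if (mv == 2) { --j; }
    else stop("dtw_core: backtrack failed");
  }

  return List::create(_["similarity_pct"] = bestMean,
                      _["path"] = path,
                      _["path_length"] = bestL);
}
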