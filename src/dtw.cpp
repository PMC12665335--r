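#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Dependent multidimensional DTW with a slope-corrected Sakoe-Chiba band and
// fractional open endpoints.
//
// Series are matrices with time in rows and dimensions in columns; the local
// cost is the Euclidean norm of the frame difference taken jointly over all
// dimensions (one shared warping path per feature).
//
// Geometry, with n = nrow(a), m = nrow(b), L = max(n, m):
//   band:  cell (i, j), 1-based, admissible iff |i * m/n - j| <= ceil(band_frac * L)
//   open:  the path may start at any admissible (i, j) with i <= mo + 1 and
//          j <= mo + 1, and end at any admissible (i, j) with i >= n - mo and
//          j >= m - mo, where mo = ceil(open_frac * L); mo = 0 reduces to the
//          textbook fixed endpoints (1,1) .. (n,m).
// Steps {(1,0),(0,1),(1,1)} with unit weights. Returns the minimum
// accumulated cost over admissible end cells and the step count of that path
// (for path-length normalisation by the caller). In a start cell the
// minimum-cost path is always the fresh length-1 path, costs being
// nonnegative. DP uses a two-row rolling buffer; memory is O(m).

// [[Rcpp::export(name = ".dtw_cost_cpp")]]
NumericVector dtw_cost_cpp(NumericMatrix a, NumericMatrix b,
                           double band_frac, double open_frac) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  if (d != b.ncol()) stop("series dimensionality differs: %d vs %d", d, b.ncol());
  if (n < 1 || m < 1) stop("empty series");
  const int L = n > m ? n : m;
  const int w  = (int)std::ceil(band_frac * L);
  const int mo = (int)std::ceil(open_frac * L);
  const double slope = (double)m / (double)n;
  const double INF = std::numeric_limits<double>::infinity();
  const double *pa = &a(0, 0), *pb = &b(0, 0);

  std::vector<double> Dprev(m + 1, INF), Dcur(m + 1, INF);
  std::vector<int> Nprev(m + 1, 0), Ncur(m + 1, 0);
  int prev_lo = 1, prev_hi = 0;  // admissible j range of the previous row
  double bestD = INF;
  int bestN = 0;

  for (int i = 1; i <= n; ++i) {
    const double c = i * slope;
    int jlo = (int)std::ceil(c - w), jhi = (int)std::floor(c + w);
    if (jlo < 1) jlo = 1;
    if (jhi > m) jhi = m;
    if (jlo > jhi) { prev_lo = 1; prev_hi = 0; continue; }
    for (int j = jlo; j <= jhi; ++j) { Dcur[j] = INF; Ncur[j] = 0; }
    for (int j = jlo; j <= jhi; ++j) {
      double cost = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = pa[(i - 1) + (size_t)k * n] - pb[(j - 1) + (size_t)k * m];
        cost += diff * diff;
      }
      cost = std::sqrt(cost);
      double best = INF;
      int bn = 0;
      if (i <= mo + 1 && j <= mo + 1) {
        best = 0.0;  // fresh start dominates any continuation
      } else {
        if (j - 1 >= prev_lo && j - 1 <= prev_hi && Dprev[j - 1] < best) {
          best = Dprev[j - 1]; bn = Nprev[j - 1];          // diagonal
        }
        if (j >= prev_lo && j <= prev_hi && Dprev[j] < best) {
          best = Dprev[j]; bn = Nprev[j];                  // vertical
        }
        if (j - 1 >= jlo && Dcur[j - 1] < best) {
          best = Dcur[j - 1]; bn = Ncur[j - 1];            // horizontal
        }
      }
      if (best < INF) {
        Dcur[j] = cost + best;
        Ncur[j] = bn + 1;
        if (i >= n - mo && j >= m - mo && Dcur[j] < bestD) {
          bestD = Dcur[j]; bestN = Ncur[j];
        }
      }
    }
    std::swap(Dprev, Dcur);
    std::swap(Nprev, Ncur);
    prev_lo = jlo; prev_hi = jhi;
  }
  return NumericVector::create(_["cost"] = bestD, _["steps"] = (double)bestN);
}
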