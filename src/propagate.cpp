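#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Inverse-distance-weighted (power 1) interpolation of sparse edge values
// over the full grid, using the m nearest edge pixels per target pixel.
// Edge pixels keep their own value exactly. Brute force over the edge list
// with a small bounded insertion sort per pixel; deterministic ties by
// edge-list order.
// [[Rcpp::export]]
NumericMatrix propagate_idw_cpp(IntegerVector edgeRow, IntegerVector edgeCol,
                                NumericVector edgeVal, int nrow, int ncol,
                                int m) {
  const int ne = edgeRow.size();
  NumericMatrix out(nrow, ncol);
  if (ne == 0) return out;
  std::vector<double> bestD(m), bestV(m);
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      int k = 0;
      bool exact = false;
      for (int e = 0; e < ne; ++e) {
        const double dr = (r + 1) - edgeRow[e];
        const double dc = (c + 1) - edgeCol[e];
        const double d2 = dr * dr + dc * dc;
        if (d2 == 0.0) { out(r, c) = edgeVal[e]; exact = true; break; }
        if (k < m) {
          int pos = k++;
          while (pos > 0 && bestD[pos - 1] > d2) {
            bestD[pos] = bestD[pos - 1]; bestV[pos] = bestV[pos - 1]; --pos;
          }
          bestD[pos] = d2; bestV[pos] = edgeVal[e];
        } else if (d2 < bestD[m - 1]) {
          int pos = m - 1;
          while (pos > 0 && bestD[pos - 1] > d2) {
            bestD[pos] = bestD[pos - 1]; bestV[pos] = bestV[pos - 1]; --pos;
          }
          bestD[pos] = d2; bestV[pos] = edgeVal[e];
        }
      }
      if (exact) continue;
      double wsum = 0.0, vsum = 0.0;
      for (int i = 0; i < k; ++i) {
        const double w = 1.0 / std::sqrt(bestD[i]);
        wsum += w; vsum += w * bestV[i];
      }
      out(r, c) = vsum / wsum;
    }
  }
  return out;
}
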