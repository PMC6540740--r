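#include <Rcpp.h>
using namespace Rcpp;

// Gaussian stem-weighted pairing matrix.
//
// bases: integer codes 1..4 (A,U,G,C). wt: 4x4 pairing-weight table
// (2 for A-U, 3 for G-C, x for G-U, 0 otherwise). For a pairable (i,j) the
// entry is the centre weight plus Gaussian-damped contributions from the
// potential stem through (i,j): outward offsets (i-t, j+t) and inward
// offsets (i+t, j-t), each direction truncated at the sequence boundary,
// at the point where the inward indices cross, or at the first offset whose
// own pairing weight is zero (a stem must be contiguous).
// [[Rcpp::export(name = ".encode_matrix_cpp")]]
NumericMatrix encode_matrix_cpp(IntegerVector bases, NumericMatrix wt,
                                double sigma, int max_offset) {
  const int n = bases.size();
  NumericMatrix W(n, n);
  const double s2 = 2.0 * sigma * sigma;
  std::vector<double> g(max_offset + 1);
  for (int t = 0; t <= max_offset; ++t) g[t] = std::exp(-(double)(t * t) / s2);

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double p0 = wt(bases[i] - 1, bases[j] - 1);
      if (p0 == 0.0) continue;
      double w = p0; // t = 0
      for (int t = 1; t <= max_offset; ++t) { // outward: (i-t, j+t)
        int ii = i - t, jj = j + t;
        if (ii < 0 || jj >= n) break;
        double p = wt(bases[ii] - 1, bases[jj] - 1);
        if (p == 0.0) break;
        w += g[t] * p;
      }
      for (int t = 1; t <= max_offset; ++t) { // inward: (i+t, j-t)
        int ii = i + t, jj = j - t;
        if (ii >= jj) break;
        double p = wt(bases[ii] - 1, bases[jj] - 1);
        if (p == 0.0) break;
        w += g[t] * p;
      }
      W(i, j) = w;
      W(j, i) = w;
    }
  }
  return W;
}
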