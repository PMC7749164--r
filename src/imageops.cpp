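#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass chamfer transform: L1 (city-block) distance from every pixel to the
// nearest TRUE pixel, measured between pixel centers. Exact for the Manhattan
// metric. Returns R_PosInf everywhere when no pixel is TRUE.

// [[Rcpp::export]]
NumericMatrix cpp_l1_distance(LogicalMatrix target) {
  const int nr = target.nrow(), nc = target.ncol();
  const double INF = 1e18;
  NumericMatrix d(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      d(r, c) = target(r, c) ? 0.0 : INF;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (r > 0 && d(r - 1, c) + 1 < d(r, c)) d(r, c) = d(r - 1, c) + 1;
      if (c > 0 && d(r, c - 1) + 1 < d(r, c)) d(r, c) = d(r, c - 1) + 1;
    }
  for (int r = nr - 1; r >= 0; --r)
    for (int c = nc - 1; c >= 0; --c) {
      if (r < nr - 1 && d(r + 1, c) + 1 < d(r, c)) d(r, c) = d(r + 1, c) + 1;
      if (c < nc - 1 && d(r, c + 1) + 1 < d(r, c)) d(r, c) = d(r, c + 1) + 1;
    }
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (d(r, c) >= INF) d(r, c) = R_PosInf;
  return d;
}

// Binary erosion of the white (1) set with a 3x3 cross structuring element,
// out-of-image treated as black, repeated `iterations` times.

// [[Rcpp::export]]
IntegerMatrix cpp_erode_cross(IntegerMatrix img, int iterations) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix cur = clone(img);
  for (int it = 0; it < iterations; ++it) {
    IntegerMatrix nxt(nr, nc);
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        int keep = cur(r, c) == 1 &&
          (r > 0 ? cur(r - 1, c) == 1 : 0) &&
          (r < nr - 1 ? cur(r + 1, c) == 1 : 0) &&
          (c > 0 ? cur(r, c - 1) == 1 : 0) &&
          (c < nc - 1 ? cur(r, c + 1) == 1 : 0);
        nxt(r, c) = keep ? 1 : 0;
      }
    cur = nxt;
  }
  return cur;
}
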