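#include <Rcpp.h>
using namespace Rcpp;

// Grayscale erosion/dilation with an arbitrary (non-flat) structuring
// element given as offset triples (dx, dy, height). Out-of-image offsets
// are ignored (border handling by restriction), which keeps the opening of
// a constant image equal to that constant up to the border. Implemented as
// one sequential pass over the image per offset for cache efficiency.

// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(const NumericMatrix& img,
                             const IntegerVector& dx,
                             const IntegerVector& dy,
                             const NumericVector& h) {
  const int nr = img.nrow(), nc = img.ncol(), k = dx.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int s = 0; s < k; ++s) {
    const int di = dx[s], dj = dy[s];
    const double hs = h[s];
    const int j0 = std::max(0, -dj), j1 = std::min(nc, nc - dj);
    const int i0 = std::max(0, -di), i1 = std::min(nr, nr - di);
    for (int j = j0; j < j1; ++j) {
      const double* src = &img(0, j + dj);
      double* dst = &out(0, j);
      for (int i = i0; i < i1; ++i) {
        double v = src[i + di] - hs;
        if (v < dst[i]) dst[i] = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& img,
                              const IntegerVector& dx,
                              const IntegerVector& dy,
                              const NumericVector& h) {
  const int nr = img.nrow(), nc = img.ncol(), k = dx.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), R_NegInf);
  for (int s = 0; s < k; ++s) {
    const int di = -dx[s], dj = -dy[s];
    const double hs = h[s];
    const int j0 = std::max(0, -dj), j1 = std::min(nc, nc - dj);
    const int i0 = std::max(0, -di), i1 = std::min(nr, nr - di);
    for (int j = j0; j < j1; ++j) {
      const double* src = &img(0, j + dj);
      double* dst = &out(0, j);
      for (int i = i0; i < i1; ++i) {
        double v = src[i + di] + hs;
        if (v > dst[i]) dst[i] = v;
      }
    }
  }
  return out;
}
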