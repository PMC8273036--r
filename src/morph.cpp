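#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Grayscale erosion with a non-flat structuring element.
// se_dr/se_dc: integer offsets of the SE support; se_h: SE height at each
// offset. Out-of-image neighbours are ignored (treated as +Inf), the
// standard convention for finite-domain images.
// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(const NumericMatrix& img,
                             const IntegerVector& se_dr,
                             const IntegerVector& se_dc,
                             const NumericVector& se_h) {
  const int nr = img.nrow(), nc = img.ncol(), k = se_dr.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), R_PosInf);
  const double* im = img.begin();
  double* o = out.begin();
  // offset-outer loops with contiguous column scans: out(r,c) =
  // min_i img(r+dr_i, c+dc_i) - h_i, out-of-image neighbours ignored
  for (int i = 0; i < k; ++i) {
    const int dr = se_dr[i], dc = se_dc[i];
    const double h = se_h[i];
    const int c0 = std::max(0, -dc), c1 = std::min(nc, nc - dc);
    const int r0 = std::max(0, -dr), r1 = std::min(nr, nr - dr);
    for (int c = c0; c < c1; ++c) {
      const double* src = im + (size_t)(c + dc) * nr + dr;
      double* dst = o + (size_t)c * nr;
      for (int r = r0; r < r1; ++r) {
        const double v = src[r] - h;
        if (v < dst[r]) dst[r] = v;
      }
    }
  }
  return out;
}

// Grayscale dilation with a non-flat structuring element (reflected SE
// handled by the caller passing negated offsets if needed; here the SE is
// symmetric so no reflection is required).
// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(const NumericMatrix& img,
                              const IntegerVector& se_dr,
                              const IntegerVector& se_dc,
                              const NumericVector& se_h) {
  const int nr = img.nrow(), nc = img.ncol(), k = se_dr.size();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), R_NegInf);
  const double* im = img.begin();
  double* o = out.begin();
  for (int i = 0; i < k; ++i) {
    const int dr = -se_dr[i], dc = -se_dc[i];
    const double h = se_h[i];
    const int c0 = std::max(0, -dc), c1 = std::min(nc, nc - dc);
    const int r0 = std::max(0, -dr), r1 = std::min(nr, nr - dr);
    for (int c = c0; c < c1; ++c) {
      const double* src = im + (size_t)(c + dc) * nr + dr;
      double* dst = o + (size_t)c * nr;
      for (int r = r0; r < r1; ++r) {
        const double v = src[r] + h;
        if (v > dst[r]) dst[r] = v;
      }
    }
  }
  return out;
}

// Connected-component labeling of a logical mask with 8-connectivity
// (ImageJ default). Labels are consecutive from 1 in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        const int r0 = q.front().first, c0 = q.front().second;
        q.pop();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int rr = r0 + dr, cc = c0 + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}
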