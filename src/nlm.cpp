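#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Symmetric reflection (edge repeated) of a 0-based index into [0, n).
static inline int reflect0(int k, int n) {
  if (n == 1) return 0;
  while (k < 0 || k >= n) {
    if (k < 0) k = -k - 1;
    if (k >= n) k = 2 * n - 1 - k;
  }
  return k;
}

// Build a reflect-padded copy of img with `pad` pixels on every side,
// stored column-major in a flat vector of size (n + 2p) x (m + 2p).
static std::vector<double> pad_image(const NumericMatrix &img, int pad,
                                     int &pn, int &pm) {
  const int n = img.nrow(), m = img.ncol();
  pn = n + 2 * pad;
  pm = m + 2 * pad;
  std::vector<double> out((size_t)pn * pm);
  for (int c = 0; c < pm; ++c) {
    const int sc = reflect0(c - pad, m);
    for (int r = 0; r < pn; ++r) {
      out[(size_t)c * pn + r] = img(reflect0(r - pad, n), sc);
    }
  }
  return out;
}

// Non-local means with mean-squared patch distance, exp(-d / h^2) weights
// and reflected borders.  Self weight: exp(0) = 1 ("include") or the largest
// raw neighbor weight ("max of neighbors").
// [[Rcpp::export]]
NumericMatrix nlm_denoise_cpp(NumericMatrix img, int patch_radius,
                              int search_radius, double h,
                              bool include_self) {
  const int n = img.nrow(), m = img.ncol();
  const int pr = patch_radius, sr = search_radius;
  const int pad = pr + sr;
  int pn, pm;
  const std::vector<double> P = pad_image(img, pad, pn, pm);
  const double h2 = h * h;
  const double np = (2.0 * pr + 1.0) * (2.0 * pr + 1.0);
  NumericMatrix out(n, m);

  for (int c = 0; c < m; ++c) {
    for (int r = 0; r < n; ++r) {
      const int ir = r + pad, ic = c + pad;
      const double *pi = &P[(size_t)ic * pn + ir];
      double wsum = 0.0, acc = 0.0, wmax = 0.0;
      for (int dc = -sr; dc <= sr; ++dc) {
        for (int dr = -sr; dr <= sr; ++dr) {
          if (dr == 0 && dc == 0) continue;
          const double *pj = &P[(size_t)(ic + dc) * pn + (ir + dr)];
          double d = 0.0;
          for (int qc = -pr; qc <= pr; ++qc) {
            const std::ptrdiff_t off = (std::ptrdiff_t)qc * pn - pr;
            const double *a = pi + off;
            const double *b = pj + off;
            for (int qr = 0; qr <= 2 * pr; ++qr) {
              const double diff = a[qr] - b[qr];
              d += diff * diff;
            }
          }
          d /= np;
          const double w = std::exp(-d / h2);
          if (w > wmax) wmax = w;
          wsum += w;
          acc += w * (*pj);
        }
      }
      double wself = include_self ? 1.0 : wmax;
      if (wself == 0.0) wself = 1.0; // degenerate: all neighbor weights underflowed
      wsum += wself;
      acc += wself * (*pi);
      out(r, c) = acc / wsum;
    }
  }
  return out;
}

// Sliding-window median with reflected borders; window (2r+1)^2 is odd so
// the median is the middle order statistic.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int radius) {
  const int n = img.nrow(), m = img.ncol();
  const int r = radius;
  int pn, pm;
  const std::vector<double> P = pad_image(img, r, pn, pm);
  const int w = 2 * r + 1;
  const int count = w * w;
  const int mid = count / 2;
  std::vector<double> buf(count);
  NumericMatrix out(n, m);
  for (int c = 0; c < m; ++c) {
    for (int rr = 0; rr < n; ++rr) {
      int k = 0;
      for (int dc = 0; dc < w; ++dc) {
        const double *col = &P[(size_t)(c + dc) * pn + rr];
        for (int dr = 0; dr < w; ++dr) buf[k++] = col[dr];
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(rr, c) = buf[mid];
    }
  }
  return out;
}
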