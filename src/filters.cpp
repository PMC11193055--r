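#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// symmetric half-sample reflection: indices ... c b a | a b c d | d c b ...
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0)
      i = -i - 1;
    else
      i = 2 * n - 1 - i;
  }
  return i;
}

// Median filter with an arbitrary (possibly even) rectangular neighbourhood.
// Even windows are anchored with the extra row/column toward increasing
// index, e.g. a 4x4 window at (i,j) spans rows i-1..i+2 and cols j-1..j+2.
// Even-sized windows use the sample median (mean of the two middle order
// statistics); borders are reflected.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(const NumericMatrix& img, int kr, int kc) {
  const int nr = img.nrow(), nc = img.ncol();
  const int br = (kr - 1) / 2, ar = kr - 1 - br;
  const int bc = (kc - 1) / 2, ac = kc - 1 - bc;
  NumericMatrix out(nr, nc);
  std::vector<double> win(static_cast<size_t>(kr) * kc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int m = 0;
      for (int dj = -bc; dj <= ac; ++dj) {
        const int cj = reflect_idx(j + dj, nc);
        for (int di = -br; di <= ar; ++di) {
          win[m++] = img(reflect_idx(i + di, nr), cj);
        }
      }
      std::sort(win.begin(), win.begin() + m);
      out(i, j) = (m % 2 == 1) ? win[m / 2]
                               : 0.5 * (win[m / 2 - 1] + win[m / 2]);
    }
  }
  return out;
}

// vertical pass: convolve each column with kernel k (odd length), reflected
// borders; cache-friendly (columns are contiguous in R's column-major layout)
static void conv_vertical(const double* in, double* out, int nr, int nc,
                          const NumericVector& k) {
  const int R = (k.size() - 1) / 2;
  for (int j = 0; j < nc; ++j) {
    const double* cin = in + static_cast<R_xlen_t>(j) * nr;
    double* cout = out + static_cast<R_xlen_t>(j) * nr;
    const int lo = std::min(R, nr), hi = std::max(0, nr - R);
    for (int i = 0; i < lo; ++i) {
      double s = 0.0;
      for (int t = -R; t <= R; ++t) s += k[t + R] * cin[reflect_idx(i + t, nr)];
      cout[i] = s;
    }
    for (int i = lo; i < hi; ++i) {  // interior: no reflection needed
      double s = 0.0;
      for (int t = -R; t <= R; ++t) s += k[t + R] * cin[i + t];
      cout[i] = s;
    }
    for (int i = std::max(lo, hi); i < nr; ++i) {
      double s = 0.0;
      for (int t = -R; t <= R; ++t) s += k[t + R] * cin[reflect_idx(i + t, nr)];
      cout[i] = s;
    }
  }
}

// horizontal pass: accumulate whole columns (contiguous streams)
static void conv_horizontal(const double* in, double* out, int nr, int nc,
                            const NumericVector& k) {
  const int R = (k.size() - 1) / 2;
  std::fill(out, out + static_cast<R_xlen_t>(nr) * nc, 0.0);
  for (int j = 0; j < nc; ++j) {
    double* cout = out + static_cast<R_xlen_t>(j) * nr;
    for (int t = -R; t <= R; ++t) {
      const double kv = k[t + R];
      const double* cin = in + static_cast<R_xlen_t>(reflect_idx(j + t, nc)) * nr;
      for (int i = 0; i < nr; ++i) cout[i] += kv * cin[i];
    }
  }
}

// Separable convolution: kernel `ky` applied along rows (vertical axis),
// `kx` along columns.  Both kernels must have odd length; borders are
// reflected (symmetric half-sample, matching the median filter).
// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(const NumericMatrix& img, const NumericVector& ky,
                           const NumericVector& kx) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<double> tmp(static_cast<size_t>(nr) * nc);
  NumericMatrix out(nr, nc);
  conv_vertical(img.begin(), tmp.data(), nr, nc, ky);
  conv_horizontal(tmp.data(), out.begin(), nr, nc, kx);
  return out;
}

// Scale-normalized negative LoG response at one scale:
// -sigma^2 * (I * (g2_y x g_x) + I * (g_y x g2_x)),
// sharing the two vertical passes.
// [[Rcpp::export]]
NumericMatrix cpp_log_response(const NumericMatrix& img,
                               const NumericVector& g,
                               const NumericVector& g2, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  const R_xlen_t n = static_cast<R_xlen_t>(nr) * nc;
  std::vector<double> vg(n), vg2(n), h(n);
  NumericMatrix out(nr, nc);
  conv_vertical(img.begin(), vg.data(), nr, nc, g);    // G along y
  conv_vertical(img.begin(), vg2.data(), nr, nc, g2);  // d2G along y
  conv_horizontal(vg2.data(), out.begin(), nr, nc, g); // (d2G_y, G_x)
  conv_horizontal(vg.data(), h.data(), nr, nc, g2);    // (G_y, d2G_x)
  const double s2 = -sigma * sigma;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = s2 * (out[i] + h[i]);
  return out;
}

// Strict local maxima of a (nr x nc x ns) scale-space response volume,
// stored in R's column-major order.  A voxel is a peak when its response is
// >= threshold and, against each of its (up to) 26 in-bounds neighbours, it
// is strictly larger, or equal but earlier in (y, x, scale) lexicographic
// order (deterministic plateau rule).  Returns 1-based (y, x, scale) rows.
// [[Rcpp::export]]
IntegerMatrix cpp_scale_space_maxima(const NumericVector& vol, int nr, int nc,
                                     int ns, double threshold) {
  std::vector<int> ri, rj, rs;
  for (int s = 0; s < ns; ++s) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        const double v = vol[i + static_cast<R_xlen_t>(nr) * (j + static_cast<R_xlen_t>(nc) * s)];
        if (!(v >= threshold)) continue;
        bool peak = true;
        for (int ds = -1; ds <= 1 && peak; ++ds) {
          const int ss = s + ds;
          if (ss < 0 || ss >= ns) continue;
          for (int dj = -1; dj <= 1 && peak; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= nc) continue;
            for (int di = -1; di <= 1 && peak; ++di) {
              if (di == 0 && dj == 0 && ds == 0) continue;
              const int ii = i + di;
              if (ii < 0 || ii >= nr) continue;
              const double u = vol[ii + static_cast<R_xlen_t>(nr) * (jj + static_cast<R_xlen_t>(nc) * ss)];
              if (u > v) {
                peak = false;
              } else if (u == v) {
                const bool precedes =
                    (i < ii) ||
                    (i == ii && (j < jj || (j == jj && s < ss)));
                if (!precedes) peak = false;
              }
            }
          }
        }
        if (peak) {
          ri.push_back(i + 1);
          rj.push_back(j + 1);
          rs.push_back(s + 1);
        }
      }
    }
  }
  const int n = static_cast<int>(ri.size());
  IntegerMatrix out(n, 3);
  for (int k = 0; k < n; ++k) {
    out(k, 0) = ri[k];
    out(k, 1) = rj[k];
    out(k, 2) = rs[k];
  }
  colnames(out) = CharacterVector::create("y", "x", "scale");
  return out;
}
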