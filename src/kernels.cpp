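#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Backward bilinear warp: out(r,c) = img(r + dy(r,c), c + dx(r,c)).
// fill_edge = true clamps out-of-range samples to the border, otherwise the
// fill value is used. mask marks samples that fell fully inside the image.
// [[Rcpp::export]]
List warp_bilinear_cpp(const NumericMatrix& img, const NumericMatrix& dy,
                       const NumericMatrix& dx, bool fill_edge, double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  LogicalMatrix mask(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double sy = i + dy(i, j);
      double sx = j + dx(i, j);
      bool inside = (sy >= 0.0 && sy <= nr - 1.0 && sx >= 0.0 && sx <= nc - 1.0);
      mask(i, j) = inside;
      if (!inside && !fill_edge) {
        // strict constant fill: any sample outside the image domain
        out(i, j) = fill;
        continue;
      }
      if (fill_edge || !inside) {
        if (sy < 0) sy = 0; else if (sy > nr - 1.0) sy = nr - 1.0;
        if (sx < 0) sx = 0; else if (sx > nc - 1.0) sx = nc - 1.0;
      }
      int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
      if (y0 >= nr - 1) y0 = nr - 2;
      if (x0 >= nc - 1) x0 = nc - 2;
      if (nr == 1) y0 = 0;
      if (nc == 1) x0 = 0;
      double fy = sy - y0, fx = sx - x0;
      int y1 = (nr == 1) ? y0 : y0 + 1;
      int x1 = (nc == 1) ? x0 : x0 + 1;
      double v00 = img(y0, x0), v01 = img(y0, x1);
      double v10 = img(y1, x0), v11 = img(y1, x1);
      out(i, j) = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                  fy * ((1 - fx) * v10 + fx * v11);
    }
  }
  return List::create(_["out"] = out, _["mask"] = mask);
}

// Backward nearest-neighbour warp for integer label maps; out-of-bounds -> 0.
// [[Rcpp::export]]
IntegerMatrix warp_nearest_cpp(const IntegerMatrix& lab, const NumericMatrix& dy,
                               const NumericMatrix& dx) {
  const int nr = lab.nrow(), nc = lab.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double sy = i + dy(i, j);
      double sx = j + dx(i, j);
      int y = (int)std::floor(sy + 0.5);
      int x = (int)std::floor(sx + 0.5);
      out(i, j) = (y >= 0 && y < nr && x >= 0 && x < nc) ? lab(y, x) : 0;
    }
  }
  return out;
}

static std::vector<double> gauss_kernel(double sigma) {
  int rad = (int)std::ceil(3.0 * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> k(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    double v = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    k[i + rad] = v;
    s += v;
  }
  for (auto& v : k) v /= s;
  return k;
}

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable Gaussian blur with reflective boundary handling.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(const NumericMatrix& img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  std::vector<double> k = gauss_kernel(sigma);
  const int rad = ((int)k.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = -rad; t <= rad; ++t)
        s += k[t + rad] * img(reflect_idx(i + t, nr), j);
      tmp(i, j) = s;
    }
  }
  // horizontal pass
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = -rad; t <= rad; ++t)
        s += k[t + rad] * tmp(i, reflect_idx(j + t, nc));
      out(i, j) = s;
    }
  }
  return out;
}

// Bilinear resize; coordinates scaled so that corners map to corners.
// [[Rcpp::export]]
NumericMatrix resize_bilinear_cpp(const NumericMatrix& img, int out_r, int out_c) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(out_r, out_c);
  double ry = (out_r > 1) ? (double)(nr - 1) / (out_r - 1) : 0.0;
  double rx = (out_c > 1) ? (double)(nc - 1) / (out_c - 1) : 0.0;
  for (int j = 0; j < out_c; ++j) {
    for (int i = 0; i < out_r; ++i) {
      double sy = i * ry, sx = j * rx;
      int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
      if (y0 >= nr - 1) y0 = std::max(0, nr - 2);
      if (x0 >= nc - 1) x0 = std::max(0, nc - 2);
      double fy = sy - y0, fx = sx - x0;
      int y1 = std::min(y0 + 1, nr - 1), x1 = std::min(x0 + 1, nc - 1);
      out(i, j) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return out;
}

// One pyramid-level matching step. ref and mov are rows x cols x C feature
// arrays (mov already resampled by the current flow estimate). For every
// integer offset within the search radius, a per-pixel sum-of-squared-
// difference cost is aggregated over a box window (summed-area table), then
// decoded per pixel either by argmin with one-dimensional parabolic subpixel
// refinement (mode 0) or by a soft-argmax with temperature tau (mode 1).
// Costs are normalised by window area and channel count so tau is expressed
// in mean per-element SSD units.
// [[Rcpp::export]]
List match_level_cpp(const NumericVector& ref, const NumericVector& mov,
                     int radius, int window, int mode, double tau) {
  IntegerVector dm = ref.attr("dim");
  const int nr = dm[0], nc = dm[1], C = dm[2];
  const int noff = (2 * radius + 1) * (2 * radius + 1);
  const double big = 1e12;
  std::vector<double> cost((size_t)nr * nc * noff);
  std::vector<double> D((size_t)nr * nc), sat((size_t)(nr + 1) * (nc + 1));
  const double* rp = ref.begin();
  const double* mp = mov.begin();

  int oi = 0;
  for (int ox = -radius; ox <= radius; ++ox) {
    for (int oy = -radius; oy <= radius; ++oy, ++oi) {
      // raw per-pixel SSD with edge-clamped sampling of mov
      for (int j = 0; j < nc; ++j) {
        int js = j + ox;
        if (js < 0) js = 0; else if (js >= nc) js = nc - 1;
        for (int i = 0; i < nr; ++i) {
          int is = i + oy;
          if (is < 0) is = 0; else if (is >= nr) is = nr - 1;
          double s = 0.0;
          for (int ch = 0; ch < C; ++ch) {
            double d = rp[i + (size_t)nr * (j + (size_t)nc * ch)] -
                       mp[is + (size_t)nr * (js + (size_t)nc * ch)];
            s += d * d;
          }
          D[i + (size_t)nr * j] = s;
        }
      }
      // summed-area table (sat has an extra leading row/col of zeros)
      for (int j = 0; j <= nc; ++j) sat[(size_t)(nr + 1) * j] = 0.0;
      for (int i = 0; i <= nr; ++i) sat[i] = 0.0;
      for (int j = 1; j <= nc; ++j) {
        double rowsum = 0.0;
        for (int i = 1; i <= nr; ++i) {
          rowsum += D[(i - 1) + (size_t)nr * (j - 1)];
          sat[i + (size_t)(nr + 1) * j] = sat[i + (size_t)(nr + 1) * (j - 1)] + rowsum;
        }
      }
      // box aggregation with edge clamping of the window
      for (int j = 0; j < nc; ++j) {
        int x0 = std::max(0, j - window), x1 = std::min(nc - 1, j + window);
        for (int i = 0; i < nr; ++i) {
          int y0 = std::max(0, i - window), y1 = std::min(nr - 1, i + window);
          double s = sat[(y1 + 1) + (size_t)(nr + 1) * (x1 + 1)] -
                     sat[y0 + (size_t)(nr + 1) * (x1 + 1)] -
                     sat[(y1 + 1) + (size_t)(nr + 1) * x0] +
                     sat[y0 + (size_t)(nr + 1) * x0];
          double area = (double)(y1 - y0 + 1) * (x1 - x0 + 1);
          // rescale partial windows to the full-window scale before norm
          cost[(i + (size_t)nr * j) + (size_t)nr * nc * oi] =
              s / area / C;
        }
      }
    }
  }

  NumericMatrix ddy(nr, nc), ddx(nr, nc), conf(nr, nc);
  const int side = 2 * radius + 1;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const size_t base = i + (size_t)nr * j;
      // cost contrast: 1 - min/mean in [0, 1); ~0 where the volume is flat
      {
        double cmean = 0.0, cmin2 = big;
        for (int o = 0; o < noff; ++o) {
          double cv = cost[base + (size_t)nr * nc * o];
          cmean += cv;
          if (cv < cmin2) cmin2 = cv;
        }
        cmean /= noff;
        conf(i, j) = (cmean > 1e-12) ? std::max(0.0, 1.0 - cmin2 / cmean)
                                     : 0.0;
      }
      if (mode == 0) {
        int besto = 0;
        double bestc = big;
        for (int o = 0; o < noff; ++o) {
          double cv = cost[base + (size_t)nr * nc * o];
          if (cv < bestc) { bestc = cv; besto = o; }
        }
        int boy = besto % side - radius;
        int box = besto / side - radius;
        double sy = 0.0, sx = 0.0;
        if (boy > -radius && boy < radius) {
          double cm = cost[base + (size_t)nr * nc * (besto - 1)];
          double cp = cost[base + (size_t)nr * nc * (besto + 1)];
          double den = cm - 2.0 * bestc + cp;
          if (den > 1e-12) {
            sy = 0.5 * (cm - cp) / den;
            if (sy > 0.5) sy = 0.5; else if (sy < -0.5) sy = -0.5;
          }
        }
        if (box > -radius && box < radius) {
          double cm = cost[base + (size_t)nr * nc * (besto - side)];
          double cp = cost[base + (size_t)nr * nc * (besto + side)];
          double den = cm - 2.0 * bestc + cp;
          if (den > 1e-12) {
            sx = 0.5 * (cm - cp) / den;
            if (sx > 0.5) sx = 0.5; else if (sx < -0.5) sx = -0.5;
          }
        }
        ddy(i, j) = boy + sy;
        ddx(i, j) = box + sx;
      } else {
        // soft-argmax
        double cmin = big;
        for (int o = 0; o < noff; ++o)
          cmin = std::min(cmin, cost[base + (size_t)nr * nc * o]);
        double Z = 0.0, ey = 0.0, ex = 0.0;
        for (int o = 0; o < noff; ++o) {
          double w = std::exp(-(cost[base + (size_t)nr * nc * o] - cmin) / tau);
          int oy2 = o % side - radius;
          int ox2 = o / side - radius;
          Z += w;
          ey += w * oy2;
          ex += w * ox2;
        }
        ddy(i, j) = ey / Z;
        ddx(i, j) = ex / Z;
      }
    }
  }
  return List::create(_["ddy"] = ddy, _["ddx"] = ddx, _["conf"] = conf);
}

// One damped Lucas-Kanade refinement step on multi-channel feature maps.
// ref and mov are rows x cols x C arrays, mov already warped by the current
// flow. Per pixel, gradients of mov and the residual (ref - mov) are
// accumulated over channels, box-aggregated over a (2w+1)^2 window via
// summed-area tables, and the damped 2x2 normal equations are solved:
// delta = (A + lambda I)^-1 b. Steps are clamped to +-maxStep px.
// [[Rcpp::export]]
List lk_step_cpp(const NumericVector& ref, const NumericVector& mov,
                 int window, double damping, double maxStep) {
  IntegerVector dm = ref.attr("dim");
  const int nr = dm[0], nc = dm[1], C = dm[2];
  const size_t npix = (size_t)nr * nc;
  std::vector<double> ayy(npix, 0.0), axx(npix, 0.0), axy(npix, 0.0),
      by(npix, 0.0), bx(npix, 0.0);
  for (int ch = 0; ch < C; ++ch) {
    const double* r = ref.begin() + npix * ch;
    const double* m = mov.begin() + npix * ch;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        int ip = std::min(i + 1, nr - 1), im = std::max(i - 1, 0);
        int jp = std::min(j + 1, nc - 1), jm = std::max(j - 1, 0);
        double gy = (m[ip + (size_t)nr * j] - m[im + (size_t)nr * j]) /
                    (ip - im);
        double gx = (m[i + (size_t)nr * jp] - m[i + (size_t)nr * jm]) /
                    (jp - jm);
        double res = r[i + (size_t)nr * j] - m[i + (size_t)nr * j];
        size_t q = i + (size_t)nr * j;
        ayy[q] += gy * gy;
        axx[q] += gx * gx;
        axy[q] += gy * gx;
        by[q] += gy * res;
        bx[q] += gx * res;
      }
    }
  }
  // box aggregation of all five accumulators
  auto boxagg = [&](std::vector<double>& v) {
    std::vector<double> sat((size_t)(nr + 1) * (nc + 1), 0.0);
    for (int j = 1; j <= nc; ++j) {
      double rowsum = 0.0;
      for (int i = 1; i <= nr; ++i) {
        rowsum += v[(i - 1) + (size_t)nr * (j - 1)];
        sat[i + (size_t)(nr + 1) * j] =
            sat[i + (size_t)(nr + 1) * (j - 1)] + rowsum;
      }
    }
    for (int j = 0; j < nc; ++j) {
      int x0 = std::max(0, j - window), x1 = std::min(nc - 1, j + window);
      for (int i = 0; i < nr; ++i) {
        int y0 = std::max(0, i - window), y1 = std::min(nr - 1, i + window);
        v[i + (size_t)nr * j] =
            sat[(y1 + 1) + (size_t)(nr + 1) * (x1 + 1)] -
            sat[y0 + (size_t)(nr + 1) * (x1 + 1)] -
            sat[(y1 + 1) + (size_t)(nr + 1) * x0] +
            sat[y0 + (size_t)(nr + 1) * x0];
      }
    }
  };
  boxagg(ayy); boxagg(axx); boxagg(axy); boxagg(by); boxagg(bx);
  NumericMatrix ddy(nr, nc), ddx(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      size_t q = i + (size_t)nr * j;
      double a = ayy[q] + damping, d = axx[q] + damping, bxy = axy[q];
      double det = a * d - bxy * bxy;
      double sy = (d * by[q] - bxy * bx[q]) / det;
      double sx = (a * bx[q] - bxy * by[q]) / det;
      if (sy > maxStep) sy = maxStep; else if (sy < -maxStep) sy = -maxStep;
      if (sx > maxStep) sx = maxStep; else if (sx < -maxStep) sx = -maxStep;
      ddy(i, j) = sy;
      ddx(i, j) = sx;
    }
  }
  return List::create(_["ddy"] = ddy, _["ddx"] = ddx);
}
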