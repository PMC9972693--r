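// Siddon-type exact pixel-chord ray tracer and TOF-weighted projection
// operators for a 2D ring geometry.
//
// Conventions (shared with the R level):
//  - image is an ng x ng matrix, first index x, second index y;
//    pixel (i, j) (0-based here) has its centre at
//    (-W + (i + 0.5) * px, -W + (j + 0.5) * px) with W = ng * px / 2.
//  - an LOR is parameterised by signed radial offset r and angle theta in
//    [0, pi): points p(t) = r * (cos t., sin t.) + t * (-sin t., cos t.);
//    the TOF coordinate t is 0 at the closest approach to the origin.
//  - TOF bins are contiguous, bin b (0-based) centred at
//    (b - (nt - 1) / 2) * dt, width dt; weights are Gaussian CDF
//    differences over the bin edges (sigma = spatial sigma along the LOR).
//  - lengths are millimetres throughout.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Geom {
  int nr, na, nt, ng;
  double dr, dt, px, sigma;
};

Geom as_geom(const List& g) {
  Geom G;
  G.nr = as<int>(g["n_radial"]);
  G.na = as<int>(g["n_angles"]);
  G.nt = as<int>(g["n_tof_bins"]);
  G.ng = as<int>(g["grid_n"]);
  G.dr = as<double>(g["radial_spacing"]);
  G.dt = as<double>(g["tof_bin_width"]);
  G.px = as<double>(g["pixel_size"]);
  G.sigma = as<double>(g["tof_sigma_mm"]);
  return G;
}

inline double lor_radius(const Geom& G, int ir) {
  return (ir - (G.nr - 1) / 2.0) * G.dr;
}

inline double ncdf(double z) { return 0.5 * erfc(-z * M_SQRT1_2); }

// Exact grid traversal; fills pixel index (0-based, column-major i + ng*j),
// chord length and along-ray midpoint of every crossed pixel.
// Returns the number of segments.
int trace(const Geom& G, double r, double theta,
          int* pix, double* len, double* tmid) {
  const double W = G.ng * G.px / 2.0;
  const double nx = std::cos(theta), ny = std::sin(theta);
  const double dx = -ny, dy = nx;
  const double x0 = r * nx, y0 = r * ny;
  const double EPS = 1e-12;

  double tmin = -1e300, tmax = 1e300;
  if (std::fabs(dx) < EPS) {
    if (x0 <= -W || x0 >= W) return 0;
  } else {
    double t1 = (-W - x0) / dx, t2 = (W - x0) / dx;
    if (t1 > t2) std::swap(t1, t2);
    if (t1 > tmin) tmin = t1;
    if (t2 < tmax) tmax = t2;
  }
  if (std::fabs(dy) < EPS) {
    if (y0 <= -W || y0 >= W) return 0;
  } else {
    double t1 = (-W - y0) / dy, t2 = (W - y0) / dy;
    if (t1 > t2) std::swap(t1, t2);
    if (t1 > tmin) tmin = t1;
    if (t2 < tmax) tmax = t2;
  }
  if (tmax - tmin < EPS) return 0;

  // entry cell, nudged inside to be robust at the boundary
  const double nudge = 1e-9 * (tmax - tmin);
  double xs = x0 + dx * (tmin + nudge), ys = y0 + dy * (tmin + nudge);
  int ix = (int)std::floor((xs + W) / G.px);
  int iy = (int)std::floor((ys + W) / G.px);
  if (ix < 0) ix = 0; if (ix > G.ng - 1) ix = G.ng - 1;
  if (iy < 0) iy = 0; if (iy > G.ng - 1) iy = G.ng - 1;

  const int sx = (dx > EPS) ? 1 : ((dx < -EPS) ? -1 : 0);
  const int sy = (dy > EPS) ? 1 : ((dy < -EPS) ? -1 : 0);
  double tMaxX = 1e300, tMaxY = 1e300, tDx = 1e300, tDy = 1e300;
  if (sx != 0) {
    double xb = -W + (ix + (sx > 0 ? 1 : 0)) * G.px;
    tMaxX = (xb - x0) / dx;
    tDx = G.px / std::fabs(dx);
  }
  if (sy != 0) {
    double yb = -W + (iy + (sy > 0 ? 1 : 0)) * G.px;
    tMaxY = (yb - y0) / dy;
    tDy = G.px / std::fabs(dy);
  }

  int n = 0;
  double t = tmin;
  while (t < tmax - EPS) {
    double tn = std::min(std::min(tMaxX, tMaxY), tmax);
    double L = tn - t;
    if (L > EPS && ix >= 0 && ix < G.ng && iy >= 0 && iy < G.ng) {
      pix[n] = ix + G.ng * iy;
      len[n] = L;
      tmid[n] = 0.5 * (t + tn);
      ++n;
    }
    if (tn >= tmax - EPS) break;
    bool ax = (tMaxX <= tMaxY);
    bool ay = (tMaxY <= tMaxX);
    if (ax) { ix += sx; tMaxX += tDx; }
    if (ay) { iy += sy; tMaxY += tDy; }
    t = tn;
  }
  return n;
}

// TOF bin range covered by a kernel centred at tm (7 sigma support; with
// sigma = 0 the single containing bin).  Returns false when no bin overlaps.
bool bin_range(const Geom& G, double tm, int& bl, int& bh) {
  const double half = (G.nt - 1) / 2.0;
  if (G.sigma <= 0.0) {
    int b = (int)std::lround(tm / G.dt + half);
    if (b < 0 || b > G.nt - 1) return false;
    bl = bh = b;
    return true;
  }
  const double span = 7.0 * G.sigma;
  bl = (int)std::floor((tm - span) / G.dt + half + 0.5);
  bh = (int)std::floor((tm + span) / G.dt + half + 0.5);
  if (bl < 0) bl = 0;
  if (bh > G.nt - 1) bh = G.nt - 1;
  return bl <= bh;
}

inline double bin_low_edge(const Geom& G, int b) {
  return (b - (G.nt - 1) / 2.0) * G.dt - 0.5 * G.dt;
}

}  // namespace

// [[Rcpp::export]]
List cpp_trace_ray(List geometry, double r, double theta) {
  Geom G = as_geom(geometry);
  std::vector<int> pix(2 * G.ng + 4);
  std::vector<double> len(2 * G.ng + 4), tm(2 * G.ng + 4);
  int n = trace(G, r, theta, pix.data(), len.data(), tm.data());
  IntegerVector p(n);
  NumericVector l(n), t(n);
  for (int k = 0; k < n; ++k) {
    p[k] = pix[k] + 1;  // 1-based for R
    l[k] = len[k];
    t[k] = tm[k];
  }
  return List::create(_["pixel"] = p, _["length"] = l, _["tmid"] = t);
}

// TOF forward projection of an image (no attenuation, no calibration):
// out[ir, k, b] = sum over crossed pixels of length * tof_weight * img.
// [[Rcpp::export]]
NumericVector cpp_fp_tof(List geometry, NumericMatrix img, IntegerVector angles) {
  Geom G = as_geom(geometry);
  const int nk = angles.size();
  NumericVector out(G.nr * nk * G.nt);
  std::vector<int> pix(2 * G.ng + 4);
  std::vector<double> len(2 * G.ng + 4), tm(2 * G.ng + 4);
  for (int k = 0; k < nk; ++k) {
    double theta = (angles[k] - 1) * M_PI / G.na;
    for (int ir = 0; ir < G.nr; ++ir) {
      int n = trace(G, lor_radius(G, ir), theta, pix.data(), len.data(), tm.data());
      for (int s = 0; s < n; ++s) {
        double v = img[pix[s]] * len[s];
        if (v == 0.0) continue;
        int bl, bh;
        if (!bin_range(G, tm[s], bl, bh)) continue;
        if (G.sigma <= 0.0) {
          out[ir + G.nr * (k + nk * bl)] += v;
          continue;
        }
        double prev = ncdf((bin_low_edge(G, bl) - tm[s]) / G.sigma);
        for (int b = bl; b <= bh; ++b) {
          double cur = ncdf((bin_low_edge(G, b + 1) - tm[s]) / G.sigma);
          out[ir + G.nr * (k + nk * b)] += v * (cur - prev);
          prev = cur;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(G.nr, nk, G.nt);
  return out;
}

// Exact adjoint of cpp_fp_tof.
// [[Rcpp::export]]
NumericMatrix cpp_bp_tof(List geometry, NumericVector sino, IntegerVector angles) {
  Geom G = as_geom(geometry);
  const int nk = angles.size();
  if ((int)sino.size() != G.nr * nk * G.nt)
    stop("sinogram size does not match geometry/angle subset");
  NumericMatrix img(G.ng, G.ng);
  std::vector<int> pix(2 * G.ng + 4);
  std::vector<double> len(2 * G.ng + 4), tm(2 * G.ng + 4);
  for (int k = 0; k < nk; ++k) {
    double theta = (angles[k] - 1) * M_PI / G.na;
    for (int ir = 0; ir < G.nr; ++ir) {
      int n = trace(G, lor_radius(G, ir), theta, pix.data(), len.data(), tm.data());
      for (int s = 0; s < n; ++s) {
        int bl, bh;
        if (!bin_range(G, tm[s], bl, bh)) continue;
        double acc = 0.0;
        if (G.sigma <= 0.0) {
          acc = sino[ir + G.nr * (k + nk * bl)];
        } else {
          double prev = ncdf((bin_low_edge(G, bl) - tm[s]) / G.sigma);
          for (int b = bl; b <= bh; ++b) {
            double cur = ncdf((bin_low_edge(G, b + 1) - tm[s]) / G.sigma);
            acc += sino[ir + G.nr * (k + nk * b)] * (cur - prev);
            prev = cur;
          }
        }
        img[pix[s]] += len[s] * acc;
      }
    }
  }
  return img;
}

// Backprojection of a per-LOR value weighted by the total TOF mass of each
// pixel (the telescoped sum of the per-bin weights used by cpp_fp_tof /
// cpp_bp_tof, so sensitivity images are exactly consistent with them).
// [[Rcpp::export]]
NumericMatrix cpp_bp_tofsum(List geometry, NumericMatrix vals, IntegerVector angles) {
  Geom G = as_geom(geometry);
  const int nk = angles.size();
  if (vals.nrow() != G.nr || vals.ncol() != nk)
    stop("value matrix does not match geometry/angle subset");
  NumericMatrix img(G.ng, G.ng);
  std::vector<int> pix(2 * G.ng + 4);
  std::vector<double> len(2 * G.ng + 4), tm(2 * G.ng + 4);
  for (int k = 0; k < nk; ++k) {
    double theta = (angles[k] - 1) * M_PI / G.na;
    for (int ir = 0; ir < G.nr; ++ir) {
      double v = vals(ir, k);
      if (v == 0.0) continue;
      int n = trace(G, lor_radius(G, ir), theta, pix.data(), len.data(), tm.data());
      for (int s = 0; s < n; ++s) {
        int bl, bh;
        if (!bin_range(G, tm[s], bl, bh)) continue;
        double w;
        if (G.sigma <= 0.0) {
          w = 1.0;
        } else {
          w = ncdf((bin_low_edge(G, bh + 1) - tm[s]) / G.sigma) -
              ncdf((bin_low_edge(G, bl) - tm[s]) / G.sigma);
        }
        img[pix[s]] += len[s] * w * v;
      }
    }
  }
  return img;
}

// Forward companion of cpp_bp_tofsum: per-LOR line integral with each pixel
// weighted by its total TOF mass, i.e. the TOF-bin sum of cpp_fp_tof.
// [[Rcpp::export]]
NumericMatrix cpp_fp_tofsum(List geometry, NumericMatrix img, IntegerVector angles) {
  Geom G = as_geom(geometry);
  const int nk = angles.size();
  NumericMatrix out(G.nr, nk);
  std::vector<int> pix(2 * G.ng + 4);
  std::vector<double> len(2 * G.ng + 4), tm(2 * G.ng + 4);
  for (int k = 0; k < nk; ++k) {
    double theta = (angles[k] - 1) * M_PI / G.na;
    for (int ir = 0; ir < G.nr; ++ir) {
      int n = trace(G, lor_radius(G, ir), theta, pix.data(), len.data(), tm.data());
      double acc = 0.0;
      for (int s = 0; s < n; ++s) {
        double v = img[pix[s]] * len[s];
        if (v == 0.0) continue;
        int bl, bh;
        if (!bin_range(G, tm[s], bl, bh)) continue;
        double w;
        if (G.sigma <= 0.0) {
          w = 1.0;
        } else {
          w = ncdf((bin_low_edge(G, bh + 1) - tm[s]) / G.sigma) -
              ncdf((bin_low_edge(G, bl) - tm[s]) / G.sigma);
        }
        acc += v * w;
      }
      out(ir, k) = acc;
    }
  }
  return out;
}

// Plain (non-TOF) line integrals: out[ir, k] = sum length * img.
// [[Rcpp::export]]
NumericMatrix cpp_fp_line(List geometry, NumericMatrix img, IntegerVector angles) {
  Geom G = as_geom(geometry);
  const int nk = angles.size();
  NumericMatrix out(G.nr, nk);
  std::vector<int> pix(2 * G.ng + 4);
  std::vector<double> len(2 * G.ng + 4), tm(2 * G.ng + 4);
  for (int k = 0; k < nk; ++k) {
    double theta = (angles[k] - 1) * M_PI / G.na;
    for (int ir = 0; ir < G.nr; ++ir) {
      int n = trace(G, lor_radius(G, ir), theta, pix.data(), len.data(), tm.data());
      double acc = 0.0;
      for (int s = 0; s < n; ++s) acc += img[pix[s]] * len[s];
      out(ir, k) = acc;
    }
  }
  return out;
}

// Exact adjoint of cpp_fp_line.
// [[Rcpp::export]]
NumericMatrix cpp_bp_line(List geometry, NumericMatrix vals, IntegerVector angles) {
  Geom G = as_geom(geometry);
  const int nk = angles.size();
  if (vals.nrow() != G.nr || vals.ncol() != nk)
    stop("value matrix does not match geometry/angle subset");
  NumericMatrix img(G.ng, G.ng);
  std::vector<int> pix(2 * G.ng + 4);
  std::vector<double> len(2 * G.ng + 4), tm(2 * G.ng + 4);
  for (int k = 0; k < nk; ++k) {
    double theta = (angles[k] - 1) * M_PI / G.na;
    for (int ir = 0; ir < G.nr; ++ir) {
      double v = vals(ir, k);
      if (v == 0.0) continue;
      int n = trace(G, lor_radius(G, ir), theta, pix.data(), len.data(), tm.data());
      for (int s = 0; s < n; ++s) img[pix[s]] += len[s] * v;
    }
  }
  return img;
}
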