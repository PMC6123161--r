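#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sampling of `vol` at (i + dx, j + dy, k + dz) for every voxel
// (i, j, k), displacements in voxel units, nearest-edge clamping.
// [[Rcpp::export]]
NumericVector cpp_warp_trilinear(const NumericVector& vol, const IntegerVector& dim,
                                 const NumericVector& dx, const NumericVector& dy,
                                 const NumericVector& dz) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector out(vol.size());
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = clampd(i + dx[idx], 0.0, nx - 1.0);
        double y = clampd(j + dy[idx], 0.0, ny - 1.0);
        double z = clampd(k + dz[idx], 0.0, nz - 1.0);
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
        if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
        if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
        if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
        if (nx == 1) x0 = 0;
        if (ny == 1) y0 = 0;
        if (nz == 1) z0 = 0;
        double fx = x - x0, fy = y - y0, fz = z - z0;
        int x1 = (nx == 1) ? 0 : x0 + 1;
        int y1 = (ny == 1) ? 0 : y0 + 1;
        int z1 = (nz == 1) ? 0 : z0 + 1;
        R_xlen_t b000 = x0 + (R_xlen_t)y0 * nx + (R_xlen_t)z0 * nxy;
        R_xlen_t b100 = x1 + (R_xlen_t)y0 * nx + (R_xlen_t)z0 * nxy;
        R_xlen_t b010 = x0 + (R_xlen_t)y1 * nx + (R_xlen_t)z0 * nxy;
        R_xlen_t b110 = x1 + (R_xlen_t)y1 * nx + (R_xlen_t)z0 * nxy;
        R_xlen_t b001 = x0 + (R_xlen_t)y0 * nx + (R_xlen_t)z1 * nxy;
        R_xlen_t b101 = x1 + (R_xlen_t)y0 * nx + (R_xlen_t)z1 * nxy;
        R_xlen_t b011 = x0 + (R_xlen_t)y1 * nx + (R_xlen_t)z1 * nxy;
        R_xlen_t b111 = x1 + (R_xlen_t)y1 * nx + (R_xlen_t)z1 * nxy;
        double c00 = vol[b000] * (1 - fx) + vol[b100] * fx;
        double c10 = vol[b010] * (1 - fx) + vol[b110] * fx;
        double c01 = vol[b001] * (1 - fx) + vol[b101] * fx;
        double c11 = vol[b011] * (1 - fx) + vol[b111] * fx;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        out[idx] = c0 * (1 - fz) + c1 * fz;
      }
    }
  }
  return out;
}

// Spatial gradient in physical units (per mm): central differences in the
// interior, one-sided at the faces.
// [[Rcpp::export]]
List cpp_gradient3(const NumericVector& vol, const IntegerVector& dim,
                   const NumericVector& spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector gx(vol.size()), gy(vol.size()), gz(vol.size());
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        if (nx > 1) {
          if (i == 0)            gx[idx] = (vol[idx + 1] - vol[idx]) / hx;
          else if (i == nx - 1)  gx[idx] = (vol[idx] - vol[idx - 1]) / hx;
          else                   gx[idx] = (vol[idx + 1] - vol[idx - 1]) / (2 * hx);
        }
        if (ny > 1) {
          if (j == 0)            gy[idx] = (vol[idx + nx] - vol[idx]) / hy;
          else if (j == ny - 1)  gy[idx] = (vol[idx] - vol[idx - nx]) / hy;
          else                   gy[idx] = (vol[idx + nx] - vol[idx - nx]) / (2 * hy);
        }
        if (nz > 1) {
          if (k == 0)            gz[idx] = (vol[idx + nxy] - vol[idx]) / hz;
          else if (k == nz - 1)  gz[idx] = (vol[idx] - vol[idx - nxy]) / hz;
          else                   gz[idx] = (vol[idx + nxy] - vol[idx - nxy]) / (2 * hz);
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// 7-point Laplacian in physical units (per mm^2), replicate (Neumann) boundary.
// [[Rcpp::export]]
NumericVector cpp_laplacian3(const NumericVector& vol, const IntegerVector& dim,
                             const NumericVector& spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector out(vol.size());
  const double wx = 1.0 / (spacing[0] * spacing[0]);
  const double wy = 1.0 / (spacing[1] * spacing[1]);
  const double wz = 1.0 / (spacing[2] * spacing[2]);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        double c = vol[idx], acc = 0.0;
        if (nx > 1) {
          double xm = (i > 0) ? vol[idx - 1] : c;
          double xp = (i < nx - 1) ? vol[idx + 1] : c;
          acc += wx * (xm + xp - 2 * c);
        }
        if (ny > 1) {
          double ym = (j > 0) ? vol[idx - nx] : c;
          double yp = (j < ny - 1) ? vol[idx + nx] : c;
          acc += wy * (ym + yp - 2 * c);
        }
        if (nz > 1) {
          double zm = (k > 0) ? vol[idx - nxy] : c;
          double zp = (k < nz - 1) ? vol[idx + nxy] : c;
          acc += wz * (zm + zp - 2 * c);
        }
        out[idx] = acc;
      }
    }
  }
  return out;
}

// 1-D convolution along one axis (1 = x, 2 = y, 3 = z) with an odd-length
// kernel and replicate padding; used for separable Gaussian smoothing.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(const NumericVector& vol, const IntegerVector& dim,
                                const NumericVector& kernel, const int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const int K = kernel.size();
  const int half = K / 2;
  NumericVector out(vol.size());
  const int n_axis = (axis == 1) ? nx : (axis == 2) ? ny : nz;
  const R_xlen_t stride = (axis == 1) ? 1 : (axis == 2) ? nx : nxy;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        const int pos = (axis == 1) ? i : (axis == 2) ? j : k;
        double acc = 0.0;
        for (int t = -half; t <= half; ++t) {
          int p = pos + t;
          if (p < 0) p = 0;
          if (p > n_axis - 1) p = n_axis - 1;
          acc += kernel[t + half] * vol[idx + (R_xlen_t)(p - pos) * stride];
        }
        out[idx] = acc;
      }
    }
  }
  return out;
}

// One box-filter pass (width w, odd) along an axis with replicate padding;
// three passes approximate a Gaussian. Running-sum, O(n) per pass.
static void box_pass(std::vector<double>& v, std::vector<double>& tmp,
                     const int nx, const int ny, const int nz,
                     const int axis, const int w) {
  const int h = w / 2;
  const int n_axis = (axis == 1) ? nx : (axis == 2) ? ny : nz;
  const R_xlen_t stride = (axis == 1) ? 1 : (axis == 2) ? (R_xlen_t)nx
                                                        : (R_xlen_t)nx * ny;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const double inv = 1.0 / w;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if ((axis == 1 && i > 0) || (axis == 2 && j > 0) || (axis == 3 && k > 0))
          continue;  // only line starts
        R_xlen_t base = i + (R_xlen_t)j * nx + (R_xlen_t)k * nxy;
        double s = 0.0;
        for (int t = -h; t <= h; ++t) {
          int p = t < 0 ? 0 : (t > n_axis - 1 ? n_axis - 1 : t);
          s += v[base + (R_xlen_t)p * stride];
        }
        for (int p = 0; p < n_axis; ++p) {
          tmp[base + (R_xlen_t)p * stride] = s * inv;
          int add = p + h + 1; if (add > n_axis - 1) add = n_axis - 1;
          int sub = p - h; if (sub < 0) sub = 0;
          s += v[base + (R_xlen_t)add * stride] - v[base + (R_xlen_t)sub * stride];
        }
      }
    }
  }
  v.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_box_smooth3(const NumericVector& vol, const IntegerVector& dim,
                              const IntegerVector& width) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end()), tmp(vol.size());
  for (int ax = 1; ax <= 3; ++ax) {
    const int w = width[ax - 1];
    if (w <= 1) continue;
    const int n_axis = (ax == 1) ? nx : (ax == 2) ? ny : nz;
    if (n_axis <= 1) continue;
    for (int pass = 0; pass < 3; ++pass) box_pass(v, tmp, nx, ny, nz, ax, w);
  }
  return NumericVector(v.begin(), v.end());
}

// Fused energy-descent direction: g_i = r * d(warped)/dx_i - lambda * lap(u_i)
// with r = warped - fixed inside the ROI (zero outside). Central differences
// inside, one-sided at faces; Laplacian with replicate boundary.
// [[Rcpp::export]]
List cpp_descent_force(const NumericVector& w, const NumericVector& IA,
                       const LogicalVector& roi,
                       const NumericVector& u1, const NumericVector& u2,
                       const NumericVector& u3,
                       const IntegerVector& dim, const NumericVector& spacing,
                       const double lambda) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const bool use_roi = roi.size() == w.size();
  NumericVector g1(w.size()), g2(w.size()), g3(w.size());
  const double hx2 = 2 * spacing[0], hy2 = 2 * spacing[1], hz2 = 2 * spacing[2];
  const double wx = 1.0 / (spacing[0] * spacing[0]);
  const double wy = 1.0 / (spacing[1] * spacing[1]);
  const double wz = 1.0 / (spacing[2] * spacing[2]);
  const NumericVector* us[3] = { &u1, &u2, &u3 };
  NumericVector* gs[3] = { &g1, &g2, &g3 };
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        double r = (!use_roi || roi[idx]) ? (w[idx] - IA[idx]) : 0.0;
        double gx = 0, gy = 0, gz = 0;
        if (nx > 1) {
          if (i == 0) gx = (w[idx + 1] - w[idx]) / spacing[0];
          else if (i == nx - 1) gx = (w[idx] - w[idx - 1]) / spacing[0];
          else gx = (w[idx + 1] - w[idx - 1]) / hx2;
        }
        if (ny > 1) {
          if (j == 0) gy = (w[idx + nx] - w[idx]) / spacing[1];
          else if (j == ny - 1) gy = (w[idx] - w[idx - nx]) / spacing[1];
          else gy = (w[idx + nx] - w[idx - nx]) / hy2;
        }
        if (nz > 1) {
          if (k == 0) gz = (w[idx + nxy] - w[idx]) / spacing[2];
          else if (k == nz - 1) gz = (w[idx] - w[idx - nxy]) / spacing[2];
          else gz = (w[idx + nxy] - w[idx - nxy]) / hz2;
        }
        (*gs[0])[idx] = r * gx;
        (*gs[1])[idx] = r * gy;
        (*gs[2])[idx] = r * gz;
        if (lambda > 0) {
          for (int c = 0; c < 3; ++c) {
            const NumericVector& u = *us[c];
            double cc = u[idx], lap = 0.0;
            if (nx > 1) {
              double xm = (i > 0) ? u[idx - 1] : cc;
              double xp = (i < nx - 1) ? u[idx + 1] : cc;
              lap += wx * (xm + xp - 2 * cc);
            }
            if (ny > 1) {
              double ym = (j > 0) ? u[idx - nx] : cc;
              double yp = (j < ny - 1) ? u[idx + nx] : cc;
              lap += wy * (ym + yp - 2 * cc);
            }
            if (nz > 1) {
              double zm = (k > 0) ? u[idx - nxy] : cc;
              double zp = (k < nz - 1) ? u[idx + nxy] : cc;
              lap += wz * (zm + zp - 2 * cc);
            }
            (*gs[c])[idx] -= lambda * lap;
          }
        }
      }
    }
  }
  return List::create(g1, g2, g3);
}

// [[Rcpp::export]]
double cpp_ssd(const NumericVector& w, const NumericVector& IA,
               const LogicalVector& roi) {
  const bool use_roi = roi.size() == w.size();
  double s = 0.0;
  for (R_xlen_t i = 0; i < w.size(); ++i) {
    if (use_roi && !roi[i]) continue;
    double r = w[i] - IA[i];
    s += r * r;
  }
  return s;
}

// total squared gradient magnitude of a scalar field, same difference
// conventions as cpp_gradient3
// [[Rcpp::export]]
double cpp_grad_sq_sum(const NumericVector& vol, const IntegerVector& dim,
                       const NumericVector& spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  double s = 0.0;
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        double g;
        if (nx > 1) {
          if (i == 0) g = (vol[idx + 1] - vol[idx]) / hx;
          else if (i == nx - 1) g = (vol[idx] - vol[idx - 1]) / hx;
          else g = (vol[idx + 1] - vol[idx - 1]) / (2 * hx);
          s += g * g;
        }
        if (ny > 1) {
          if (j == 0) g = (vol[idx + nx] - vol[idx]) / hy;
          else if (j == ny - 1) g = (vol[idx] - vol[idx - nx]) / hy;
          else g = (vol[idx + nx] - vol[idx - nx]) / (2 * hy);
          s += g * g;
        }
        if (nz > 1) {
          if (k == 0) g = (vol[idx + nxy] - vol[idx]) / hz;
          else if (k == nz - 1) g = (vol[idx] - vol[idx - nxy]) / hz;
          else g = (vol[idx + nxy] - vol[idx - nxy]) / (2 * hz);
          s += g * g;
        }
      }
    }
  }
  return s;
}
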