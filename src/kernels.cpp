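// Low-level numeric kernels: 3D im2col/col2im for convolution via GEMM,
// a parallel-beam projector/backprojector pair, and 6-connected component
// labelling. All arrays are column-major, matching R's layout.
#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline int out_dim(int d, int k, int pad, int stride) {
  return (d + 2 * pad - k) / stride + 1;
}

// x: (nx, ny, nz, C) array flattened column-major.
// Returns matrix [n_out_voxels x k^3*C]; row order follows column-major
// (ox fastest) order of the output grid; column index = kx + k*(ky + k*(kz + k*c)).
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector x, IntegerVector dims,
                          int k, int pad, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int ox = out_dim(nx, k, pad, stride);
  const int oy = out_dim(ny, k, pad, stride);
  const int oz = out_dim(nz, k, pad, stride);
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  NumericMatrix out(nout, (R_xlen_t)k * k * k * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* ch = px + (R_xlen_t)c * nx * ny * nz;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int col = kx + k * (ky + k * (kz + k * c));
          double* po = &out(0, col);
          // valid output range along x for this kernel offset
          int x_lo = 0, x_hi = ox;
          while (x_lo < ox && x_lo * stride - pad + kx < 0) ++x_lo;
          while (x_hi > x_lo && (x_hi - 1) * stride - pad + kx >= nx) --x_hi;
          for (int z = 0; z < oz; ++z) {
            const int iz = z * stride - pad + kz;
            const bool okz = iz >= 0 && iz < nz;
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride - pad + ky;
              R_xlen_t r = ((R_xlen_t)z * oy + y) * ox;
              if (!okz || iy < 0 || iy >= ny) {
                std::fill(po + r, po + r + ox, 0.0);
                continue;
              }
              const double* src = ch + ((R_xlen_t)iz * ny + iy) * nx;
              if (x_lo > 0) std::fill(po + r, po + r + x_lo, 0.0);
              if (x_hi < ox) std::fill(po + r + x_hi, po + r + ox, 0.0);
              if (stride == 1) {
                std::memcpy(po + r + x_lo, src + x_lo - pad + kx,
                            (x_hi - x_lo) * sizeof(double));
              } else {
                for (int xw = x_lo; xw < x_hi; ++xw)
                  po[r + xw] = src[xw * stride - pad + kx];
              }
            }
          }
        }
  }
  return out;
}

// Transpose of im2col: scatter-add columns of `cols` back into an input-
// shaped gradient array of dims (nx, ny, nz, C).
// [[Rcpp::export]]
NumericVector cpp_col2im3(NumericMatrix cols, IntegerVector dims,
                          int k, int pad, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int ox = out_dim(nx, k, pad, stride);
  const int oy = out_dim(ny, k, pad, stride);
  const int oz = out_dim(nz, k, pad, stride);
  NumericVector out((R_xlen_t)nx * ny * nz * C);
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    double* ch = po + (R_xlen_t)c * nx * ny * nz;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int col = kx + k * (ky + k * (kz + k * c));
          const double* pc = &cols(0, col);
          int x_lo = 0, x_hi = ox;
          while (x_lo < ox && x_lo * stride - pad + kx < 0) ++x_lo;
          while (x_hi > x_lo && (x_hi - 1) * stride - pad + kx >= nx) --x_hi;
          for (int z = 0; z < oz; ++z) {
            const int iz = z * stride - pad + kz;
            if (iz < 0 || iz >= nz) continue;
            for (int y = 0; y < oy; ++y) {
              const int iy = y * stride - pad + ky;
              if (iy < 0 || iy >= ny) continue;
              const R_xlen_t r = ((R_xlen_t)z * oy + y) * ox;
              double* dst = ch + ((R_xlen_t)iz * ny + iy) * nx - pad + kx;
              if (stride == 1)
                for (int xw = x_lo; xw < x_hi; ++xw) dst[xw] += pc[r + xw];
              else
                for (int xw = x_lo; xw < x_hi; ++xw)
                  dst[xw * stride] += pc[r + xw];
            }
          }
        }
  }
  return out;
}

// Parallel-beam forward projection, slice by slice along z.
// mu: attenuation volume (nx, ny, nz) in 1/mm; in-plane grid centred on the
// rotation axis. Returns (n_det, n_angles, nz) line integrals (dimensionless).
// Ray for (detector j, angle a): passes through (s*cos a, s*sin a) with
// direction (-sin a, cos a); sampled every step_mm with bilinear interpolation.
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector mu, IntegerVector dims,
                                  double dx, double dy,
                                  int n_det, double det_pitch,
                                  NumericVector angles, double step_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles.size();
  NumericVector sino((R_xlen_t)n_det * na * nz);
  const double x0 = -0.5 * (nx - 1) * dx;
  const double y0 = -0.5 * (ny - 1) * dy;
  const double half_diag = 0.5 * std::sqrt((double)nx * nx * dx * dx +
                                           (double)ny * ny * dy * dy);
  const double tmax = half_diag + step_mm;
  const int nsteps = (int)std::ceil(2.0 * tmax / step_mm);
  const double* pmu = mu.begin();
  double* ps = sino.begin();
  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int j = 0; j < n_det; ++j) {
      const double s = (j - 0.5 * (n_det - 1)) * det_pitch;
      const double bx = s * ca, by = s * sa;
      for (int z = 0; z < nz; ++z) {
        const double* sl = pmu + (R_xlen_t)z * nx * ny;
        double acc = 0.0;
        for (int t = 0; t <= nsteps; ++t) {
          const double tt = -tmax + t * step_mm;
          const double wx = bx - tt * sa, wy = by + tt * ca;
          const double fx = (wx - x0) / dx, fy = (wy - y0) / dy;
          const int ix = (int)std::floor(fx), iy = (int)std::floor(fy);
          if (ix < 0 || ix >= nx - 1 || iy < 0 || iy >= ny - 1) continue;
          const double ax = fx - ix, ay = fy - iy;
          const double* p00 = sl + (R_xlen_t)iy * nx + ix;
          const double v = (1 - ax) * (1 - ay) * p00[0] + ax * (1 - ay) * p00[1] +
                           (1 - ax) * ay * p00[nx] + ax * ay * p00[nx + 1];
          acc += v;
        }
        ps[(R_xlen_t)z * n_det * na + (R_xlen_t)a * n_det + j] = acc * step_mm;
      }
    }
  }
  sino.attr("dim") = IntegerVector::create(n_det, na, nz);
  return sino;
}

// Backprojection of ramp-filtered projections q (n_det, n_angles, nz) onto an
// (nx, ny, nz) grid; caller applies the pi/n_angles FBP weight.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector q, IntegerVector qdims,
                              int nx, int ny, double dx, double dy,
                              double det_pitch, NumericVector angles) {
  const int n_det = qdims[0], na = qdims[1], nz = qdims[2];
  NumericVector vol((R_xlen_t)nx * ny * nz);
  const double x0 = -0.5 * (nx - 1) * dx;
  const double y0 = -0.5 * (ny - 1) * dy;
  const double s0 = -0.5 * (n_det - 1) * det_pitch;
  const double* pq = q.begin();
  double* pv = vol.begin();
  std::vector<double> cs(na), sn(na);
  for (int a = 0; a < na; ++a) { cs[a] = std::cos(angles[a]); sn[a] = std::sin(angles[a]); }
  for (int z = 0; z < nz; ++z) {
    const double* qs = pq + (R_xlen_t)z * n_det * na;
    double* sl = pv + (R_xlen_t)z * nx * ny;
    for (int a = 0; a < na; ++a) {
      const double* qa = qs + (R_xlen_t)a * n_det;
      const double ca = cs[a], sa = sn[a];
      R_xlen_t idx = 0;
      for (int y = 0; y < ny; ++y) {
        const double wy = y0 + y * dy;
        for (int x = 0; x < nx; ++x, ++idx) {
          const double wx = x0 + x * dx;
          const double s = wx * ca + wy * sa;
          const double fj = (s - s0) / det_pitch;
          const int j = (int)std::floor(fj);
          if (j < 0 || j >= n_det - 1) continue;
          const double aj = fj - j;
          sl[idx] += (1 - aj) * qa[j] + aj * qa[j + 1];
        }
      }
    }
  }
  vol.attr("dim") = IntegerVector::create(nx, ny, nz);
  return vol;
}

// 6-connected component labelling of a binary mask (nx, ny, nz).
// Returns integer labels 0 (off) / 1..n_components, BFS order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  const int dxs[6] = {-1, 1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, -1, 1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      const R_xlen_t cur = q.front(); q.pop();
      const int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / ((R_xlen_t)nx * ny);
      for (int d = 0; d < 6; ++d) {
        const int ax = cx + dxs[d], ay = cy + dys[d], az = cz + dzs[d];
        if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz) continue;
        const R_xlen_t ni = ((R_xlen_t)az * ny + ay) * nx + ax;
        if (mask[ni] && !lab[ni]) { lab[ni] = next; q.push(ni); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
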