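// Numeric kernels for voxel rasterization, the 3D convolutional network and
// layer-wise relevance propagation.
//
// Tensor layout: a C-channel cubic image of edge D is a numeric vector of
// length C*D^3 with the channel index fastest:
//   t[c + C*(ix + D*(iy + D*iz))],  0-based c, ix, iy, iz.
// Convolution weights for Cin -> Cout with a 3^3 kernel are stored as
//   w[ci + Cin*(co + Cout*(kx + 3*(ky + 3*kz)))].
// These layouts make the hot inner loops contiguous dot products / axpy
// updates over the input channels.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Piece-wise continuous atom density: exp(-2r^2/R^2) inside the vdW radius,
// a quadratic tail that reaches zero at 1.5 R, zero beyond.
static inline double density_kernel_c(double r, double R) {
  if (r < 0.0) return 0.0;
  if (r < R) return std::exp(-2.0 * r * r / (R * R));
  if (r < 1.5 * R) {
    const double e2 = std::exp(2.0);
    return 4.0 * r * r / (e2 * R * R) - 12.0 * r / (e2 * R) + 9.0 / e2;
  }
  return 0.0;
}

// [[Rcpp::export(name = ".density_kernel_cpp")]]
NumericVector density_kernel_cpp(NumericVector r, double R) {
  if (R <= 0) stop("vdW radius must be positive");
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) out[i] = density_kernel_c(r[i], R);
  return out;
}

// Sum typed atom densities onto per-type channels.
// coords: n x 3 matrix (Angstrom); type_idx: 1-based channel index per atom;
// origin: position of the *center* of voxel (0,0,0).
// [[Rcpp::export(name = ".rasterize_cpp")]]
NumericVector rasterize_cpp(NumericMatrix coords, NumericVector radii,
                            IntegerVector type_idx, int n_types,
                            NumericVector origin, double spacing, int D) {
  const int n = coords.nrow();
  NumericVector out(static_cast<R_xlen_t>(n_types) * D * D * D);
  for (int a = 0; a < n; ++a) {
    const int c = type_idx[a] - 1;
    if (c < 0 || c >= n_types) stop("atom type index out of range");
    const double R = radii[a];
    const double cut = 1.5 * R;
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    // voxel index range overlapping the kernel support
    int lo[3], hi[3];
    const double pos[3] = {ax, ay, az};
    bool outside = false;
    for (int d = 0; d < 3; ++d) {
      lo[d] = (int)std::ceil((pos[d] - cut - origin[d]) / spacing);
      hi[d] = (int)std::floor((pos[d] + cut - origin[d]) / spacing);
      if (lo[d] < 0) lo[d] = 0;
      if (hi[d] > D - 1) hi[d] = D - 1;
      if (lo[d] > hi[d]) outside = true;
    }
    if (outside) continue;
    for (int iz = lo[2]; iz <= hi[2]; ++iz) {
      const double dz = origin[2] + iz * spacing - az;
      for (int iy = lo[1]; iy <= hi[1]; ++iy) {
        const double dy = origin[1] + iy * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        for (int ix = lo[0]; ix <= hi[0]; ++ix) {
          const double dx = origin[0] + ix * spacing - ax;
          const double r = std::sqrt(dx * dx + dyz2);
          if (r < cut) {
            const R_xlen_t idx =
                c + (R_xlen_t)n_types * (ix + (R_xlen_t)D * (iy + (R_xlen_t)D * iz));
            out[idx] += density_kernel_c(r, R);
          }
        }
      }
    }
  }
  return out;
}

// 3D convolution, kernel 3, stride 1, zero padding 1 (same-size output).
// [[Rcpp::export(name = ".conv3d_fwd_cpp")]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int Cin, int Cout, int D) {
  NumericVector y(static_cast<R_xlen_t>(Cout) * D * D * D);
  const double *xp = x.begin(), *wp = w.begin();
  double *yp = y.begin();
  for (int oz = 0; oz < D; ++oz)
    for (int oy = 0; oy < D; ++oy)
      for (int ox = 0; ox < D; ++ox) {
        double *yv = yp + (R_xlen_t)Cout * (ox + (R_xlen_t)D * (oy + (R_xlen_t)D * oz));
        for (int co = 0; co < Cout; ++co) yv[co] = b[co];
        for (int kz = 0; kz < 3; ++kz) {
          const int iz = oz + kz - 1;
          if (iz < 0 || iz >= D) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int iy = oy + ky - 1;
            if (iy < 0 || iy >= D) continue;
            for (int kx = 0; kx < 3; ++kx) {
              const int ix = ox + kx - 1;
              if (ix < 0 || ix >= D) continue;
              const double *xv = xp + (R_xlen_t)Cin * (ix + (R_xlen_t)D * (iy + (R_xlen_t)D * iz));
              const double *wk = wp + (R_xlen_t)Cin * Cout * (kx + 3 * (ky + 3 * kz));
              for (int co = 0; co < Cout; ++co) {
                const double *wc = wk + (R_xlen_t)Cin * co;
                double s = 0.0;
                for (int ci = 0; ci < Cin; ++ci) s += xv[ci] * wc[ci];
                yv[co] += s;
              }
            }
          }
        }
      }
  return y;
}

// Gradient wrt input: full correlation with flipped kernel, done by looping
// over output positions and scattering into dx.
// [[Rcpp::export(name = ".conv3d_bwd_x_cpp")]]
NumericVector conv3d_bwd_x_cpp(NumericVector dy, NumericVector w,
                               int Cin, int Cout, int D) {
  NumericVector dx(static_cast<R_xlen_t>(Cin) * D * D * D);
  const double *dyp = dy.begin(), *wp = w.begin();
  double *dxp = dx.begin();
  for (int oz = 0; oz < D; ++oz)
    for (int oy = 0; oy < D; ++oy)
      for (int ox = 0; ox < D; ++ox) {
        const double *dyv = dyp + (R_xlen_t)Cout * (ox + (R_xlen_t)D * (oy + (R_xlen_t)D * oz));
        for (int kz = 0; kz < 3; ++kz) {
          const int iz = oz + kz - 1;
          if (iz < 0 || iz >= D) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int iy = oy + ky - 1;
            if (iy < 0 || iy >= D) continue;
            for (int kx = 0; kx < 3; ++kx) {
              const int ix = ox + kx - 1;
              if (ix < 0 || ix >= D) continue;
              double *dxv = dxp + (R_xlen_t)Cin * (ix + (R_xlen_t)D * (iy + (R_xlen_t)D * iz));
              const double *wk = wp + (R_xlen_t)Cin * Cout * (kx + 3 * (ky + 3 * kz));
              for (int co = 0; co < Cout; ++co) {
                const double g = dyv[co];
                if (g == 0.0) continue;
                const double *wc = wk + (R_xlen_t)Cin * co;
                for (int ci = 0; ci < Cin; ++ci) dxv[ci] += g * wc[ci];
              }
            }
          }
        }
      }
  return dx;
}

// Gradients wrt weights and biases.
// [[Rcpp::export(name = ".conv3d_bwd_w_cpp")]]
List conv3d_bwd_w_cpp(NumericVector x, NumericVector dy,
                      int Cin, int Cout, int D) {
  NumericVector dw(static_cast<R_xlen_t>(Cout) * Cin * 27);
  NumericVector db(Cout);
  const double *xp = x.begin(), *dyp = dy.begin();
  double *dwp = dw.begin();
  for (int oz = 0; oz < D; ++oz)
    for (int oy = 0; oy < D; ++oy)
      for (int ox = 0; ox < D; ++ox) {
        const double *dyv = dyp + (R_xlen_t)Cout * (ox + (R_xlen_t)D * (oy + (R_xlen_t)D * oz));
        for (int co = 0; co < Cout; ++co) db[co] += dyv[co];
        for (int kz = 0; kz < 3; ++kz) {
          const int iz = oz + kz - 1;
          if (iz < 0 || iz >= D) continue;
          for (int ky = 0; ky < 3; ++ky) {
            const int iy = oy + ky - 1;
            if (iy < 0 || iy >= D) continue;
            for (int kx = 0; kx < 3; ++kx) {
              const int ix = ox + kx - 1;
              if (ix < 0 || ix >= D) continue;
              const double *xv = xp + (R_xlen_t)Cin * (ix + (R_xlen_t)D * (iy + (R_xlen_t)D * iz));
              double *wk = dwp + (R_xlen_t)Cin * Cout * (kx + 3 * (ky + 3 * kz));
              for (int co = 0; co < Cout; ++co) {
                const double g = dyv[co];
                if (g == 0.0) continue;
                double *wc = wk + (R_xlen_t)Cin * co;
                for (int ci = 0; ci < Cin; ++ci) wc[ci] += g * xv[ci];
              }
            }
          }
        }
      }
  return List::create(_["dw"] = dw, _["db"] = db);
}

// 2x2x2 max pooling; records the 1-based linear argmax (first maximum) for
// the training backward pass.
// [[Rcpp::export(name = ".maxpool_fwd_cpp")]]
List maxpool_fwd_cpp(NumericVector x, int C, int D) {
  if (D % 2 != 0) stop("max pooling requires an even edge length");
  const int Do = D / 2;
  NumericVector y(static_cast<R_xlen_t>(C) * Do * Do * Do);
  IntegerVector amax(y.size());
  const double *xp = x.begin();
  for (int oz = 0; oz < Do; ++oz)
    for (int oy = 0; oy < Do; ++oy)
      for (int ox = 0; ox < Do; ++ox)
        for (int c = 0; c < C; ++c) {
          double best = -1e300;
          R_xlen_t bidx = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy_ = 0; dy_ < 2; ++dy_)
              for (int dx_ = 0; dx_ < 2; ++dx_) {
                const int ix = 2 * ox + dx_, iy = 2 * oy + dy_, iz = 2 * oz + dz;
                const R_xlen_t idx = c + (R_xlen_t)C * (ix + (R_xlen_t)D * (iy + (R_xlen_t)D * iz));
                if (xp[idx] > best) { best = xp[idx]; bidx = idx; }
              }
          const R_xlen_t oidx = c + (R_xlen_t)C * (ox + (R_xlen_t)Do * (oy + (R_xlen_t)Do * oz));
          y[oidx] = best;
          amax[oidx] = (int)(bidx + 1);
        }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool_bwd_cpp")]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector amax, R_xlen_t nx) {
  NumericVector dx(nx);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[amax[i] - 1] += dy[i];
  return dx;
}

// z+ rule relevance propagation through a 3^3/stride-1/pad-1 convolution.
// For each output node j: skip if the pre-activation is negative (gating) or
// the positive-part denominator vanishes; otherwise distribute R_j over its
// receptive field in proportion to x_i * max(w_ij, 0).
// [[Rcpp::export(name = ".lrp_conv_cpp")]]
NumericVector lrp_conv_cpp(NumericVector x, NumericVector w, NumericVector b,
                           NumericVector Rup, int Cin, int Cout, int D) {
  NumericVector Rlow(static_cast<R_xlen_t>(Cin) * D * D * D);
  const double *xp = x.begin(), *wp = w.begin();
  double *rp = Rlow.begin();
  for (int oz = 0; oz < D; ++oz)
    for (int oy = 0; oy < D; ++oy)
      for (int ox = 0; ox < D; ++ox) {
        const R_xlen_t obase = (R_xlen_t)Cout * (ox + (R_xlen_t)D * (oy + (R_xlen_t)D * oz));
        for (int co = 0; co < Cout; ++co) {
          const double Rj = Rup[obase + co];
          if (Rj == 0.0) continue;
          // first pass: pre-activation and z+ denominator
          double pre = b[co], denom = 0.0;
          for (int kz = 0; kz < 3; ++kz) {
            const int iz = oz + kz - 1;
            if (iz < 0 || iz >= D) continue;
            for (int ky = 0; ky < 3; ++ky) {
              const int iy = oy + ky - 1;
              if (iy < 0 || iy >= D) continue;
              for (int kx = 0; kx < 3; ++kx) {
                const int ix = ox + kx - 1;
                if (ix < 0 || ix >= D) continue;
                const double *xv = xp + (R_xlen_t)Cin * (ix + (R_xlen_t)D * (iy + (R_xlen_t)D * iz));
                const double *wc = wp + (R_xlen_t)Cin * (co + (R_xlen_t)Cout * (kx + 3 * (ky + 3 * kz)));
                for (int ci = 0; ci < Cin; ++ci) {
                  const double z = xv[ci] * wc[ci];
                  pre += z;
                  if (z > 0.0) denom += z;
                }
              }
            }
          }
          if (pre < 0.0 || denom <= 0.0) continue;
          const double scale = Rj / denom;
          for (int kz = 0; kz < 3; ++kz) {
            const int iz = oz + kz - 1;
            if (iz < 0 || iz >= D) continue;
            for (int ky = 0; ky < 3; ++ky) {
              const int iy = oy + ky - 1;
              if (iy < 0 || iy >= D) continue;
              for (int kx = 0; kx < 3; ++kx) {
                const int ix = ox + kx - 1;
                if (ix < 0 || ix >= D) continue;
                const double *xv = xp + (R_xlen_t)Cin * (ix + (R_xlen_t)D * (iy + (R_xlen_t)D * iz));
                double *rv = rp + (R_xlen_t)Cin * (ix + (R_xlen_t)D * (iy + (R_xlen_t)D * iz));
                const double *wc = wp + (R_xlen_t)Cin * (co + (R_xlen_t)Cout * (kx + 3 * (ky + 3 * kz)));
                for (int ci = 0; ci < Cin; ++ci) {
                  const double z = xv[ci] * wc[ci];
                  if (z > 0.0) rv[ci] += scale * z;
                }
              }
            }
          }
        }
      }
  return Rlow;
}

// Relevance propagation through 2x2x2 max pooling: each output's relevance
// goes to the maximal input(s) of its window, ties split equally.
// [[Rcpp::export(name = ".lrp_pool_cpp")]]
NumericVector lrp_pool_cpp(NumericVector x, NumericVector Rup, int C, int D) {
  if (D % 2 != 0) stop("max pooling requires an even edge length");
  const int Do = D / 2;
  NumericVector Rlow(x.size());
  const double *xp = x.begin();
  R_xlen_t winners[8];
  for (int oz = 0; oz < Do; ++oz)
    for (int oy = 0; oy < Do; ++oy)
      for (int ox = 0; ox < Do; ++ox)
        for (int c = 0; c < C; ++c) {
          const R_xlen_t oidx = c + (R_xlen_t)C * (ox + (R_xlen_t)Do * (oy + (R_xlen_t)Do * oz));
          const double Rj = Rup[oidx];
          if (Rj == 0.0) continue;
          double best = -1e300;
          int nwin = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy_ = 0; dy_ < 2; ++dy_)
              for (int dx_ = 0; dx_ < 2; ++dx_) {
                const int ix = 2 * ox + dx_, iy = 2 * oy + dy_, iz = 2 * oz + dz;
                const R_xlen_t idx = c + (R_xlen_t)C * (ix + (R_xlen_t)D * (iy + (R_xlen_t)D * iz));
                if (xp[idx] > best) { best = xp[idx]; nwin = 0; winners[nwin++] = idx; }
                else if (xp[idx] == best) winners[nwin++] = idx;
              }
          const double share = Rj / nwin;
          for (int k = 0; k < nwin; ++k) Rlow[winners[k]] += share;
        }
  return Rlow;
}
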