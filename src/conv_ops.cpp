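#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// 3D cross-correlation with "same" zero padding.
// input: [nx, ny, nz, Cin] column-major; w: [kx, ky, kz, Cin, Cout]; bias: [Cout].
// out[x,y,z,co] = bias[co] + sum_{ci,d} in[x+dx-cx, y+dy-cy, z+dz-cz, ci] * w[dx,dy,dz,ci,co]
// Loop order keeps the x sweep contiguous so the compiler can vectorize.
// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector input, IntegerVector idim,
                         NumericVector w, IntegerVector kdim,
                         NumericVector bias) {
  const int nx = idim[0], ny = idim[1], nz = idim[2], nci = idim[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2], nco = kdim[4];
  const int cx = kx / 2, cy = ky / 2, cz = kz / 2;
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox * nco);
  const double *pin = REAL(input), *pw = REAL(w);
  double *pout = REAL(out);

  for (int co = 0; co < nco; ++co) {
    double *o = pout + (size_t)co * nvox;
    const double b = bias[co];
    for (size_t i = 0; i < nvox; ++i) o[i] = b;
    for (int ci = 0; ci < nci; ++ci) {
      const double *in = pin + (size_t)ci * nvox;
      for (int dz = 0; dz < kz; ++dz)
        for (int dy = 0; dy < ky; ++dy)
          for (int dx = 0; dx < kx; ++dx) {
            const double wv =
                pw[dx + (size_t)kx * (dy + (size_t)ky * (dz + (size_t)kz * (ci + (size_t)nci * co)))];
            if (wv == 0.0) continue;
            const int ox = dx - cx, oy = dy - cy, oz = dz - cz;
            const int z0 = std::max(0, -oz), z1 = std::min(nz, nz - oz);
            const int y0 = std::max(0, -oy), y1 = std::min(ny, ny - oy);
            const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
            const int len = x1 - x0;
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                double *orow = o + x0 + (size_t)nx * (y + (size_t)ny * z);
                const double *irow =
                    in + (x0 + ox) + (size_t)nx * ((y + oy) + (size_t)ny * (z + oz));
                for (int x = 0; x < len; ++x) orow[x] += wv * irow[x];
              }
          }
    }
  }
  return out;
}

// Gradient w.r.t. the input of conv3d_fwd.
// gout: [nx,ny,nz,Cout]; returns [nx,ny,nz,Cin].
// gin[u,ci] = sum_{co,d} w[d,ci,co] * gout[u - (d - c), co]
// [[Rcpp::export]]
NumericVector conv3d_bwd_input(NumericVector gout, IntegerVector idim,
                               NumericVector w, IntegerVector kdim) {
  const int nx = idim[0], ny = idim[1], nz = idim[2], nci = idim[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2], nco = kdim[4];
  const int cx = kx / 2, cy = ky / 2, cz = kz / 2;
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector gin(nvox * nci);
  const double *pg = REAL(gout), *pw = REAL(w);
  double *pi = REAL(gin);

  for (int ci = 0; ci < nci; ++ci) {
    double *gi = pi + (size_t)ci * nvox;
    for (int co = 0; co < nco; ++co) {
      const double *go = pg + (size_t)co * nvox;
      for (int dz = 0; dz < kz; ++dz)
        for (int dy = 0; dy < ky; ++dy)
          for (int dx = 0; dx < kx; ++dx) {
            const double wv =
                pw[dx + (size_t)kx * (dy + (size_t)ky * (dz + (size_t)kz * (ci + (size_t)nci * co)))];
            if (wv == 0.0) continue;
            const int ox = cx - dx, oy = cy - dy, oz = cz - dz;
            const int z0 = std::max(0, -oz), z1 = std::min(nz, nz - oz);
            const int y0 = std::max(0, -oy), y1 = std::min(ny, ny - oy);
            const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
            const int len = x1 - x0;
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                double *grow = gi + x0 + (size_t)nx * (y + (size_t)ny * z);
                const double *gorow =
                    go + (x0 + ox) + (size_t)nx * ((y + oy) + (size_t)ny * (z + oz));
                for (int x = 0; x < len; ++x) grow[x] += wv * gorow[x];
              }
          }
    }
  }
  return gin;
}

// Gradient w.r.t. the weights of conv3d_fwd.
// gw[d,ci,co] = sum_x in[x + d - c, ci] * gout[x, co]
// [[Rcpp::export]]
NumericVector conv3d_bwd_weights(NumericVector input, IntegerVector idim,
                                 NumericVector gout, IntegerVector kdim) {
  const int nx = idim[0], ny = idim[1], nz = idim[2], nci = idim[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2], nco = kdim[4];
  const int cx = kx / 2, cy = ky / 2, cz = kz / 2;
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector gw((size_t)kx * ky * kz * nci * nco);
  const double *pin = REAL(input), *pg = REAL(gout);
  double *pw = REAL(gw);

  for (int co = 0; co < nco; ++co) {
    const double *go = pg + (size_t)co * nvox;
    for (int ci = 0; ci < nci; ++ci) {
      const double *in = pin + (size_t)ci * nvox;
      for (int dz = 0; dz < kz; ++dz)
        for (int dy = 0; dy < ky; ++dy)
          for (int dx = 0; dx < kx; ++dx) {
            const int ox = dx - cx, oy = dy - cy, oz = dz - cz;
            const int z0 = std::max(0, -oz), z1 = std::min(nz, nz - oz);
            const int y0 = std::max(0, -oy), y1 = std::min(ny, ny - oy);
            const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
            const int len = x1 - x0;
            double acc = 0.0;
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                const double *gorow = go + x0 + (size_t)nx * (y + (size_t)ny * z);
                const double *irow =
                    in + (x0 + ox) + (size_t)nx * ((y + oy) + (size_t)ny * (z + oz));
                for (int x = 0; x < len; ++x) acc += gorow[x] * irow[x];
              }
            pw[dx + (size_t)kx * (dy + (size_t)ky * (dz + (size_t)kz * (ci + (size_t)nci * co)))] = acc;
          }
    }
  }
  return gw;
}

// 2x2x2 max pooling, stride 2, floor on odd dims. Returns pooled values and the
// 0-based linear argmax indices into the input (for the backward scatter).
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector input, IntegerVector idim) {
  const int nx = idim[0], ny = idim[1], nz = idim[2], nc = idim[3];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const size_t nvox = (size_t)nx * ny * nz, mvox = (size_t)mx * my * mz;
  NumericVector out(mvox * nc);
  IntegerVector arg(mvox * nc);
  const double *pin = REAL(input);
  double *po = REAL(out);
  int *pa = INTEGER(arg);

  for (int c = 0; c < nc; ++c) {
    const double *in = pin + (size_t)c * nvox;
    double *o = po + (size_t)c * mvox;
    int *a = pa + (size_t)c * mvox;
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y)
        for (int x = 0; x < mx; ++x) {
          double best = -HUGE_VAL;
          size_t bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const size_t ii =
                    (2 * x + dx) + (size_t)nx * ((2 * y + dy) + (size_t)ny * (2 * z + dz));
                const double v = in[ii];
                if (v > best) { best = v; bidx = ii; }
              }
          const size_t oi = x + (size_t)mx * (y + (size_t)my * z);
          o[oi] = best;
          a[oi] = (int)(bidx + (size_t)c * nvox);
        }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// Trilinear resize of a single-channel volume to a new grid; cell-centered
// coordinate mapping with edge clamping.
// [[Rcpp::export]]
NumericVector resize_trilinear(NumericVector input, IntegerVector idim,
                               IntegerVector odim) {
  const int nx = idim[0], ny = idim[1], nz = idim[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double *in = REAL(input);
  double *o = REAL(out);
  const double sx = (double)nx / ox, sy = (double)ny / oy, sz = (double)nz / oz;

  for (int z = 0; z < oz; ++z) {
    double fz = (z + 0.5) * sz - 0.5;
    fz = std::min(std::max(fz, 0.0), (double)(nz - 1));
    const int z0 = (int)fz, z1 = std::min(z0 + 1, nz - 1);
    const double tz = fz - z0;
    for (int y = 0; y < oy; ++y) {
      double fy = (y + 0.5) * sy - 0.5;
      fy = std::min(std::max(fy, 0.0), (double)(ny - 1));
      const int y0 = (int)fy, y1 = std::min(y0 + 1, ny - 1);
      const double ty = fy - y0;
      for (int x = 0; x < ox; ++x) {
        double fx = (x + 0.5) * sx - 0.5;
        fx = std::min(std::max(fx, 0.0), (double)(nx - 1));
        const int x0 = (int)fx, x1 = std::min(x0 + 1, nx - 1);
        const double tx = fx - x0;
        #define IN(a, b, c) in[(a) + (size_t)nx * ((b) + (size_t)ny * (c))]
        const double v00 = IN(x0, y0, z0) * (1 - tx) + IN(x1, y0, z0) * tx;
        const double v10 = IN(x0, y1, z0) * (1 - tx) + IN(x1, y1, z0) * tx;
        const double v01 = IN(x0, y0, z1) * (1 - tx) + IN(x1, y0, z1) * tx;
        const double v11 = IN(x0, y1, z1) * (1 - tx) + IN(x1, y1, z1) * tx;
        #undef IN
        const double v0 = v00 * (1 - ty) + v10 * ty;
        const double v1 = v01 * (1 - ty) + v11 * ty;
        o[x + (size_t)ox * (y + (size_t)oy * z)] = v0 * (1 - tz) + v1 * tz;
      }
    }
  }
  return out;
}

// Trilinear sampling of a single-channel volume at arbitrary 0-based voxel
// coordinates (n x 3 matrix); samples outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector sample_trilinear(NumericVector vol, IntegerVector vdim,
                               NumericMatrix coords, double fill) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const int n = coords.nrow();
  NumericVector out(n);
  const double *in = REAL(vol);
  for (int i = 0; i < n; ++i) {
    const double fx = coords(i, 0), fy = coords(i, 1), fz = coords(i, 2);
    if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
      out[i] = fill;
      continue;
    }
    const int x0 = (int)fx, y0 = (int)fy, z0 = (int)fz;
    const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
    const double tx = fx - x0, ty = fy - y0, tz = fz - z0;
    #define IN(a, b, c) in[(a) + (size_t)nx * ((b) + (size_t)ny * (c))]
    const double v00 = IN(x0, y0, z0) * (1 - tx) + IN(x1, y0, z0) * tx;
    const double v10 = IN(x0, y1, z0) * (1 - tx) + IN(x1, y1, z0) * tx;
    const double v01 = IN(x0, y0, z1) * (1 - tx) + IN(x1, y0, z1) * tx;
    const double v11 = IN(x0, y1, z1) * (1 - tx) + IN(x1, y1, z1) * tx;
    #undef IN
    const double v0 = v00 * (1 - ty) + v10 * ty;
    const double v1 = v01 * (1 - ty) + v11 * ty;
    out[i] = v0 * (1 - tz) + v1 * tz;
  }
  return out;
}

// im2col for 3D "same" zero-padded correlation: returns [nvox, kx*ky*kz*Cin]
// with tap index dx + kx*(dy + ky*(dz + kz*ci)), matching the flattened
// kernel layout [kx,ky,kz,Cin,Cout], so forward = cols %*% Wmat.
// [[Rcpp::export]]
NumericMatrix im2col3d(NumericVector input, IntegerVector idim,
                       IntegerVector kdim) {
  const int nx = idim[0], ny = idim[1], nz = idim[2], nci = idim[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int cx = kx / 2, cy = ky / 2, cz = kz / 2;
  const size_t nvox = (size_t)nx * ny * nz;
  const int ntap = kx * ky * kz * nci;
  NumericMatrix cols(nvox, ntap);
  const double *pin = REAL(input);
  double *pc = REAL(cols);
  for (int ci = 0; ci < nci; ++ci) {
    const double *in = pin + (size_t)ci * nvox;
    for (int dz = 0; dz < kz; ++dz)
      for (int dy = 0; dy < ky; ++dy)
        for (int dx = 0; dx < kx; ++dx) {
          const int t = dx + kx * (dy + ky * (dz + kz * ci));
          double *col = pc + (size_t)t * nvox;
          const int ox = dx - cx, oy = dy - cy, oz = dz - cz;
          const int z0 = std::max(0, -oz), z1 = std::min(nz, nz - oz);
          const int y0 = std::max(0, -oy), y1 = std::min(ny, ny - oy);
          const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
          const int len = x1 - x0;
          for (int z = z0; z < z1; ++z)
            for (int y = y0; y < y1; ++y) {
              double *crow = col + x0 + (size_t)nx * (y + (size_t)ny * z);
              const double *irow =
                  in + (x0 + ox) + (size_t)nx * ((y + oy) + (size_t)ny * (z + oz));
              std::copy(irow, irow + len, crow);
            }
        }
  }
  return cols;
}

// Adjoint of im2col3d: scatter-add columns back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im3d(NumericMatrix cols, IntegerVector idim,
                       IntegerVector kdim) {
  const int nx = idim[0], ny = idim[1], nz = idim[2], nci = idim[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const int cx = kx / 2, cy = ky / 2, cz = kz / 2;
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector gin(nvox * nci);
  const double *pc = REAL(cols);
  double *pi = REAL(gin);
  for (int ci = 0; ci < nci; ++ci) {
    double *gi = pi + (size_t)ci * nvox;
    for (int dz = 0; dz < kz; ++dz)
      for (int dy = 0; dy < ky; ++dy)
        for (int dx = 0; dx < kx; ++dx) {
          const int t = dx + kx * (dy + ky * (dz + kz * ci));
          const double *col = pc + (size_t)t * nvox;
          const int ox = dx - cx, oy = dy - cy, oz = dz - cz;
          const int z0 = std::max(0, -oz), z1 = std::min(nz, nz - oz);
          const int y0 = std::max(0, -oy), y1 = std::min(ny, ny - oy);
          const int x0 = std::max(0, -ox), x1 = std::min(nx, nx - ox);
          const int len = x1 - x0;
          for (int z = z0; z < z1; ++z)
            for (int y = y0; y < y1; ++y) {
              double *girow =
                  gi + (x0 + ox) + (size_t)nx * ((y + oy) + (size_t)ny * (z + oz));
              const double *crow = col + x0 + (size_t)nx * (y + (size_t)ny * z);
              for (int x = 0; x < len; ++x) girow[x] += crow[x];
            }
        }
  }
  return gin;
}
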