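#include <Rcpp.h>
using namespace Rcpp;

static inline int clampi(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// Trilinear warp of a channel-major feature stack.
//
// featT: C x nvox matrix (channels fastest) over an nx*ny*nz grid
//        (x fastest voxel order). dx/dy/dz: per-voxel displacement in
//        voxel units. Output value at voxel p is the stack sampled at
//        p + disp(p), clamped to the grid (edge replication).
// [[Rcpp::export(name = ".warp_channels_cpp")]]
NumericMatrix warp_channels_cpp(NumericMatrix featT, IntegerVector dims,
                                NumericVector dx, NumericVector dy,
                                NumericVector dz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int C = featT.nrow();
  if (featT.ncol() != nvox) stop("feature stack does not match grid");
  NumericMatrix out(C, nvox);
  const double* F = featT.begin();
  double* O = out.begin();
  R_xlen_t v = 0;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x, ++v) {
        double sx = x + dx[v], sy = y + dy[v], sz = z + dz[v];
        sx = sx < 0 ? 0 : (sx > nx - 1 ? nx - 1 : sx);
        sy = sy < 0 ? 0 : (sy > ny - 1 ? ny - 1 : sy);
        sz = sz < 0 ? 0 : (sz > nz - 1 ? nz - 1 : sz);
        int x0 = (int)sx, y0 = (int)sy, z0 = (int)sz;
        if (x0 > nx - 2) x0 = nx > 1 ? nx - 2 : 0;
        if (y0 > ny - 2) y0 = ny > 1 ? ny - 2 : 0;
        if (z0 > nz - 2) z0 = nz > 1 ? nz - 2 : 0;
        const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        const int x1 = clampi(x0 + 1, nx), y1 = clampi(y0 + 1, ny),
                  z1 = clampi(z0 + 1, nz);
        const R_xlen_t i000 = ((R_xlen_t)z0 * ny + y0) * nx + x0;
        const R_xlen_t i100 = ((R_xlen_t)z0 * ny + y0) * nx + x1;
        const R_xlen_t i010 = ((R_xlen_t)z0 * ny + y1) * nx + x0;
        const R_xlen_t i110 = ((R_xlen_t)z0 * ny + y1) * nx + x1;
        const R_xlen_t i001 = ((R_xlen_t)z1 * ny + y0) * nx + x0;
        const R_xlen_t i101 = ((R_xlen_t)z1 * ny + y0) * nx + x1;
        const R_xlen_t i011 = ((R_xlen_t)z1 * ny + y1) * nx + x0;
        const R_xlen_t i111 = ((R_xlen_t)z1 * ny + y1) * nx + x1;
        const double w000 = (1 - fx) * (1 - fy) * (1 - fz);
        const double w100 = fx * (1 - fy) * (1 - fz);
        const double w010 = (1 - fx) * fy * (1 - fz);
        const double w110 = fx * fy * (1 - fz);
        const double w001 = (1 - fx) * (1 - fy) * fz;
        const double w101 = fx * (1 - fy) * fz;
        const double w011 = (1 - fx) * fy * fz;
        const double w111 = fx * fy * fz;
        const double* c000 = F + i000 * C; const double* c100 = F + i100 * C;
        const double* c010 = F + i010 * C; const double* c110 = F + i110 * C;
        const double* c001 = F + i001 * C; const double* c101 = F + i101 * C;
        const double* c011 = F + i011 * C; const double* c111 = F + i111 * C;
        double* o = O + v * C;
        for (int c = 0; c < C; ++c) {
          o[c] = w000 * c000[c] + w100 * c100[c] + w010 * c010[c] +
                 w110 * c110[c] + w001 * c001[c] + w101 * c101[c] +
                 w011 * c011[c] + w111 * c111[c];
        }
      }
    }
  }
  return out;
}

// Demons force ingredients for a multi-channel similarity term.
//
// For each voxel p: diff_c = ff(c,p) - w(c,p); with the symmetric
// (ESM-style) gradient g_c = (grad ff_c + grad w_c) / 2, returns
//   esim = mean_p sum_c diff_c^2,
//   s (nvox x 3): sum_c diff_c * g_c (central differences), and
//   nrm (nvox): sum_c |g_c|^2.
// [[Rcpp::export(name = ".reg_forces_cpp")]]
List reg_forces_cpp(NumericMatrix ffT, NumericMatrix wT,
                    IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int C = ffT.nrow();
  if (wT.nrow() != C || ffT.ncol() != nvox || wT.ncol() != nvox)
    stop("feature stacks do not match");
  NumericMatrix s(nvox, 3);
  NumericVector nrm(nvox);
  const double* F = ffT.begin();
  const double* W = wT.begin();
  double esim = 0.0;
  R_xlen_t v = 0;
  for (int z = 0; z < nz; ++z) {
    const int zp = clampi(z + 1, nz), zm = clampi(z - 1, nz);
    for (int y = 0; y < ny; ++y) {
      const int yp = clampi(y + 1, ny), ym = clampi(y - 1, ny);
      for (int x = 0; x < nx; ++x, ++v) {
        const int xp = clampi(x + 1, nx), xm = clampi(x - 1, nx);
        const double* wv = W + v * C;
        const double* fv = F + v * C;
        const R_xlen_t ixp = (((R_xlen_t)z * ny + y) * nx + xp) * C;
        const R_xlen_t ixm = (((R_xlen_t)z * ny + y) * nx + xm) * C;
        const R_xlen_t iyp = (((R_xlen_t)z * ny + yp) * nx + x) * C;
        const R_xlen_t iym = (((R_xlen_t)z * ny + ym) * nx + x) * C;
        const R_xlen_t izp = (((R_xlen_t)zp * ny + y) * nx + x) * C;
        const R_xlen_t izm = (((R_xlen_t)zm * ny + y) * nx + x) * C;
        const double* wxp = W + ixp; const double* wxm = W + ixm;
        const double* wyp = W + iyp; const double* wym = W + iym;
        const double* wzp = W + izp; const double* wzm = W + izm;
        const double* fxp = F + ixp; const double* fxm = F + ixm;
        const double* fyp = F + iyp; const double* fym = F + iym;
        const double* fzp = F + izp; const double* fzm = F + izm;
        double sx = 0, sy = 0, sz = 0, nv = 0;
        for (int c = 0; c < C; ++c) {
          const double diff = fv[c] - wv[c];
          esim += diff * diff;
          const double gx = 0.25 * (wxp[c] - wxm[c] + fxp[c] - fxm[c]);
          const double gy = 0.25 * (wyp[c] - wym[c] + fyp[c] - fym[c]);
          const double gz = 0.25 * (wzp[c] - wzm[c] + fzp[c] - fzm[c]);
          sx += diff * gx; sy += diff * gy; sz += diff * gz;
          nv += gx * gx + gy * gy + gz * gz;
        }
        s(v, 0) = sx; s(v, 1) = sy; s(v, 2) = sz;
        nrm[v] = nv;
      }
    }
  }
  return List::create(_["esim"] = esim / (double)nvox, _["s"] = s,
                      _["nrm"] = nrm);
}
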