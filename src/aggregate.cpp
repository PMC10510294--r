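#include <Rcpp.h>
using namespace Rcpp;

// Bin-average pooling of a multi-channel feature map.
//
// feat: nvox x M matrix (column-major voxel ordering of an nx*ny*nz grid,
//       x fastest). For each bin (a set of integer voxel offsets) the
//       output channel block is the mean over the bin's offsets of the
//       edge-replicated shifted feature map: out(p, (n-1)*M + m) =
//       mean_{t in bin n} feat(clamp(p + t), m).
// dims: grid shape (nx, ny, nz).
// kernels: list of IntegerMatrix (cnt x 3) offset sets, one per bin;
//          empty bins yield zero-filled channel blocks.
// [[Rcpp::export(name = ".bin_average_cpp")]]
NumericVector bin_average_cpp(NumericMatrix feat, IntegerVector dims,
                              List kernels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int M = feat.ncol();
  const int N = kernels.size();
  if (feat.nrow() != nvox) stop("feature matrix does not match grid");

  NumericVector out((R_xlen_t)nvox * M * N);
  std::vector<double> acc(nvox);

  for (int n = 0; n < N; ++n) {
    IntegerMatrix offs = kernels[n];
    const int cnt = offs.nrow();
    if (cnt == 0) continue;
    for (int m = 0; m < M; ++m) {
      std::fill(acc.begin(), acc.end(), 0.0);
      const double* col = &feat(0, m);
      for (int t = 0; t < cnt; ++t) {
        const int ox = offs(t, 0), oy = offs(t, 1), oz = offs(t, 2);
        // split the x loop into clamped border runs and a branch-free
        // interior run the compiler can vectorize
        const int xa = std::min(std::max(0, -ox), nx);
        const int xb = std::max(std::min(nx, nx - ox), xa);
        R_xlen_t v = 0;
        for (int z = 0; z < nz; ++z) {
          int cz = z + oz; cz = cz < 0 ? 0 : (cz >= nz ? nz - 1 : cz);
          const R_xlen_t zoff = (R_xlen_t)cz * nx * ny;
          for (int y = 0; y < ny; ++y) {
            int cy = y + oy; cy = cy < 0 ? 0 : (cy >= ny ? ny - 1 : cy);
            const double* row = col + zoff + (R_xlen_t)cy * nx;
            double* a = &acc[v];
            for (int x = 0; x < xa; ++x) a[x] += row[0];
            const double* rs = row + ox;
            for (int x = xa; x < xb; ++x) a[x] += rs[x];
            for (int x = xb; x < nx; ++x) a[x] += row[nx - 1];
            v += nx;
          }
        }
      }
      double* dst = &out[((R_xlen_t)n * M + m) * nvox];
      const double inv = 1.0 / cnt;
      for (R_xlen_t v = 0; v < nvox; ++v) dst[v] = acc[v] * inv;
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, M * N);
  return out;
}
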