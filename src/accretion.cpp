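#include <Rcpp.h>
using namespace Rcpp;

// Stochastic surface accretion on a voxel lattice.
//
// Synchronous update: at each step every fluid voxel face-adjacent (6-
// connectivity) to solid-or-clot converts to clot with the per-voxel
// probability prob(ix, iz), which encodes the longitudinal bias, inlet
// capture, gap bridging and velocity dependence (constant along the rod
// axis y). Draws come from R's RNG so set.seed() gives bit-identical
// volumes. Returns the clot mask (disjoint from the initial solid).
//
// grids are in R array order: index = ix + nx*iy + nx*ny*iz.
// [[Rcpp::export]]
LogicalVector accrete_cpp(LogicalVector solid, NumericMatrix prob,
                          int nx, int ny, int nz, int steps) {
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;
  if (solid.size() != n) stop("solid grid size does not match dimensions");
  if (prob.nrow() != nx || prob.ncol() != nz)
    stop("probability field must be nx x nz");

  std::vector<unsigned char> occ(n), clot(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) occ[i] = solid[i] ? 1 : 0;

  std::vector<R_xlen_t> newly;
  for (int t = 0; t < steps; ++t) {
    newly.clear();
    for (int iz = 0; iz < nz; ++iz) {
      for (int iy = 0; iy < ny; ++iy) {
        const R_xlen_t base = nxy * iz + (R_xlen_t)nx * iy;
        for (int ix = 0; ix < nx; ++ix) {
          const R_xlen_t i = base + ix;
          if (occ[i]) continue;
          bool adj =
            (ix > 0      && occ[i - 1]) ||
            (ix < nx - 1 && occ[i + 1]) ||
            (iy > 0      && occ[i - nx]) ||
            (iy < ny - 1 && occ[i + nx]) ||
            (iz > 0      && occ[i - nxy]) ||
            (iz < nz - 1 && occ[i + nxy]);
          if (!adj) continue;
          const double p = prob(ix, iz);
          if (p > 0.0 && unif_rand() < p) newly.push_back(i);
        }
      }
    }
    for (R_xlen_t j : newly) { occ[j] = 1; clot[j] = 1; }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = clot[i] != 0;
  return out;
}
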