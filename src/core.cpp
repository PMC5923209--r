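#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Batch eigendecomposition of symmetric 3x3 tensors.
// comps: n x 6 matrix of (xx, yy, zz, xy, xz, yz).
// Returns values (n x 3, descending) and vectors (n x 9, e1 then e2 then e3,
// each as x,y,z). Rows with non-finite input yield NA rows.
// [[Rcpp::export]]
List eig_sym3_batch(const arma::mat& comps) {
  const arma::uword n = comps.n_rows;
  arma::mat values(n, 3);
  arma::mat vectors(n, 9);
  arma::mat33 D;
  arma::vec3 eval;
  arma::mat33 evec;
  for (arma::uword i = 0; i < n; ++i) {
    D(0, 0) = comps(i, 0); D(1, 1) = comps(i, 1); D(2, 2) = comps(i, 2);
    D(0, 1) = D(1, 0) = comps(i, 3);
    D(0, 2) = D(2, 0) = comps(i, 4);
    D(1, 2) = D(2, 1) = comps(i, 5);
    if (!D.is_finite()) {
      values.row(i).fill(NA_REAL);
      vectors.row(i).fill(NA_REAL);
      continue;
    }
    arma::eig_sym(eval, evec, D);  // ascending order
    for (int j = 0; j < 3; ++j) {
      values(i, j) = eval(2 - j);
      for (int k = 0; k < 3; ++k) vectors(i, 3 * j + k) = evec(k, 2 - j);
    }
  }
  return List::create(_["values"] = values, _["vectors"] = vectors);
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Line-integral convolution of a scalar noise volume along a 3D unit
// orientation field (axial: sign-continuity maintained per step).
// noise:  nx*ny*nz vector (column-major array layout)
// orient: nx*ny*nz*3 vector; zero vectors mark voxels without orientation
// spacing: physical voxel size per axis; step: physical step length;
// nsteps: number of steps traced in each direction from the voxel.
// Voxels without orientation are returned unchanged.
// [[Rcpp::export]]
NumericVector lic3d(const NumericVector& noise, const NumericVector& orient,
                    const IntegerVector& dims, const NumericVector& spacing,
                    double step, int nsteps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t v = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double ox = orient[v], oy = orient[v + nvox], oz = orient[v + 2 * nvox];
        if (ox == 0.0 && oy == 0.0 && oz == 0.0) {
          out[v] = noise[v];
          continue;
        }
        double acc = noise[v];
        double wsum = 1.0;
        for (int dir = -1; dir <= 1; dir += 2) {
          // physical position at voxel centre
          double px = (i + 0.5) * sx, py = (j + 0.5) * sy, pz = (k + 0.5) * sz;
          double dx = dir * ox, dy = dir * oy, dz = dir * oz;
          for (int s = 0; s < nsteps; ++s) {
            px += step * dx; py += step * dy; pz += step * dz;
            int ii = clampi((int)std::floor(px / sx), 0, nx - 1);
            int jj = clampi((int)std::floor(py / sy), 0, ny - 1);
            int kk = clampi((int)std::floor(pz / sz), 0, nz - 1);
            const R_xlen_t u = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            double ux = orient[u], uy = orient[u + nvox], uz = orient[u + 2 * nvox];
            if (ux == 0.0 && uy == 0.0 && uz == 0.0) break;  // left the field
            // axial continuity: keep direction within 90 deg of previous step
            if (ux * dx + uy * dy + uz * dz < 0) { ux = -ux; uy = -uy; uz = -uz; }
            dx = ux; dy = uy; dz = uz;
            // Hann-style taper toward the streamline ends
            double w = 0.5 * (1.0 + std::cos(M_PI * (s + 1.0) / (nsteps + 1.0)));
            acc += w * noise[u];
            wsum += w;
          }
        }
        out[v] = acc / wsum;
      }
    }
  }
  return out;
}
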