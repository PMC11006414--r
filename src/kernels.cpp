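#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
#include <algorithm>
using namespace Rcpp;

// 3D arrays are passed as flat NumericVector in R's column-major layout:
// index(i,j,k) = i + nx*(j + ny*k), 0-based.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

// Mirror (zero-flux) index reflection at domain faces.
static inline int refl(int i, int n) {
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - i - 1;
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_lap3d(NumericVector f, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(f.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double c = f[idx3(i, j, k, nx, ny)];
        double s = f[idx3(refl(i - 1, nx), j, k, nx, ny)]
                 + f[idx3(refl(i + 1, nx), j, k, nx, ny)]
                 + f[idx3(i, refl(j - 1, ny), k, nx, ny)]
                 + f[idx3(i, refl(j + 1, ny), k, nx, ny)]
                 + f[idx3(i, j, refl(k - 1, nz), nx, ny)]
                 + f[idx3(i, j, refl(k + 1, nz), nx, ny)];
        out[idx3(i, j, k, nx, ny)] = s - 6.0 * c;
      }
  return out;
}

// Separable Gaussian blur with reflected boundaries; sigma in voxels.
// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector f, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (sigma <= 0) return clone(f);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double ssum = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    ssum += ker[t + rad];
  }
  for (double &w : ker) w /= ssum;

  NumericVector a = clone(f), b(f.size());
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int t = -rad; t <= rad; ++t)
          acc += ker[t + rad] * a[idx3(refl(i + t, nx), j, k, nx, ny)];
        b[idx3(i, j, k, nx, ny)] = acc;
      }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int t = -rad; t <= rad; ++t)
          acc += ker[t + rad] * b[idx3(i, refl(j + t, ny), k, nx, ny)];
        a[idx3(i, j, k, nx, ny)] = acc;
      }
  // z pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int t = -rad; t <= rad; ++t)
          acc += ker[t + rad] * a[idx3(i, j, refl(k + t, nz), nx, ny)];
        b[idx3(i, j, k, nx, ny)] = acc;
      }
  return b;
}

// Explicit Euler integration of the phase-field growth law in lattice units:
//   df/dt = f(1-f) * (d*K + lap K),  K = -lap f,
// K positive over convex solid (f = 1) features. Frozen voxels are pinned to
// their initial values; the result is clipped to [0,1] after every step.
// [[Rcpp::export]]
List cpp_growth_run(NumericVector f0, LogicalVector frozen, IntegerVector dims,
                    double d, double dt, int nsteps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = f0.size();
  NumericVector f = clone(f0);
  std::vector<double> pinned(n);
  for (R_xlen_t i = 0; i < n; ++i) pinned[i] = f0[i];

  for (int s = 0; s < nsteps; ++s) {
    NumericVector L1 = cpp_lap3d(f, dims);   // lap f  (= -K)
    NumericVector L2 = cpp_lap3d(L1, dims);  // lap lap f (= -lap K)
    bool bad = false;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const int q = idx3(i, j, k, nx, ny);
          if (frozen[q]) { f[q] = pinned[q]; continue; }
          const double fv = f[q];
          const double rate = fv * (1.0 - fv) * (-d * L1[q] - L2[q]);
          double nf = fv + dt * rate;
          if (std::isnan(nf)) { bad = true; nf = fv; }
          if (nf < 0.0) nf = 0.0;
          if (nf > 1.0) nf = 1.0;
          f[q] = nf;
        }
    if (bad) stop("growth step produced NaN at step %d; reduce dt", s + 1);
  }
  return List::create(_["f"] = f, _["steps"] = nsteps);
}

// Steady-state Laplace solve on air voxels by conjugate gradients.
// Boundary coding per air voxel neighbor:
//  - air neighbor: standard stencil link;
//  - solid neighbor: Dirichlet hSurface if that solid voxel is wet, else
//    zero-flux (dry substrate);
//  - below bottom face: Dirichlet hSurface if bottomWet else zero-flux;
//  - above top face: Dirichlet hTop;
//  - lateral out-of-domain: zero-flux.
// [[Rcpp::export]]
List cpp_cg_laplace(LogicalVector solid, LogicalVector wet, LogicalVector cold,
                    IntegerVector dims,
                    double hSurface, double hTop, bool bottomWet,
                    double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = solid.size();
  std::vector<int> map(ntot, -1);
  std::vector<int> air;
  air.reserve(ntot);
  for (R_xlen_t q = 0; q < ntot; ++q)
    if (!solid[q] && !cold[q]) { map[q] = (int)air.size(); air.push_back((int)q); }
  const int nAir = (int)air.size();
  if (nAir == 0) stop("no air voxels in domain");

  // Precompute per-unknown diagonal, neighbor list and rhs.
  std::vector<double> diag(nAir, 0.0), b(nAir, 0.0);
  std::vector<std::array<int, 6>> nb(nAir);
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  for (int a = 0; a < nAir; ++a) {
    const int q = air[a];
    const int i = q % nx, j = (q / nx) % ny, k = q / (nx * ny);
    for (int m = 0; m < 6; ++m) {
      const int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      nb[a][m] = -1;
      // Dirichlet values act on the voxel face (half-spacing): coefficient 2
      if (kk < 0) {                       // below bottom plate
        if (bottomWet) { diag[a] += 2.0; b[a] += 2.0 * hSurface; }
      } else if (kk >= nz) {              // above top plate
        diag[a] += 2.0; b[a] += 2.0 * hTop;
      } else if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) {
        // lateral: zero-flux
      } else {
        const int p = idx3(ii, jj, kk, nx, ny);
        if (solid[p]) {
          if (wet[p]) { diag[a] += 2.0; b[a] += 2.0 * hSurface; }
        } else if (cold[p]) {             // far-field region held at hTop
          diag[a] += 2.0; b[a] += 2.0 * hTop;
        } else {
          diag[a] += 1.0; nb[a][m] = map[p];
        }
      }
    }
  }

  // CG on A x = b with A = diag - adjacency (SPD).
  std::vector<double> x(nAir, 0.0), r(nAir), p(nAir), Ap(nAir);
  // initial guess: linear vertical profile
  for (int a = 0; a < nAir; ++a) {
    const int k = air[a] / (nx * ny);
    x[a] = hSurface + (hTop - hSurface) * ((k + 0.5) / (double)nz);
  }
  auto matvec = [&](const std::vector<double> &v, std::vector<double> &out) {
    for (int a = 0; a < nAir; ++a) {
      double acc = diag[a] * v[a];
      for (int m = 0; m < 6; ++m)
        if (nb[a][m] >= 0) acc -= v[nb[a][m]];
      out[a] = acc;
    }
  };
  matvec(x, Ap);
  double bnorm = 0.0;
  for (int a = 0; a < nAir; ++a) { r[a] = b[a] - Ap[a]; bnorm += b[a] * b[a]; }
  bnorm = std::sqrt(std::max(bnorm, 1e-300));
  double rs = 0.0;
  for (int a = 0; a < nAir; ++a) rs += r[a] * r[a];
  p = r;
  int it = 0;
  double rel = std::sqrt(rs) / bnorm;
  while (rel > tol && it < maxit) {
    matvec(p, Ap);
    double pAp = 0.0;
    for (int a = 0; a < nAir; ++a) pAp += p[a] * Ap[a];
    const double alpha = rs / pAp;
    double rs2 = 0.0;
    for (int a = 0; a < nAir; ++a) {
      x[a] += alpha * p[a];
      r[a] -= alpha * Ap[a];
      rs2 += r[a] * r[a];
    }
    const double beta = rs2 / rs;
    for (int a = 0; a < nAir; ++a) p[a] = r[a] + beta * p[a];
    rs = rs2;
    rel = std::sqrt(rs) / bnorm;
    ++it;
  }

  NumericVector h(ntot, NA_REAL);
  for (int a = 0; a < nAir; ++a) h[air[a]] = x[a];
  return List::create(_["h"] = h, _["iterations"] = it, _["residual"] = rel,
                      _["converged"] = (rel <= tol));
}

// Air voxels reachable from the top layer by face connectivity.
// [[Rcpp::export]]
LogicalVector cpp_flood_air(LogicalVector solid, LogicalVector cold,
                            IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = solid.size();
  LogicalVector reach(ntot, false);
  std::vector<int> stack;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      const int q = idx3(i, j, nz - 1, nx, ny);
      if (!solid[q] && !cold[q]) { reach[q] = true; stack.push_back(q); }
    }
  // voxels of the far-field Dirichlet region seed their air neighbors
  for (R_xlen_t q = 0; q < ntot; ++q)
    if (cold[q] && !reach[q]) { reach[q] = true; stack.push_back((int)q); }
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  while (!stack.empty()) {
    const int q = stack.back();
    stack.pop_back();
    const int i = q % nx, j = (q / nx) % ny, k = q / (nx * ny);
    for (int m = 0; m < 6; ++m) {
      const int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      const int p = idx3(ii, jj, kk, nx, ny);
      if (!solid[p] && !cold[p] && !reach[p]) { reach[p] = true; stack.push_back(p); }
    }
  }
  return reach;
}

// Trailing temporal median over a window: mat is npix x nframes, output
// npix x (nframes - window + 1); output column t covers frames [t, t+window-1].
// For even windows the UPPER central order statistic is used: moving animals
// only ever darken a pixel, so requiring a strict majority of dark samples
// (6 of 10) before the filter output turns dark biases the filter against
// transients without affecting persistent changes.
// [[Rcpp::export]]
NumericMatrix cpp_rolling_median(NumericMatrix mat, int window) {
  const int npix = mat.nrow(), nf = mat.ncol();
  const int nout = nf - window + 1;
  if (nout < 1) stop("fewer frames than the median window");
  NumericMatrix out(npix, nout);
  std::vector<double> buf(window);
  for (int p = 0; p < npix; ++p) {
    for (int t = 0; t < nout; ++t) {
      for (int w = 0; w < window; ++w) buf[w] = mat(p, t + w);
      std::nth_element(buf.begin(), buf.begin() + window / 2, buf.end());
      out(p, t) = buf[window / 2];
    }
  }
  return out;
}

// Brute-force nearest-neighbor: for each query row return 1-based index of
// the nearest reference row (Euclidean, 3D).
// [[Rcpp::export]]
IntegerVector cpp_nearest_index(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("empty reference point set");
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double best = R_PosInf;
    int arg = 0;
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    for (int r = 0; r < nr; ++r) {
      const double dx = qx - ref(r, 0), dy = qy - ref(r, 1), dz = qz - ref(r, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; arg = r; }
    }
    out[q] = arg + 1;
  }
  return out;
}
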