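#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 7-point finite-difference operator for the linearized Poisson-Boltzmann
// equation, with harmonic-mean face permittivities. Interior unknowns are
// solved by Jacobi-preconditioned conjugate gradients; boundary nodes hold
// fixed Dirichlet values whose contribution has been folded into b.
//
// A(x)_c = (sum_f eps_f + k2h2_c) * x_c - sum_{nb interior} eps_f * x_nb

static inline double face_eps(double a, double b) {
  return 2.0 / (1.0 / a + 1.0 / b);
}

// [[Rcpp::export(name = ".cg_solve_pb")]]
List cg_solve_pb(NumericVector eps, NumericVector k2h2, NumericVector b,
                 NumericVector phi_fixed, IntegerVector dims,
                 double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  auto idx = [nx, ny](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };
  auto interior = [nx, ny, nz](int i, int j, int k) {
    return i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1;
  };

  std::vector<double> x(n, 0.0), r(n, 0.0), z(n, 0.0), p(n, 0.0), Ap(n, 0.0),
      diag(n, 1.0), rhs(n, 0.0);

  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};

  // rhs = b + boundary contributions; diag for preconditioner
  double bnorm2 = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t c = idx(i, j, k);
        if (!interior(i, j, k)) continue;
        double sum_eps = 0.0, bc = b[c];
        for (int f = 0; f < 6; ++f) {
          int ii = i + di[f], jj = j + dj[f], kk = k + dk[f];
          R_xlen_t nb = idx(ii, jj, kk);
          double ef = face_eps(eps[c], eps[nb]);
          sum_eps += ef;
          if (!interior(ii, jj, kk)) bc += ef * phi_fixed[nb];
        }
        diag[c] = sum_eps + k2h2[c];
        rhs[c] = bc;
        bnorm2 += bc * bc;
      }

  if (bnorm2 == 0.0) {
    NumericVector phi(n);
    for (R_xlen_t c = 0; c < n; ++c) phi[c] = 0.0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          if (!interior(i, j, k)) phi[idx(i, j, k)] = phi_fixed[idx(i, j, k)];
    phi.attr("dim") = dims;
    return List::create(_["phi"] = phi, _["iterations"] = 0,
                        _["residual"] = 0.0, _["converged"] = true);
  }

  auto apply_A = [&](const std::vector<double> &v, std::vector<double> &out) {
    for (int k = 1; k < nz - 1; ++k)
      for (int j = 1; j < ny - 1; ++j)
        for (int i = 1; i < nx - 1; ++i) {
          R_xlen_t c = idx(i, j, k);
          double acc = (diag[c]) * v[c];
          for (int f = 0; f < 6; ++f) {
            int ii = i + di[f], jj = j + dj[f], kk = k + dk[f];
            if (!interior(ii, jj, kk)) continue;
            R_xlen_t nb = idx(ii, jj, kk);
            acc -= face_eps(eps[c], eps[nb]) * v[nb];
          }
          out[c] = acc;
        }
  };

  // CG iterations (x0 = 0 so r0 = rhs)
  r = rhs;
  double rz = 0.0;
  for (R_xlen_t c = 0; c < n; ++c) {
    z[c] = r[c] / diag[c];
    rz += r[c] * z[c];
  }
  p = z;
  double res = std::sqrt(bnorm2);
  const double target = tol * std::sqrt(bnorm2);
  int it = 0;
  bool converged = false;
  for (it = 0; it < maxit; ++it) {
    apply_A(p, Ap);
    double pAp = 0.0;
    for (R_xlen_t c = 0; c < n; ++c) pAp += p[c] * Ap[c];
    if (pAp <= 0.0) break;
    double alpha = rz / pAp;
    double rnorm2 = 0.0;
    for (R_xlen_t c = 0; c < n; ++c) {
      x[c] += alpha * p[c];
      r[c] -= alpha * Ap[c];
      rnorm2 += r[c] * r[c];
    }
    res = std::sqrt(rnorm2);
    if (res <= target) { converged = true; ++it; break; }
    double rz_new = 0.0;
    for (R_xlen_t c = 0; c < n; ++c) {
      z[c] = r[c] / diag[c];
      rz_new += r[c] * z[c];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (R_xlen_t c = 0; c < n; ++c) p[c] = z[c] + beta * p[c];
  }

  NumericVector phi(n);
  for (R_xlen_t c = 0; c < n; ++c) phi[c] = x[c];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (!interior(i, j, k)) phi[idx(i, j, k)] = phi_fixed[idx(i, j, k)];
  phi.attr("dim") = dims;
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["residual"] = res / std::sqrt(bnorm2),
                      _["converged"] = converged);
}

// Sum of Debye-Hueckel monopole potentials at a set of points.
// phi(r) = C * q * exp(-kappa * r) / (eps_s * r)
// [[Rcpp::export(name = ".dh_potential")]]
NumericVector dh_potential(NumericMatrix pts, NumericMatrix qpos,
                           NumericVector q, double coulomb, double eps_s,
                           double kappa) {
  const int np = pts.nrow(), nq = qpos.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double acc = 0.0;
    for (int j = 0; j < nq; ++j) {
      double dx = pts(i, 0) - qpos(j, 0);
      double dy = pts(i, 1) - qpos(j, 1);
      double dz = pts(i, 2) - qpos(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-6) r = 1e-6;
      acc += coulomb * q[j] * std::exp(-kappa * r) / (eps_s * r);
    }
    out[i] = acc;
  }
  return out;
}

// Mark voxels inside any atom sphere: sets region[] = code.
// [[Rcpp::export(name = ".mark_protein_voxels")]]
IntegerVector mark_protein_voxels(IntegerVector region, NumericMatrix apos,
                                  NumericVector radius, NumericVector origin,
                                  double h, IntegerVector dims, int code) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out = clone(region);
  for (int a = 0; a < apos.nrow(); ++a) {
    double R = radius[a];
    if (R <= 0) continue;
    double ax = apos(a, 0), ay = apos(a, 1), az = apos(a, 2);
    int i0 = std::max(0, (int)std::ceil((ax - R - origin[0]) / h));
    int i1 = std::min(nx - 1, (int)std::floor((ax + R - origin[0]) / h));
    int j0 = std::max(0, (int)std::ceil((ay - R - origin[1]) / h));
    int j1 = std::min(ny - 1, (int)std::floor((ay + R - origin[1]) / h));
    int k0 = std::max(0, (int)std::ceil((az - R - origin[2]) / h));
    int k1 = std::min(nz - 1, (int)std::floor((az + R - origin[2]) / h));
    double R2 = R * R;
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * h - az;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * h - ay;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * h - ax;
          if (dx * dx + dy * dy + dz * dz <= R2)
            out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = code;
        }
      }
    }
  }
  return out;
}
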