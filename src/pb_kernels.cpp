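#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grid layout convention shared by all kernels: node (i,j,k) with
// 0 <= i < nx (x fastest) lives at flat index i + nx*(j + ny*k) and
// Cartesian position (x0 + i*h, y0 + j*h, z0 + k*h), everything in Angstrom.

// Mark grid nodes lying inside the union of atom spheres (radius + inflate).
// [[Rcpp::export]]
LogicalVector mark_interior_cpp(NumericMatrix xyz, NumericVector radius,
                                double inflate,
                                double x0, double y0, double z0,
                                double h, int nx, int ny, int nz) {
  LogicalVector inside(nx * ny * nz, false);
  const int na = xyz.nrow();
  for (int a = 0; a < na; ++a) {
    const double r = radius[a] + inflate;
    if (r <= 0.0) continue;
    const double ax = xyz(a, 0), ay = xyz(a, 1), az = xyz(a, 2);
    const double r2 = r * r;
    int i0 = (int)std::ceil((ax - r - x0) / h), i1 = (int)std::floor((ax + r - x0) / h);
    int j0 = (int)std::ceil((ay - r - y0) / h), j1 = (int)std::floor((ay + r - y0) / h);
    int k0 = (int)std::ceil((az - r - z0) / h), k1 = (int)std::floor((az + r - z0) / h);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = z0 + k * h - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = y0 + j * h - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2) continue;
        const std::size_t base = (std::size_t)nx * (j + (std::size_t)ny * k);
        for (int i = i0; i <= i1; ++i) {
          const double dx = x0 + i * h - ax;
          if (dx * dx + dyz2 <= r2) inside[base + i] = true;
        }
      }
    }
  }
  return inside;
}

// Successive over-relaxation sweep solver for the linearized PB equation
//   div(eps grad phi) - eps*kappa2*phi = -4*pi*C*rho
// discretised with harmonic-mean face dielectrics on a uniform grid.
// phi carries Dirichlet values on the outer boundary faces on entry.
// src = 4*pi*C*q_node/h; kap = eps_node*kappa2_node*h^2 (zero where unscreened).
// Convergence: max node update < tol * max |phi| (or tol absolute if phi ~ 0).
// [[Rcpp::export]]
List pb_sor_cpp(NumericVector phi, NumericVector eps, NumericVector kap,
                NumericVector src, int nx, int ny, int nz,
                double omega, double tol, int maxit) {
  NumericVector ph = clone(phi);
  double *p = ph.begin();
  const double *e = eps.begin(), *kp = kap.begin(), *s = src.begin();
  const std::size_t sx = 1, sy = nx, sz = (std::size_t)nx * ny;
  double maxupd = R_PosInf;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    maxupd = 0.0;
    double maxphi = 0.0;
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        std::size_t idx = sx + sy * j + sz * k;
        for (int i = 1; i < nx - 1; ++i, ++idx) {
          const double e0 = e[idx];
          const double exm = 2.0 * e0 * e[idx - sx] / (e0 + e[idx - sx]);
          const double exp_ = 2.0 * e0 * e[idx + sx] / (e0 + e[idx + sx]);
          const double eym = 2.0 * e0 * e[idx - sy] / (e0 + e[idx - sy]);
          const double eyp = 2.0 * e0 * e[idx + sy] / (e0 + e[idx + sy]);
          const double ezm = 2.0 * e0 * e[idx - sz] / (e0 + e[idx - sz]);
          const double ezp = 2.0 * e0 * e[idx + sz] / (e0 + e[idx + sz]);
          const double denom = exm + exp_ + eym + eyp + ezm + ezp + kp[idx];
          const double rhs = exm * p[idx - sx] + exp_ * p[idx + sx] +
                             eym * p[idx - sy] + eyp * p[idx + sy] +
                             ezm * p[idx - sz] + ezp * p[idx + sz] + s[idx];
          const double pnew = (1.0 - omega) * p[idx] + omega * rhs / denom;
          const double upd = std::fabs(pnew - p[idx]);
          if (upd > maxupd) maxupd = upd;
          p[idx] = pnew;
          const double ap = std::fabs(pnew);
          if (ap > maxphi) maxphi = ap;
        }
      }
    }
    const double scale = maxphi > 1.0 ? maxphi : 1.0;
    if (maxupd < tol * scale) break;
  }
  return List::create(_["phi"] = ph, _["iterations"] = it,
                      _["residual"] = maxupd,
                      _["converged"] = (it <= maxit));
}

// Trilinear interpolation of a grid field at arbitrary points; NA outside.
// [[Rcpp::export]]
NumericVector grid_interp_cpp(NumericVector field,
                              double x0, double y0, double z0, double h,
                              int nx, int ny, int nz, NumericMatrix pts) {
  const int np = pts.nrow();
  NumericVector out(np);
  const std::size_t sy = nx, sz = (std::size_t)nx * ny;
  for (int m = 0; m < np; ++m) {
    const double fx = (pts(m, 0) - x0) / h;
    const double fy = (pts(m, 1) - y0) / h;
    const double fz = (pts(m, 2) - z0) / h;
    const int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    if (i < 0 || j < 0 || k < 0 || i > nx - 2 || j > ny - 2 || k > nz - 2) {
      out[m] = NA_REAL;
      continue;
    }
    const double ax = fx - i, ay = fy - j, az = fz - k;
    const std::size_t idx = i + sy * j + sz * k;
    const double c000 = field[idx],          c100 = field[idx + 1];
    const double c010 = field[idx + sy],     c110 = field[idx + 1 + sy];
    const double c001 = field[idx + sz],     c101 = field[idx + 1 + sz];
    const double c011 = field[idx + sy + sz], c111 = field[idx + 1 + sy + sz];
    out[m] =
      c000 * (1 - ax) * (1 - ay) * (1 - az) + c100 * ax * (1 - ay) * (1 - az) +
      c010 * (1 - ax) * ay * (1 - az)       + c110 * ax * ay * (1 - az) +
      c001 * (1 - ax) * (1 - ay) * az       + c101 * ax * (1 - ay) * az +
      c011 * (1 - ax) * ay * az             + c111 * ax * ay * az;
  }
  return out;
}

// Cloud-in-cell (trilinear) spreading of point charges onto grid nodes.
// [[Rcpp::export]]
NumericVector spread_charges_cpp(NumericMatrix pts, NumericVector q,
                                 double x0, double y0, double z0, double h,
                                 int nx, int ny, int nz) {
  NumericVector grid((std::size_t)nx * ny * nz, 0.0);
  const std::size_t sy = nx, sz = (std::size_t)nx * ny;
  for (int m = 0; m < pts.nrow(); ++m) {
    const double fx = (pts(m, 0) - x0) / h;
    const double fy = (pts(m, 1) - y0) / h;
    const double fz = (pts(m, 2) - z0) / h;
    const int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    if (i < 0 || j < 0 || k < 0 || i > nx - 2 || j > ny - 2 || k > nz - 2)
      stop("charge outside grid interior");
    const double ax = fx - i, ay = fy - j, az = fz - k;
    const std::size_t idx = i + sy * j + sz * k;
    const double qq = q[m];
    grid[idx]           += qq * (1 - ax) * (1 - ay) * (1 - az);
    grid[idx + 1]       += qq * ax * (1 - ay) * (1 - az);
    grid[idx + sy]      += qq * (1 - ax) * ay * (1 - az);
    grid[idx + 1 + sy]  += qq * ax * ay * (1 - az);
    grid[idx + sz]      += qq * (1 - ax) * (1 - ay) * az;
    grid[idx + 1 + sz]  += qq * ax * (1 - ay) * az;
    grid[idx + sy + sz] += qq * (1 - ax) * ay * az;
    grid[idx + 1 + sy + sz] += qq * ax * ay * az;
  }
  return grid;
}

// Screened-Coulomb (Debye-Hueckel) boundary potential on the six outer faces.
// coef = e^2/(4 pi eps0) in meV*Angstrom; phi in mV on return.
// [[Rcpp::export]]
NumericVector boundary_potential_cpp(NumericMatrix pts, NumericVector q,
                                     double coef, double eps_solvent,
                                     double kappa,
                                     double x0, double y0, double z0, double h,
                                     int nx, int ny, int nz) {
  NumericVector phi((std::size_t)nx * ny * nz, 0.0);
  const std::size_t sy = nx, sz = (std::size_t)nx * ny;
  const int nq = pts.nrow();
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1 &&
            k != 0 && k != nz - 1)
          continue;
        const double px = x0 + i * h, py = y0 + j * h, pz = z0 + k * h;
        double v = 0.0;
        for (int m = 0; m < nq; ++m) {
          const double dx = px - pts(m, 0), dy = py - pts(m, 1),
                       dz = pz - pts(m, 2);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < 1e-6) r = 1e-6;
          v += coef * q[m] * std::exp(-kappa * r) / (eps_solvent * r);
        }
        phi[i + sy * j + sz * k] = v;
      }
    }
  }
  return phi;
}
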