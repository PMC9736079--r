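#include <Rcpp.h>
using namespace Rcpp;

// Red-black Gauss-Seidel SOR for the 7-point finite-difference form of
//   div(eps grad u) - Lambda u = -src_scaled / h^2
// assembled per interior node as
//   u0 = (sum_e eps_e * u_nb + src0) / (sum_e eps_e + h^2 * Lambda0)
// Boundary nodes hold Dirichlet values supplied in u0 and are never updated.
// epsx/epsy/epsz are edge dielectrics: epsx[i,j,k] sits between nodes
// (i,j,k) and (i+1,j,k), dims (nx-1) x ny x nz, and similarly for y/z.
// Convergence: max |delta u| <= tol * max |u| per full sweep.
// [[Rcpp::export]]
List sor_lpbe_cpp(IntegerVector dims, double h,
                  NumericVector epsx, NumericVector epsy, NumericVector epsz,
                  NumericVector lambda, NumericVector src,
                  NumericVector u_init, double omega, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector u = clone(u_init);
  const double h2 = h * h;
  auto idx = [nx, ny](int i, int j, int k) { return i + nx * (j + ny * k); };
  auto ex = [nx, ny](int i, int j, int k) { return i + (nx - 1) * (j + ny * k); };
  auto ey = [nx, ny](int i, int j, int k) { return i + nx * (j + (ny - 1) * k); };
  auto ez = [nx, ny](int i, int j, int k) { return i + nx * (j + ny * k); };
  std::vector<double> resid_hist;
  int iter = 0;
  bool converged = false;
  for (iter = 1; iter <= maxit; ++iter) {
    double maxd = 0.0, maxu = 0.0;
    for (int rb = 0; rb < 2; ++rb) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          for (int i = 1; i < nx - 1; ++i) {
            if (((i + j + k) & 1) != rb) continue;
            const int n = idx(i, j, k);
            const double exm = epsx[ex(i - 1, j, k)], exp_ = epsx[ex(i, j, k)];
            const double eym = epsy[ey(i, j - 1, k)], eyp = epsy[ey(i, j, k)];
            const double ezm = epsz[ez(i, j, k - 1)], ezp = epsz[ez(i, j, k)];
            const double ssum = exm + exp_ + eym + eyp + ezm + ezp;
            const double num = exm * u[n - 1] + exp_ * u[n + 1] +
                               eym * u[n - nx] + eyp * u[n + nx] +
                               ezm * u[n - nx * ny] + ezp * u[n + nx * ny] +
                               src[n];
            const double unew = (1.0 - omega) * u[n] +
                                omega * num / (ssum + h2 * lambda[n]);
            const double d = std::fabs(unew - u[n]);
            if (d > maxd) maxd = d;
            const double au = std::fabs(unew);
            if (au > maxu) maxu = au;
            u[n] = unew;
          }
        }
      }
    }
    resid_hist.push_back(maxd);
    if (maxd <= tol * (maxu > 0.0 ? maxu : 1.0)) { converged = true; break; }
  }
  return List::create(_["u"] = u, _["iterations"] = iter,
                      _["converged"] = converged,
                      _["residual_history"] = wrap(resid_hist));
}

// Screened Coulomb sum over point charges, evaluated at every grid node:
//   sum_i pref * q_i * exp(-kappa * r_i) / (eps * r_i)
// Nodes closer than rmin to a charge get the capped value cap_per_q * q_i
// (cell-average of 1/r over one grid cell), keeping the field finite when a
// charge coincides with a node.
// [[Rcpp::export]]
NumericVector coulomb_grid_cpp(IntegerVector dims, NumericVector origin,
                               double h, NumericMatrix charge_xyz,
                               NumericVector q, double eps, double kappa,
                               double pref, double rmin, double cap_per_q) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nq = charge_xyz.nrow();
  NumericVector g(nx * ny * nz);
  for (int k = 0; k < nz; ++k) {
    const double z = origin[2] + k * h;
    for (int j = 0; j < ny; ++j) {
      const double y = origin[1] + j * h;
      for (int i = 0; i < nx; ++i) {
        const double x = origin[0] + i * h;
        double s = 0.0;
        for (int c = 0; c < nq; ++c) {
          const double dx = x - charge_xyz(c, 0), dy = y - charge_xyz(c, 1),
                       dz = z - charge_xyz(c, 2);
          const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < rmin) {
            s += q[c] * cap_per_q;
          } else {
            s += pref * q[c] * std::exp(-kappa * r) / (eps * r);
          }
        }
        g[i + nx * (j + ny * k)] = s;
      }
    }
  }
  return g;
}

// Shrake-Rupley accessible surface: for each atom, the fraction of a fixed
// deterministic point set on its probe-expanded sphere not buried inside any
// neighbour's expanded sphere.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii, double probe,
                       NumericMatrix sphere_pts) {
  const int n = xyz.nrow();
  const int npts = sphere_pts.nrow();
  NumericVector area(n);
  std::vector<double> rexp(n);
  for (int i = 0; i < n; ++i) rexp[i] = radii[i] + probe;
  for (int i = 0; i < n; ++i) {
    const double ri = rexp[i];
    // neighbours that can occlude atom i
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xyz(j, 0) - xyz(i, 0), dy = xyz(j, 1) - xyz(i, 1),
                   dz = xyz(j, 2) - xyz(i, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double rr = ri + rexp[j];
      if (d2 < rr * rr) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < npts; ++p) {
      const double px = xyz(i, 0) + ri * sphere_pts(p, 0);
      const double py = xyz(i, 1) + ri * sphere_pts(p, 1);
      const double pz = xyz(i, 2) + ri * sphere_pts(p, 2);
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        const double dx = px - xyz(j, 0), dy = py - xyz(j, 1),
                     dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rexp[j] * rexp[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)npts;
  }
  return area;
}
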