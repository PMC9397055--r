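// Steady incompressible flow through voxel domains:
//  - 6-connected flood fill from the inlet face (pore connectivity)
//  - D3Q19 two-relaxation-time lattice-Boltzmann solver with halfway
//    bounce-back no-slip walls, plug-velocity inlet and zero-pressure
//    outlet (Guo non-equilibrium extrapolation ghosts)
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector flood_fill_from_inlet(IntegerVector occ, IntegerVector dims,
                                    bool periodic_x, bool periodic_y) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector reach(n, false);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  // seed: fluid cells on the inlet face (k = 0)
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t id = i + (R_xlen_t)nx * j;
      if (occ[id] == 0) { reach[id] = true; stack.push_back(id); }
    }
  const int di[6] = { 1, -1, 0, 0, 0, 0 };
  const int dj[6] = { 0, 0, 1, -1, 0, 0 };
  const int dk[6] = { 0, 0, 0, 0, 1, -1 };
  while (!stack.empty()) {
    R_xlen_t id = stack.back(); stack.pop_back();
    int k = (int)(id / ((R_xlen_t)nx * ny));
    int rem = (int)(id - (R_xlen_t)nx * ny * k);
    int j = rem / nx, i = rem % nx;
    for (int q = 0; q < 6; ++q) {
      int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
      if (periodic_x) ii = (ii + nx) % nx;
      if (periodic_y) jj = (jj + ny) % ny;
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      R_xlen_t id2 = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (occ[id2] == 0 && !reach[id2]) { reach[id2] = true; stack.push_back(id2); }
    }
  }
  return reach;
}

// D3Q19 stencil
static const int EX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int EY[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int EZ[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const int OPP[19] = {0, 2, 1, 4, 3, 6, 5, 8, 7,10, 9,12,11,14,13,16,15,18,17};
static const double W[19] = {
  1.0/3,
  1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36
};

static inline double feq_q(int q, double rho, double ux, double uy, double uz,
                           double usq15) {
  const double eu = EX[q] * ux + EY[q] * uy + EZ[q] * uz;
  return W[q] * rho * (1.0 + 3.0 * eu + 4.5 * eu * eu - usq15);
}

// occ: 0 = fluid, >0 = solid. Returns lattice-unit fields on the full grid
// (NA in solid cells) plus the residual history.
// [[Rcpp::export]]
List lbm_solve(IntegerVector occ, IntegerVector dims,
               bool periodic_x, bool periodic_y,
               double u_in_lat, double tau_plus, double lambda_trt,
               double tol, double rel_tol, int max_iter, int check_every,
               bool verbose) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ncell = (R_xlen_t)nx * ny * nz;

  // fluid node indexing
  std::vector<int> id(ncell, -1);
  std::vector<int> ci, cj, ck;
  int nf = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t c = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (occ[c] == 0) {
          id[c] = nf++;
          ci.push_back(i); cj.push_back(j); ck.push_back(k);
        }
      }
  if (nf == 0) stop("impermeable domain: no fluid cells");

  // streaming sources: >=0 fluid node, -1 solid (bounce-back),
  // -2 inlet ghost, -3 outlet ghost
  std::vector<int> src((size_t)nf * 19);
  for (int n = 0; n < nf; ++n) {
    for (int q = 0; q < 19; ++q) {
      int i = ci[n] - EX[q], j = cj[n] - EY[q], k = ck[n] - EZ[q];
      if (periodic_x) i = (i + nx) % nx;
      if (periodic_y) j = (j + ny) % ny;
      int code;
      if (k < 0) code = -2;
      else if (k >= nz) code = -3;
      else if (i < 0 || i >= nx || j < 0 || j >= ny) code = -1;
      else {
        R_xlen_t c = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        code = (occ[c] == 0) ? id[c] : -1;
      }
      src[(size_t)n * 19 + q] = code;
    }
  }

  const double om_p = 1.0 / tau_plus;
  const double tau_minus = 0.5 + lambda_trt / (tau_plus - 0.5);
  const double om_m = 1.0 / tau_minus;

  std::vector<double> fA((size_t)nf * 19), fB((size_t)nf * 19);
  std::vector<double> rho(nf, 1.0), ux(nf, 0.0), uy(nf, 0.0), uz(nf, 0.0);
  std::vector<double> ux_chk(nf, 0.0), uy_chk(nf, 0.0), uz_chk(nf, 0.0);
  for (int n = 0; n < nf; ++n)
    for (int q = 0; q < 19; ++q) fA[(size_t)n * 19 + q] = W[q];

  std::vector<double> hist_step, hist_res, hist_rel;
  bool converged = false;
  int steps = 0;
  double fin[19];

  for (int t = 1; t <= max_iter; ++t) {
    const std::vector<double>& fprev = (t % 2) ? fA : fB;
    std::vector<double>& fnext = (t % 2) ? fB : fA;
    for (int n = 0; n < nf; ++n) {
      const size_t b = (size_t)n * 19;
      const double rn = rho[n], uxn = ux[n], uyn = uy[n], uzn = uz[n];
      const double usq15_n = 1.5 * (uxn * uxn + uyn * uyn + uzn * uzn);
      const double usq15_in = 1.5 * (u_in_lat * u_in_lat);
      for (int q = 0; q < 19; ++q) {
        const int s = src[b + q];
        if (s >= 0) {
          fin[q] = fprev[(size_t)s * 19 + q];
        } else if (s == -1) {
          fin[q] = fprev[b + OPP[q]];
        } else if (s == -2) {
          // inlet: plug velocity (0,0,u_in), non-equilibrium from this node
          fin[q] = feq_q(q, rn, 0.0, 0.0, u_in_lat, usq15_in) +
            (fprev[b + q] - feq_q(q, rn, uxn, uyn, uzn, usq15_n));
        } else {
          // outlet: zero gauge pressure, zeroth-order velocity extrapolation
          fin[q] = feq_q(q, 1.0, uxn, uyn, uzn, usq15_n) +
            (fprev[b + q] - feq_q(q, rn, uxn, uyn, uzn, usq15_n));
        }
      }
      double r = 0.0;
      for (int q = 0; q < 19; ++q) r += fin[q];
      const double d12 = fin[1] - fin[2], d34 = fin[3] - fin[4],
        d56 = fin[5] - fin[6], d78 = fin[7] - fin[8], d910 = fin[9] - fin[10],
        d1112 = fin[11] - fin[12], d1314 = fin[13] - fin[14],
        d1516 = fin[15] - fin[16], d1718 = fin[17] - fin[18];
      const double vx = (d12 + d78 + d910 + d1112 + d1314) / r;
      const double vy = (d34 + d78 - d910 + d1516 + d1718) / r;
      const double vz = (d56 + d1112 - d1314 + d1516 - d1718) / r;
      const double usq15 = 1.5 * (vx * vx + vy * vy + vz * vz);
      const double t0 = 1.0 - usq15;
      // pairwise TRT collision: feq+ = w r (t0 + 4.5 eu^2), feq- = 3 w r eu
      fnext[b] = fin[0] - om_p * (fin[0] - (1.0 / 3.0) * r * t0);
      const double EU[9] = { vx, vy, vz, vx + vy, vx - vy, vx + vz, vx - vz,
                             vy + vz, vy - vz };
      for (int pz = 0; pz < 9; ++pz) {
        const int q = 1 + 2 * pz, qb = q + 1;
        const double w = (pz < 3) ? (1.0 / 18.0) : (1.0 / 36.0);
        const double eu = EU[pz];
        const double ep = w * r * (t0 + 4.5 * eu * eu);
        const double em = 3.0 * w * r * eu;
        const double fp = 0.5 * (fin[q] + fin[qb]), fm = 0.5 * (fin[q] - fin[qb]);
        const double dp = om_p * (fp - ep), dm = om_m * (fm - em);
        fnext[b + q] = fin[q] - dp - dm;
        fnext[b + qb] = fin[qb] - dp + dm;
      }
      rho[n] = r; ux[n] = vx; uy[n] = vy; uz[n] = vz;
    }
    steps = t;
    if (t % check_every == 0) {
      double sd = 0.0, su = 0.0;
      for (int n = 0; n < nf; ++n) {
        const double dx = ux[n] - ux_chk[n], dy = uy[n] - uy_chk[n],
          dz = uz[n] - uz_chk[n];
        sd += dx * dx + dy * dy + dz * dz;
        su += ux[n] * ux[n] + uy[n] * uy[n] + uz[n] * uz[n];
        ux_chk[n] = ux[n]; uy_chk[n] = uy[n]; uz_chk[n] = uz[n];
      }
      const double res = std::sqrt(sd / nf) / (u_in_lat * check_every);
      const double rel = (su > 0.0) ? std::sqrt(sd / su) : 1.0;
      hist_step.push_back(t); hist_res.push_back(res); hist_rel.push_back(rel);
      if (verbose) Rcpp::Rcout << "step " << t << " residual " << res
                               << " rel.change " << rel << "\n";
      if (res < tol && rel < rel_tol) { converged = true; break; }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericVector Ux(ncell, NA_REAL), Uy(ncell, NA_REAL), Uz(ncell, NA_REAL),
    Rho(ncell, NA_REAL);
  for (int n = 0; n < nf; ++n) {
    R_xlen_t c = ci[n] + (R_xlen_t)nx * (cj[n] + (R_xlen_t)ny * ck[n]);
    Ux[c] = ux[n]; Uy[c] = uy[n]; Uz[c] = uz[n]; Rho[c] = rho[n];
  }
  return List::create(
    _["ux"] = Ux, _["uy"] = Uy, _["uz"] = Uz, _["rho"] = Rho,
    _["steps"] = steps, _["converged"] = converged,
    _["hist_step"] = wrap(hist_step), _["hist_residual"] = wrap(hist_res),
    _["hist_rel_change"] = wrap(hist_rel), _["n_fluid"] = nf);
}
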