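// Explicit FTCS reaction-diffusion stepper for community growth on an
// agarose column. Two metabolite fields (lysine L, hypoxanthine A) diffuse
// in a 3-D grid with no-flux boundaries and a per-layer diffusion
// coefficient; two biomass fields (cells per lateral grid element) live in
// the top layer, grow by Moser kinetics on the local metabolite, consume a
// fixed amount per birth and release at a per-cell rate (the lysine release
// rate optionally interpolated from a piecewise law in the local
// hypoxanthine concentration, or linear in the releaser's net growth rate).
//
// Units: lengths um, time h, concentrations uM, per-cell amounts fmole,
// D in um^2/h. uM = fmole / voxel_mL * 1e-6.

#include <Rcpp.h>
using namespace Rcpp;

static inline double moser(double s, double bmax, double K, double n) {
  if (s <= 0.0) return 0.0;
  double sn = std::pow(s, n);
  return bmax * sn / (sn + std::pow(K, n));
}

static inline double interp_clamped(const NumericVector& x,
                                    const NumericVector& y, double q) {
  int m = x.size();
  if (q <= x[0]) return y[0];
  if (q >= x[m - 1]) return y[m - 1];
  int i = 1;
  while (x[i] < q) ++i;
  double w = (q - x[i - 1]) / (x[i] - x[i - 1]);
  return y[i - 1] + w * (y[i] - y[i - 1]);
}

// [[Rcpp::export(name = ".spatial_core")]]
List spatial_core(NumericVector L, NumericVector A,
                  NumericVector nL, NumericVector nA,
                  int nx, int ny, int nz,
                  double dx, double dz,
                  NumericVector D_layer_um2_h,
                  List params, double dt, int n_steps, int record_every) {
  NumericVector Lw = clone(L), Aw = clone(A);
  NumericVector nLw = clone(nL), nAw = clone(nA);
  NumericVector Lbuf(Lw.size()), Abuf(Aw.size());

  const double bmaxL = params["bmaxL"], KL = params["KL"], nnL = params["nL"];
  const double bmaxA = params["bmaxA"], KA = params["KA"], nnA = params["nA"];
  const double dL_rate = params["dL"], dA_rate = params["dA"];
  const double cL = params["cL"], cA = params["cA"];
  const double rA = params["rA"];
  const int law_type = params["law_type"];  // 0 fixed, 1 linear(g), 2 table(H)
  const double rL_fixed = params["rL_fixed"];
  const double rL_icept = params["rL_intercept"], rL_slope = params["rL_slope"];
  const NumericVector lawH = params["law_H"], lawR = params["law_r"];
  const double voxel_mL = dx * dx * dz * 1e-12;   // um^3 -> mL
  const double conv = 1e-6 / voxel_mL;            // fmole -> uM in one voxel

  const double inv_dx2 = 1.0 / (dx * dx), inv_dz2 = 1.0 / (dz * dz);
  const int nxy = nx * ny;
  int n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_nL(n_rec), rec_nA(n_rec);
  double cum_release_L = 0, cum_cons_L = 0, cum_release_A = 0, cum_cons_A = 0;

  auto idx = [&](int i, int j, int k) { return i + nx * j + nxy * k; };

  auto record = [&](int slot, double t) {
    double sL = 0, sA = 0;
    for (int q = 0; q < nxy; ++q) { sL += nLw[q]; sA += nAw[q]; }
    rec_t[slot] = t; rec_nL[slot] = sL; rec_nA[slot] = sA;
  };
  record(0, 0.0);
  int slot = 1;

  for (int step = 1; step <= n_steps; ++step) {
    // diffusion (flux form, no-flux boundaries, per-layer D with
    // face-averaged vertical coefficients)
    for (int pass = 0; pass < 2; ++pass) {
      NumericVector& F = pass == 0 ? Lw : Aw;
      NumericVector& G = pass == 0 ? Lbuf : Abuf;
      for (int k = 0; k < nz; ++k) {
        double Dk = D_layer_um2_h[k];
        double Ddn = k + 1 < nz ? 0.5 * (Dk + D_layer_um2_h[k + 1]) : 0.0;
        double Dup = k > 0 ? 0.5 * (Dk + D_layer_um2_h[k - 1]) : 0.0;
        for (int j = 0; j < ny; ++j) {
          for (int i = 0; i < nx; ++i) {
            int q = idx(i, j, k);
            double c0 = F[q], acc = 0.0;
            if (i > 0)      acc += Dk * (F[q - 1] - c0) * inv_dx2;
            if (i < nx - 1) acc += Dk * (F[q + 1] - c0) * inv_dx2;
            if (j > 0)      acc += Dk * (F[q - nx] - c0) * inv_dx2;
            if (j < ny - 1) acc += Dk * (F[q + nx] - c0) * inv_dx2;
            if (k > 0)      acc += Dup * (F[q - nxy] - c0) * inv_dz2;
            if (k < nz - 1) acc += Ddn * (F[q + nxy] - c0) * inv_dz2;
            G[q] = c0 + dt * acc;
          }
        }
      }
      for (int q = 0; q < F.size(); ++q) F[q] = G[q];
    }

    // reaction in the top (community) layer, k = 0
    for (int q = 0; q < nxy; ++q) {
      double l = Lw[q] > 0 ? Lw[q] : 0.0;
      double a = Aw[q] > 0 ? Aw[q] : 0.0;
      double bL = moser(l, bmaxL, KL, nnL);
      double bA = moser(a, bmaxA, KA, nnA);
      double rL;
      if (law_type == 2)      rL = interp_clamped(lawH, lawR, a);
      else if (law_type == 1) rL = std::max(0.0, rL_icept + rL_slope * (bA - dA_rate));
      else                    rL = rL_fixed;

      double cells_L = nLw[q], cells_A = nAw[q];
      double births_L = bL * cells_L * dt, births_A = bA * cells_A * dt;
      double rel_L = rL * cells_A * dt, rel_A = rA * cells_L * dt;  // fmole
      double cons_L = cL * births_L, cons_A = cA * births_A;        // fmole

      nLw[q] += births_L - dL_rate * cells_L * dt;
      nAw[q] += births_A - dA_rate * cells_A * dt;
      Lw[q] += (rel_L - cons_L) * conv;
      Aw[q] += (rel_A - cons_A) * conv;
      cum_release_L += rel_L; cum_cons_L += cons_L;
      cum_release_A += rel_A; cum_cons_A += cons_A;
    }

    if (step % record_every == 0 && slot < n_rec) {
      record(slot, step * dt);
      ++slot;
    }
  }

  return List::create(
    _["time_h"] = rec_t[Range(0, slot - 1)],
    _["total_L_cells"] = rec_nL[Range(0, slot - 1)],
    _["total_A_cells"] = rec_nA[Range(0, slot - 1)],
    _["L_field"] = Lw, _["A_field"] = Aw,
    _["nL"] = nLw, _["nA"] = nAw,
    _["cum_release_L_fmole"] = cum_release_L,
    _["cum_consumption_L_fmole"] = cum_cons_L,
    _["cum_release_A_fmole"] = cum_release_A,
    _["cum_consumption_A_fmole"] = cum_cons_A);
}
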