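#include <Rcpp.h>
using namespace Rcpp;

// Explicit forward-Euler integration of the Pennes bioheat equation on a
// voxel grid:
//
//   rho c dT/dt = div(k grad T) + rho SAR + rho q_met + W_b c_b (T_blood - T)
//
// Face conductances use the harmonic mean of the adjacent conductivities;
// solid faces adjacent to in-grid air carry a Robin (convective) flux
// h (T - T_ambient); faces on the domain boundary are adiabatic.  The
// lumped blood pool, when enabled, evolves with the net tissue-blood
// exchange divided by its heat capacity.  Perfusion may carry a
// piecewise-linear temperature ramp (factor 1 below 39 C rising to a
// per-voxel maximum at 45 C).

static inline double perfMult(double T, double mmax, int ramp) {
  if (!ramp || mmax <= 1.0) return 1.0;
  if (T <= 39.0) return 1.0;
  if (T >= 45.0) return mmax;
  return 1.0 + (mmax - 1.0) * (T - 39.0) / 6.0;
}

// [[Rcpp::export]]
List cpp_bioheat_run(IntegerVector solid, NumericVector rho, NumericVector ch,
                     NumericVector kc, NumericVector wb, NumericVector qmet,
                     NumericVector sar, NumericVector mmax, int perfRamp,
                     IntegerVector dims, NumericVector vox_m, double h,
                     double Tamb, NumericVector T0, double Tblood0,
                     int variableCore, double Vb_m3, double rhoB, double cB,
                     double dt, int nsteps, int recordEvery,
                     IntegerVector coreMask, IntegerVector skinMask) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double dx = vox_m[0], dy = vox_m[1], dz = vox_m[2];
  const double dV = dx * dy * dz;
  const double inv2[3] = {1.0 / (dx * dx), 1.0 / (dy * dy), 1.0 / (dz * dz)};
  const double hInv[3] = {h / dx, h / dy, h / dz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};

  std::vector<double> Tc(T0.begin(), T0.end()), Tn(n);
  double Tb = Tblood0;
  const int *sol = INTEGER(solid);
  const double *prho = REAL(rho), *pch = REAL(ch), *pk = REAL(kc),
               *pwb = REAL(wb), *pq = REAL(qmet), *psar = REAL(sar),
               *pmx = REAL(mmax);

  // collect solid voxel indices once
  std::vector<R_xlen_t> sv;
  sv.reserve(n / 2);
  for (R_xlen_t i = 0; i < n; ++i) if (sol[i]) sv.push_back(i);

  // precompute core / skin mass weights
  double coreW = 0.0, skinW = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (coreMask[i]) coreW += prho[i];
    if (skinMask[i]) skinW += prho[i];
  }

  int nrec = nsteps / std::max(recordEvery, 1) + 2;
  NumericMatrix series(nrec, 6);
  colnames(series) = CharacterVector::create("t_s", "T_core_C", "T_max_C",
                                             "T_blood_C", "T_skin_mean_C",
                                             "energy_J");
  int irec = 0;
  int lastRecorded = -1;
  auto record = [&](int stepDone) {
    lastRecorded = stepDone;
    double tcore = 0.0, tmax = -1e300, tskin = 0.0, energy = 0.0;
    for (size_t u = 0; u < sv.size(); ++u) {
      R_xlen_t i = sv[u];
      double T = Tc[i];
      if (T > tmax) tmax = T;
      if (coreMask[i]) tcore += prho[i] * T;
      if (skinMask[i]) tskin += prho[i] * T;
      energy += prho[i] * pch[i] * T * dV;
    }
    energy += Vb_m3 * rhoB * cB * Tb;
    series(irec, 0) = stepDone * dt;
    series(irec, 1) = coreW > 0 ? tcore / coreW : NA_REAL;
    series(irec, 2) = tmax;
    series(irec, 3) = Tb;
    series(irec, 4) = skinW > 0 ? tskin / skinW : NA_REAL;
    series(irec, 5) = energy;
    ++irec;
  };
  record(0);

  const double bloodCap = Vb_m3 * rhoB * cB;
  int xyz[3];
  for (int step = 1; step <= nsteps; ++step) {
    double exch = 0.0;
    for (size_t u = 0; u < sv.size(); ++u) {
      const R_xlen_t i = sv[u];
      const double T = Tc[i];
      xyz[2] = (int)(i / strides[2]);
      xyz[1] = (int)((i / strides[1]) % ny);
      xyz[0] = (int)(i % nx);
      const int hi[3] = {nx - 1, ny - 1, nz - 1};
      double flux = 0.0;
      for (int ax = 0; ax < 3; ++ax) {
        for (int s = -1; s <= 1; s += 2) {
          int c = xyz[ax] + s;
          if (c < 0 || c > hi[ax]) continue;          // domain edge: adiabatic
          R_xlen_t j = i + s * strides[ax];
          if (sol[j]) {
            double kf = 2.0 * pk[i] * pk[j] / (pk[i] + pk[j]);
            flux += kf * (Tc[j] - T) * inv2[ax];
          } else {
            flux -= hInv[ax] * (T - Tamb);            // Robin to ambient
          }
        }
      }
      const double mult = perfMult(T, pmx[i], perfRamp);
      const double wcb = pwb[i] * cB * mult;
      const double src = prho[i] * (psar[i] + pq[i]) + wcb * (Tb - T);
      Tn[i] = T + dt * (flux + src) / (prho[i] * pch[i]);
      exch += wcb * (T - Tb);
    }
    if (variableCore && bloodCap > 0) Tb += dt * exch * dV / bloodCap;
    std::swap(Tc, Tn);
    if (step % std::max(recordEvery, 1) == 0 && irec < nrec) {
      record(step);
      double tmax = series(irec - 1, 2);
      if (!std::isfinite(tmax) || std::fabs(tmax) > 150.0 ||
          !std::isfinite(Tb))
        stop("thermal solver instability detected at t = %g s (T_max = %g)",
             step * dt, tmax);
    }
  }

  if (lastRecorded != nsteps && irec < nrec) record(nsteps);

  NumericVector Tout(n, NA_REAL);
  for (size_t u = 0; u < sv.size(); ++u) Tout[sv[u]] = Tc[sv[u]];
  return List::create(_["T"] = Tout, _["Tblood"] = Tb,
                      _["series"] = series(Range(0, irec - 1), _),
                      _["t"] = nsteps * dt);
}

// Positivity (maximum-principle) time-step bound: for every solid voxel,
// dt <= rho c / (sum of face conductances per volume + perfusion
// coefficient), scaled by a 0.9 safety factor.

// [[Rcpp::export]]
double cpp_dt_bound(IntegerVector solid, NumericVector rho, NumericVector ch,
                    NumericVector kc, NumericVector wb, NumericVector mmax,
                    IntegerVector dims, NumericVector vox_m, double h,
                    double cB) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double dx = vox_m[0], dy = vox_m[1], dz = vox_m[2];
  const double inv2[3] = {1.0 / (dx * dx), 1.0 / (dy * dy), 1.0 / (dz * dz)};
  const double hInv[3] = {h / dx, h / dy, h / dz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int *sol = INTEGER(solid);
  const double *prho = REAL(rho), *pch = REAL(ch), *pk = REAL(kc),
               *pwb = REAL(wb), *pmx = REAL(mmax);
  double best = R_PosInf;
  int xyz[3];
  const int hi[3] = {nx - 1, ny - 1, nz - 1};
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!sol[i]) continue;
    xyz[2] = (int)(i / strides[2]);
    xyz[1] = (int)((i / strides[1]) % ny);
    xyz[0] = (int)(i % nx);
    double denom = pwb[i] * cB * std::max(1.0, pmx[i]);
    for (int ax = 0; ax < 3; ++ax)
      for (int s = -1; s <= 1; s += 2) {
        int c = xyz[ax] + s;
        if (c < 0 || c > hi[ax]) continue;
        R_xlen_t j = i + s * strides[ax];
        if (sol[j]) denom += 2.0 * pk[i] * pk[j] / (pk[i] + pk[j]) * inv2[ax];
        else denom += hInv[ax];
      }
    if (denom > 0) {
      double b = prho[i] * pch[i] / denom;
      if (b < best) best = b;
    }
  }
  return 0.9 * best;
}
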