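// Compiled kernel of the method-of-lines right-hand side: finite-volume
// transport plus the full reaction network, plus piecewise-linear evaluation
// of the transient boundary conditions.  Mirrors the reference R
// implementation (.transport_kernel / .reaction_extents); the test suite
// asserts that both paths produce identical tendencies.
//
// Two entry points:
//   - sediagen_rhs_core (.Call): one tendency evaluation for a given state
//     and boundary set; used by the R-driven solver path and parity tests.
//   - sediagen_derivs  (deSolve native signature): used directly by lsodes,
//     avoiding R-level call overhead; the model context is installed
//     beforehand with sediagen_set_context.
#include <Rcpp.h>
#include <R_ext/Rdynload.h>
#include <vector>
using namespace Rcpp;

// Species indices (must match .SPECIES in R/reactions.R)
enum {
  iO2 = 0, iNO3, iSO4, iNH4, iMn2, iFe2, iHS, iCH4,
  iCO2, iHCO3, iN2, iHPO4,
  iOM1, iOM2, iMo1, iMo2, iFoh1, iFoh2,
  iFeS, iFeS2, iViv, iMnCO3, NSPEC
};

// Parameter vector layout (must match .kvec in R/simulate.R)
enum {
  pPor = 0, pRho, pDdbl, pDbmin, pL, pFdnra, pNy, pNz, pNs,
  pKdO2, pKdNO3, pKdMn, pKdFe, pKdSO4, pKdCH4,
  pKO2, pKNO3, pKMn, pKFe, pKSO4,
  pNhox, pMox, pFox, pSox, pChox,
  pNhmo, pNhmx, pNhfo, pNhfx,
  pFmo, pFmx, pSmo, pSmx, pSfo, pSfx,
  pChso, pMoN,
  pVivpre, pVivdis, pEqViv, pSviv,
  pFeSpre, pFeSdis, pEqFeS, pPyrpre,
  pMnCpre, pEqHCO3, pEqMnC, pHplus, NPAR
};

static inline double guard(double c, double L) {
  return c > 0.0 ? c / (c + L) : 0.0;
}

// C1-smooth replacement for max(x, 0) that is exactly zero for x <= 0:
// quadratic blending over [0, eps] keeps the curvature bounded at 1/eps
// (no derivative discontinuity for the stiff integrator) without leaking
// any rate below the threshold.
static inline double hinge(double x, double eps) {
  if (x <= 0.0) return 0.0;
  if (x >= eps) return x - 0.5 * eps;
  return 0.5 * x * x / eps;
}

struct ModelCtx {
  int n = 0, nreact = 0;
  std::vector<double> kvec, h, dxc, shape, Dsed, Dmol;
  std::vector<double> S;          // nreact x NSPEC, row-major
  std::vector<int> goff, gidx;
  // boundary timelines for NSPEC species + Db0 + sed_rate (NVAR = 24)
  std::vector<std::vector<double>> byears, bvals;
  std::vector<double> amp, scale;
  bool seasonal = false, frozen = false;
  int interleaved = 0;
  double frozen_t = 0.0;
};
static ModelCtx G;
static const int NVAR = NSPEC + 2;

// piecewise-linear with constant extrapolation
static double interp_bp(const std::vector<double> &xs,
                        const std::vector<double> &ys, double t) {
  const int m = (int) xs.size();
  if (t <= xs[0]) return ys[0];
  if (t >= xs[m - 1]) return ys[m - 1];
  int j = 1;
  while (xs[j] < t) ++j;
  double w = (t - xs[j - 1]) / (xs[j] - xs[j - 1]);
  return ys[j - 1] * (1.0 - w) + ys[j] * w;
}

static void eval_boundary(double t, double *bv) {
  if (G.frozen) t = G.frozen_t;
  double cs = std::cos(2.0 * M_PI * t);
  for (int v = 0; v < NVAR; ++v) {
    double x = interp_bp(G.byears[v], G.bvals[v], t) * G.scale[v];
    if (G.seasonal && G.amp[v] != 0.0) x *= (1.0 + G.amp[v] * cs);
    bv[v] = x;
  }
}

// The core tendency kernel shared by both entry points.
static void kernel(const double *y, double *dy, const double *kv, int n,
                   int nreact, const double *h, const double *dxc,
                   const double *shape, const double *Dsed,
                   const double *Dmol, const double *S, const int *goff,
                   const int *gidx, double Db0, double v, const double *B,
                   const double *J, int interleaved) {
  // state layout strides: species-major (default) or node-major
  const int ss = interleaved ? 1 : n;      // stride between species
  const int si = interleaved ? NSPEC : 1;  // stride between nodes
  const double phi = kv[pPor];
  const double m = kv[pRho] * (1.0 - phi);   // g solid per cm^3 bulk
  const double m_phi = m / phi;              // g solid per cm^3 porewater
  const double L = kv[pL];

  std::vector<double> Dbint(n - 1);
  for (int j = 0; j < n - 1; ++j) Dbint[j] = Db0 * shape[j] + kv[pDbmin];

  // ---- transport ----------------------------------------------------------
  for (int s = 0; s < NSPEC; ++s) {
    const double *C = y + s * ss;
    double *d = dy + s * ss;
    const bool solute = s < 12;
    const double eps = solute ? phi : m;
    double Fprev = solute ? Dmol[s] * (B[s] - C[0]) / kv[pDdbl] : J[s - 12];
    for (int j = 0; j < n - 1; ++j) {
      double D = solute ? Dbint[j] + Dsed[s] : Dbint[j];
      double F = -eps * D * (C[(j + 1) * si] - C[j * si]) / dxc[j] +
                 eps * v * C[j * si];
      d[j * si] = (Fprev - F) / (eps * h[j]);
      Fprev = F;
    }
    double Fbot = eps * v * C[(n - 1) * si];
    d[(n - 1) * si] = (Fprev - Fbot) / (eps * h[n - 1]);
  }

  // ---- reactions ----------------------------------------------------------
  // Rate laws are evaluated on the raw state: every consumption term is
  // linear (or Monod) in the consumed species, so it vanishes at zero and
  // continues smoothly (restoring) for the small negative excursions a
  // multistep integrator can produce.  Clamping instead creates derivative
  // discontinuities exactly where trace species live and destroys the
  // integrator's step-size control.
  std::vector<double> ext(nreact);
  double c[NSPEC];
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < NSPEC; ++s) {
      double cc = y[s * ss + i * si];
      c[s] = (s < 12) ? cc : cc * m_phi;
    }
    // native solid contents for the oxide limitation terms and mineral laws
    double Mo1_solid = c[iMo1] / m_phi;
    double Foh1_solid = c[iFoh1] / m_phi;
    double FeS_solid = c[iFeS] / m_phi;
    double Viv_solid = c[iViv] / m_phi;

    // mineralization cascade factors; the oxide terms use the reactive
    // pools, which are the pools the pathways actually consume
    double l1 = c[iO2] / (std::fabs(c[iO2]) + kv[pKO2]);
    double l2 = c[iNO3] / (std::fabs(c[iNO3]) + kv[pKNO3]);
    double l3 = Mo1_solid / (std::fabs(Mo1_solid) + kv[pKMn]);
    double l4 = Foh1_solid / (std::fabs(Foh1_solid) + kv[pKFe]);
    double l5 = c[iSO4] / (std::fabs(c[iSO4]) + kv[pKSO4]);
    double cum = 1.0, f[6];
    f[0] = l1; cum *= (1.0 - l1);
    f[1] = l2 * cum; cum *= (1.0 - l2);
    f[2] = l3 * cum; cum *= (1.0 - l3);
    f[3] = l4 * cum; cum *= (1.0 - l4);
    f[4] = l5 * cum; cum *= (1.0 - l5);
    f[5] = cum;

    double OM1pw = c[iOM1];
    int r = 0;
    ext[r++] = kv[pKdO2] * f[0] * OM1pw;                       // min_O2
    double denit = kv[pKdNO3] * f[1] * OM1pw;
    ext[r++] = (1.0 - kv[pFdnra]) * denit;                     // min_NO3
    ext[r++] = kv[pFdnra] * denit;                             // min_DNRA
    ext[r++] = kv[pKdMn] * f[2] * OM1pw;                       // min_MnO2
    ext[r++] = kv[pKdFe] * f[3] * OM1pw;                       // min_FeOOH
    ext[r++] = kv[pKdSO4] * f[4] * OM1pw;                      // min_SO4
    ext[r++] = kv[pKdCH4] * f[5] * OM1pw;                      // min_CH4
    ext[r++] = kv[pNhox] * c[iNH4] * c[iO2];                   // nhox
    ext[r++] = kv[pMox] * c[iMn2] * c[iO2];                    // mox
    ext[r++] = kv[pFox] * c[iFe2] * c[iO2];                    // fox
    ext[r++] = kv[pSox] * c[iHS] * c[iO2];                     // sox
    ext[r++] = kv[pChox] * c[iCH4] * c[iO2];                   // chox
    ext[r++] = kv[pNhmo] * c[iNH4] * c[iMo1];                  // nhmo
    ext[r++] = kv[pNhmx] * c[iNH4] * c[iMo2];                  // nhmx
    ext[r++] = kv[pNhfo] * c[iNH4] * c[iFoh1];                 // nhfo
    ext[r++] = kv[pNhfx] * c[iNH4] * c[iFoh2];                 // nhfx
    ext[r++] = kv[pFmo] * c[iFe2] * c[iMo1];                   // fmo
    ext[r++] = kv[pFmx] * c[iFe2] * c[iMo2];                   // fmx
    ext[r++] = kv[pSmo] * c[iHS] * c[iMo1];                    // smo
    ext[r++] = kv[pSmx] * c[iHS] * c[iMo2];                    // smx
    ext[r++] = kv[pSfo] * c[iHS] * c[iFoh1];                   // sfo
    ext[r++] = kv[pSfx] * c[iHS] * c[iFoh2];                   // sfx
    ext[r++] = kv[pChso] * c[iCH4] * c[iSO4];                  // chso
    ext[r++] = kv[pMoN] * c[iMn2] * c[iNO3];                   // moN

    double fe_m = hinge(c[iFe2], 1e-6) * 1e-3,
           po_m = hinge(c[iHPO4], 1e-6) * 1e-3;
    double om_viv = fe_m * fe_m * fe_m * po_m * po_m / kv[pEqViv];
    // proton activity on the model concentration scale (umol cm^-3)
    double Hm = kv[pHplus] * 1e3;
    double om_fes = c[iFe2] * c[iHS] / Hm / kv[pEqFeS];
    double co3 = kv[pEqHCO3] * c[iHCO3] / Hm;
    double om_mnc = c[iMn2] * co3 / kv[pEqMnC];
    ext[r++] = kv[pVivpre] * hinge(om_viv - 1.0, 0.1) * m_phi;   // viv_pre
    ext[r++] = kv[pVivdis] * Viv_solid * hinge(1.0 - om_viv, 0.1) * m_phi;
    ext[r++] = kv[pSviv] * Viv_solid * c[iHS] * m_phi;            // viv_sulf
    ext[r++] = kv[pFeSpre] * hinge(om_fes - 1.0, 0.1) * m_phi;   // FeS_pre
    ext[r++] = kv[pFeSdis] * FeS_solid * hinge(1.0 - om_fes, 0.1) * m_phi;
    ext[r++] = kv[pPyrpre] * FeS_solid * c[iHS] * m_phi;          // pyr_pre
    ext[r++] = kv[pMnCpre] * hinge(om_mnc - 1.0, 0.1) * m_phi;   // MnCO3_pre

    // L-guard on every consumed species, then source assembly
    for (int q = 0; q < nreact; ++q) {
      double g = 1.0;
      for (int k = goff[q]; k < goff[q + 1]; ++k)
        g *= guard(c[gidx[k]], L);
      double e = ext[q] * g;
      if (e == 0.0) continue;
      const double *Srow = S + (size_t) q * NSPEC;
      for (int s = 0; s < NSPEC; ++s) {
        double sv = Srow[s];
        if (sv != 0.0)
          dy[s * ss + i * si] += (s < 12) ? e * sv : e * sv / m_phi;
      }
    }
  }
}

// ---- .Call entry points ----------------------------------------------------

extern "C" SEXP sediagen_rhs_core(SEXP ySEXP, SEXP ctxSEXP, SEXP Db0SEXP,
                                  SEXP vSEXP, SEXP BSEXP, SEXP JSEXP) {
  BEGIN_RCPP
  NumericVector y(ySEXP), B(BSEXP), J(JSEXP);
  List ctx(ctxSEXP);
  NumericVector kv = ctx["kvec"], h = ctx["h"], dxc = ctx["dxc"],
                shape = ctx["Db_shape"], Dsed = ctx["D_sed"],
                Dmol = ctx["D_mol"];
  NumericMatrix Sm = ctx["S"];
  IntegerVector goff = ctx["guard_off"], gidx = ctx["guard_idx"];
  const int n = h.size(), nreact = Sm.nrow();
  if (kv.size() != NPAR) stop("parameter vector length mismatch");
  if (Sm.ncol() != NSPEC) stop("stoichiometry matrix width mismatch");
  std::vector<double> Srm((size_t) nreact * NSPEC);
  for (int q = 0; q < nreact; ++q)
    for (int s = 0; s < NSPEC; ++s) Srm[(size_t) q * NSPEC + s] = Sm(q, s);
  NumericVector dy(NSPEC * n);
  kernel(y.begin(), dy.begin(), kv.begin(), n, nreact, h.begin(),
         dxc.begin(), shape.begin(), Dsed.begin(), Dmol.begin(), Srm.data(),
         goff.begin(), gidx.begin(), as<double>(Db0SEXP),
         as<double>(vSEXP), B.begin(), J.begin(), 0);
  return dy;
  END_RCPP
}

extern "C" SEXP sediagen_set_context(SEXP ctxSEXP, SEXP bndSEXP) {
  BEGIN_RCPP
  List ctx(ctxSEXP), bnd(bndSEXP);
  NumericVector kv = ctx["kvec"], h = ctx["h"], dxc = ctx["dxc"],
                shape = ctx["Db_shape"], Dsed = ctx["D_sed"],
                Dmol = ctx["D_mol"];
  NumericMatrix Sm = ctx["S"];
  IntegerVector goff = ctx["guard_off"], gidx = ctx["guard_idx"];
  if (kv.size() != NPAR) stop("parameter vector length mismatch");
  if (Sm.ncol() != NSPEC) stop("stoichiometry matrix width mismatch");
  G.n = h.size();
  G.nreact = Sm.nrow();
  G.kvec.assign(kv.begin(), kv.end());
  G.h.assign(h.begin(), h.end());
  G.dxc.assign(dxc.begin(), dxc.end());
  G.shape.assign(shape.begin(), shape.end());
  G.Dsed.assign(Dsed.begin(), Dsed.end());
  G.Dmol.assign(Dmol.begin(), Dmol.end());
  G.S.resize((size_t) G.nreact * NSPEC);
  for (int q = 0; q < G.nreact; ++q)
    for (int s = 0; s < NSPEC; ++s) G.S[(size_t) q * NSPEC + s] = Sm(q, s);
  G.goff.assign(goff.begin(), goff.end());
  G.gidx.assign(gidx.begin(), gidx.end());
  List years = bnd["years"], vals = bnd["values"];
  if (years.size() != NVAR || vals.size() != NVAR)
    stop("boundary table must have one timeline per species + Db0 + sed_rate");
  G.byears.assign(NVAR, std::vector<double>());
  G.bvals.assign(NVAR, std::vector<double>());
  for (int v = 0; v < NVAR; ++v) {
    NumericVector xs = years[v], ys = vals[v];
    if (xs.size() != ys.size() || xs.size() < 1)
      stop("malformed boundary timeline");
    G.byears[v].assign(xs.begin(), xs.end());
    G.bvals[v].assign(ys.begin(), ys.end());
  }
  NumericVector amp = bnd["amp"], scale = bnd["scale"];
  G.amp.assign(amp.begin(), amp.end());
  G.scale.assign(scale.begin(), scale.end());
  G.seasonal = as<bool>(bnd["seasonal"]);
  G.interleaved = as<int>(bnd["interleaved"]);
  G.frozen = as<bool>(bnd["frozen"]);
  G.frozen_t = as<double>(bnd["frozen_t"]);
  return R_NilValue;
  END_RCPP
}

// ---- deSolve native entry point --------------------------------------------

extern "C" void sediagen_derivs(int *neq, double *t, double *y, double *ydot,
                                double *yout, int *ip) {
  (void) yout; (void) ip;
  if (G.n == 0 || *neq != NSPEC * G.n)
    Rf_error("sediagen model context not initialized for this problem size");
  double bv[NVAR];
  eval_boundary(*t, bv);
  kernel(y, ydot, G.kvec.data(), G.n, G.nreact, G.h.data(), G.dxc.data(),
         G.shape.data(), G.Dsed.data(), G.Dmol.data(), G.S.data(),
         G.goff.data(), G.gidx.data(), bv[NSPEC], bv[NSPEC + 1], bv, bv + 12,
         G.interleaved);
}

// ---- registration -----------------------------------------------------------

static const R_CallMethodDef CallEntries[] = {
  {"sediagen_rhs_core", (DL_FUNC) &sediagen_rhs_core, 6},
  {"sediagen_set_context", (DL_FUNC) &sediagen_set_context, 2},
  {NULL, NULL, 0}
};

extern "C" void R_init_sediagen(DllInfo *dll) {
  R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);   // deSolve looks sediagen_derivs up by name
}
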