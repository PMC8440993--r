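#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Compartment order everywhere: 0 brain, 1 fat/bone, 2 central, 3 muscle.
// Gas order: 0 N2, 1 O2, 2 CO2.  Pressures/tensions in ATA, volumes in ml,
// flows in ml/min, time internally in minutes (1 Hz samples = 1/60 min).

static inline double hillS(double p, double p50, double h) {
  if (p <= 0.0) return 0.0;
  double ph = std::pow(p, h);
  return ph / (std::pow(p50, h) + ph);
}

struct Pars {
  double Vc[4];        // compartment volumes, ml
  double bN2[4];       // tissue N2 solubility per compartment
  double fS[4], fD[4]; // flow splits, surface / diving
  double mr[4];        // diving metabolic rate per compartment, ml O2/min
  double bN2b, bO2, bCO2;
  double hb, p50, hillH, o2cap;
  double mbCap, mbP50; // muscle Mb O2 capacity (ml) and half-saturation (ATA)
  double rq;
  double Qs, Qd;       // total cardiac output, ml/min
  double TLC, VD0, VfAmax, dlv;
  double Kp, nAirway, rigid;
  double gamma, s0;
  double pH2O;
  double surf[3];      // surface tensions N2 O2 CO2
};

static Pars readPars(const List& par) {
  Pars p;
  NumericVector Vc = par["compVolume"], bN2 = par["betaN2"],
                fS = par["surfaceSplit"], fD = par["diveSplit"],
                mr = par["diveMR"], surf = par["surfaceTensions"];
  for (int i = 0; i < 4; ++i) {
    p.Vc[i] = Vc[i]; p.bN2[i] = bN2[i];
    p.fS[i] = fS[i]; p.fD[i] = fD[i]; p.mr[i] = mr[i];
  }
  p.bN2b = par["betaN2Blood"]; p.bO2 = par["betaO2"]; p.bCO2 = par["betaCO2"];
  p.hb = par["hb"]; p.p50 = par["p50"]; p.hillH = par["hillH"];
  p.o2cap = par["o2cap"];
  p.mbCap = par["mbCap"]; p.mbP50 = par["mbP50"];
  p.rq = par["rq"];
  p.Qs = par["qSurface"]; p.Qd = par["qDive"];
  p.TLC = par["tlc"]; p.VD0 = par["vd0"]; p.VfAmax = par["vfaMax"];
  p.dlv = par["dlv"];
  p.Kp = par["kp"]; p.nAirway = par["nAirway"]; p.rigid = par["rigidFraction"];
  p.gamma = par["shuntExponent"]; p.s0 = par["shuntBaseline"];
  p.pH2O = par["ph2o"];
  for (int g = 0; g < 3; ++g) p.surf[g] = surf[g];
  return p;
}

static inline double bloodO2Content(const Pars& p, double po2) {
  return p.o2cap * p.hb * hillS(po2, p.p50, p.hillH) + p.bO2 * po2;
}

// Tissue gas store (ml STPD) at tension t for compartment i, gas g.
static inline double tissueStore(const Pars& p, int i, int g, double t) {
  if (g == 0) return p.bN2[i] * p.Vc[i] * t;
  if (g == 1) {
    double s = p.bO2 * p.Vc[i] * t;
    if (i == 3) s += p.mbCap * t / (t + p.mbP50);
    return s;
  }
  return p.bCO2 * p.Vc[i] * t;
}

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector depths, List par, int nsub = 1) {
  const Pars p = readPars(par);
  const int n = depths.size();
  const double dtm = 1.0 / 60.0 / nsub;  // substep, minutes

  // state
  double T[4][3];  // compartment tensions
  for (int i = 0; i < 4; ++i)
    for (int g = 0; g < 3; ++g) T[i][g] = p.surf[g];
  double S[3];     // lung gas store, ml STPD (dry)
  for (int g = 0; g < 3; ++g) S[g] = p.dlv * p.TLC * p.surf[g];

  const int ncol = 30;
  NumericMatrix out(n, ncol);
  std::vector<int> evO2, evLung;

  for (int t = 0; t < n; ++t) {
    const double d = depths[t];
    const double P = 1.0 + d / 10.0;
    const bool diving = d > 0.0;

    double shunt = 0.0, vfa = 0.0;
    double pfav[3], art[3], pmv[3];

    for (int sub = 0; sub < nsub; ++sub) {
      const double* split = diving ? p.fD : p.fS;
      const double Q = diving ? p.Qd : p.Qs;
      bool collapsed = false;

      if (!diving) {
        // Breathing: lung refilled at surface composition, arterial snaps
        // to the surface constants, no metabolic offset (ventilation is
        // assumed to match metabolism while breathing).
        for (int g = 0; g < 3; ++g) {
          S[g] = p.dlv * p.TLC * p.surf[g];
          pfav[g] = p.surf[g];
          art[g] = p.surf[g];
        }
        double vTot = p.dlv * p.TLC;
        double vd = p.VD0;  // dead space at 1 ATA
        if (vd > vTot) vd = vTot;
        vfa = vTot - vd;
        if (vfa > p.VfAmax) vfa = p.VfAmax;
        shunt = 0.0;
      } else {
        double Stot = S[0] + S[1] + S[2];
        if (Stot < 1e-12) Stot = 1e-12;
        double vTot = Stot / (P - p.pH2O);
        double comp = std::pow(1.0 + (P - 1.0) / std::fabs(p.Kp), -p.nAirway);
        double vd = p.VD0 * (p.rigid + (1.0 - p.rigid) * comp);
        if (vd > vTot) vd = vTot;
        vfa = vTot - vd;
        if (vfa > p.VfAmax) vfa = p.VfAmax;
        if (vfa <= 0.0) { vfa = 0.0; collapsed = true; }
        shunt = collapsed ? 1.0
          : p.s0 + (1.0 - p.s0) * std::pow(1.0 - vfa / p.VfAmax, p.gamma);
        for (int g = 0; g < 3; ++g) {
          pfav[g] = S[g] / Stot * (P - p.pH2O);
          pmv[g] = 0.0;
          for (int i = 0; i < 4; ++i) pmv[g] += split[i] * T[i][g];
          art[g] = (1.0 - shunt) * pfav[g] + shunt * pmv[g];
        }
      }

      // store bookkeeping (exact tissue store deltas debit the lung)
      double storeOld[4][3];
      for (int i = 0; i < 4; ++i)
        for (int g = 0; g < 3; ++g) storeOld[i][g] = tissueStore(p, i, g, T[i][g]);

      double mrTot = 0.0;
      for (int i = 0; i < 4; ++i) {
        const double Qi = Q * split[i];
        const double Vi = p.Vc[i];
        const double mri = diving ? p.mr[i] : 0.0;
        mrTot += mri;

        // N2: linear, exact exponential step
        {
          const double k = Qi * p.bN2b / (Vi * p.bN2[i]);
          T[i][0] = art[0] + (T[i][0] - art[0]) * std::exp(-k * dtm);
        }
        // O2: secant blood-content slope, tissue capacitance incl. Mb
        {
          double diff = art[1] - T[i][1];
          double bs;
          if (std::fabs(diff) > 1e-12)
            bs = (bloodO2Content(p, art[1]) - bloodO2Content(p, T[i][1])) / diff;
          else {
            // derivative of the content curve at the common tension
            double t1 = T[i][1];
            double eps = 1e-8;
            bs = (bloodO2Content(p, t1 + eps) - bloodO2Content(p, t1)) / eps;
          }
          double cap = p.bO2 * Vi;
          if (i == 3) {
            double denom = T[i][1] + p.mbP50;
            cap += p.mbCap * p.mbP50 / (denom * denom);
          }
          const double k = Qi * bs / cap;
          const double u = -mri / cap;              // ATA/min sink
          const double tgt = art[1] + u / k;
          double tn = tgt + (T[i][1] - tgt) * std::exp(-k * dtm);
          if (tn < 0.0) { tn = 0.0; evO2.push_back(t + 1); }
          T[i][1] = tn;
        }
        // CO2: equal blood/tissue effective solubility, production source
        {
          const double k = Qi / Vi;
          const double u = p.rq * mri / (p.bCO2 * Vi);
          const double tgt = art[2] + u / k;
          T[i][2] = tgt + (T[i][2] - tgt) * std::exp(-k * dtm);
        }
      }

      if (diving && !collapsed) {
        for (int g = 0; g < 3; ++g) {
          double delta = 0.0;
          for (int i = 0; i < 4; ++i)
            delta += tissueStore(p, i, g, T[i][g]) - storeOld[i][g];
          if (g == 1) delta += mrTot * dtm;          // O2 consumed
          if (g == 2) delta -= p.rq * mrTot * dtm;   // CO2 produced
          S[g] -= delta;
          if (S[g] < 0.0) { S[g] = 0.0; evLung.push_back(t + 1); }
        }
      }
    }

    // record (post-update); mixed venous with the current phase's split
    const double* split = diving ? p.fD : p.fS;
    for (int g = 0; g < 3; ++g) {
      pmv[g] = 0.0;
      for (int i = 0; i < 4; ++i) pmv[g] += split[i] * T[i][g];
    }
    out(t, 0) = t; out(t, 1) = d; out(t, 2) = P; out(t, 3) = diving ? 1 : 0;
    out(t, 4) = shunt; out(t, 5) = vfa;
    for (int g = 0; g < 3; ++g) {
      out(t, 6 + g) = pfav[g];
      out(t, 9 + g) = art[g];
      out(t, 12 + g) = pmv[g];
    }
    for (int i = 0; i < 4; ++i)
      for (int g = 0; g < 3; ++g) out(t, 15 + 3 * i + g) = T[i][g];
    for (int g = 0; g < 3; ++g) {
      double inv = S[g];
      for (int i = 0; i < 4; ++i) inv += tissueStore(p, i, g, T[i][g]);
      out(t, 27 + g) = inv;
    }
  }

  return List::create(_["trajectory"] = out,
                      _["tissueO2Floor"] = wrap(evO2),
                      _["lungFloor"] = wrap(evLung));
}

// Single perfusion-limited relaxation step: exact exponential update of a
// tissue tension toward a constant arterial tension with a constant source.
// [[Rcpp::export(name = ".perfusion_step")]]
double perfusion_step(double tension, double arterial, double k, double u,
                      double dtMin) {
  double tgt = arterial + (k > 0 ? u / k : 0.0);
  double tn = tgt + (tension - tgt) * std::exp(-k * dtMin);
  return tn < 0.0 ? 0.0 : tn;
}
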