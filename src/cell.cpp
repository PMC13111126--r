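// Whole-cell time stepping core.
//
// One explicit-Euler step of length dt advances: the Hodgkin-Huxley gates of
// the background currents, the LCC (7-state) and RyR (4-state) channel
// populations -- binomial/multinomial tau-leaping in stochastic mode, the
// mean-field occupancy ODE in deterministic mode -- the three-compartment
// calcium cycling with instantaneous buffering, Na+/K+ bookkeeping, and the
// membrane potential.  All rates are frozen at the step's initial state.
//
// The R-level functions lccRates(), ryrRates(), icalCurrent(), iup(), etc.
// implement the identical formulas and are used in the test suite to
// cross-check single evaluations of this engine.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double F, R, T, Cm, Vc, Vsr, Vss;
  double Ko, Nao, Cao;
  double GNa, GK1, Gto, GKr, GKs, pKNa, GCaL, GbNa, GbCa, GpK, GpCa, KpCa;
  double PNaK, KmK, KmNa;
  double kNaCa, KmNai, KmCa, ksat, gammaNCX, alphaNCX;
  double Vmaxup, Kup, Vleak, Vxfer, Vrel;
  double Bufc, Kbufc, Bufsr, Kbufsr, Bufss, Kbufss;
  double k1p, k2p, k3, k4, maxsr, minsr, EC, gammaRyR, ryrTimeScale;
  bool  kcasrLiteral;
  double x7, fSlowScale, gCaLScale, VofsCaL, phi, eta;
  double FRT;
};

Params readParams(const NumericVector& p) {
  Params q;
  q.F = p["Faraday"]; q.R = p["Rgas"]; q.T = p["Temp"]; q.Cm = p["Cm"];
  q.Vc = p["Vc"]; q.Vsr = p["Vsr"]; q.Vss = p["Vss"];
  q.Ko = p["Ko"]; q.Nao = p["Nao"]; q.Cao = p["Cao"];
  q.GNa = p["GNa"]; q.GK1 = p["GK1"]; q.Gto = p["Gto"]; q.GKr = p["GKr"];
  q.GKs = p["GKs"]; q.pKNa = p["pKNa"]; q.GCaL = p["GCaL"];
  q.GbNa = p["GbNa"]; q.GbCa = p["GbCa"]; q.GpK = p["GpK"];
  q.GpCa = p["GpCa"]; q.KpCa = p["KpCa"];
  q.PNaK = p["PNaK"]; q.KmK = p["KmK"]; q.KmNa = p["KmNa"];
  q.kNaCa = p["kNaCa"]; q.KmNai = p["KmNai"]; q.KmCa = p["KmCa"];
  q.ksat = p["ksat"]; q.gammaNCX = p["gammaNCX"]; q.alphaNCX = p["alphaNCX"];
  q.Vmaxup = p["Vmaxup"]; q.Kup = p["Kup"]; q.Vleak = p["Vleak"];
  q.Vxfer = p["Vxfer"]; q.Vrel = p["Vrel"];
  q.Bufc = p["Bufc"]; q.Kbufc = p["Kbufc"]; q.Bufsr = p["Bufsr"];
  q.Kbufsr = p["Kbufsr"]; q.Bufss = p["Bufss"]; q.Kbufss = p["Kbufss"];
  q.k1p = p["k1prime"]; q.k2p = p["k2prime"]; q.k3 = p["k3"]; q.k4 = p["k4"];
  q.maxsr = p["maxsr"]; q.minsr = p["minsr"]; q.EC = p["EC"];
  q.gammaRyR = p["gammaRyR"]; q.kcasrLiteral = p["kcasrLiteral"] > 0;
  q.ryrTimeScale = p["ryrTimeScale"];
  q.x7 = p["x7"]; q.fSlowScale = p["fSlowScale"];
  q.gCaLScale = p["gCaLScale"];
  q.VofsCaL = p["VofsCaL"]; q.phi = p["phi"];
  q.eta = p["eta"];
  q.FRT = q.F / (q.R * q.T);
  return q;
}

// state layout in the flat vector handed over from R
enum { iV = 0, iM, iH, iJ, iXr1, iXr2, iXs, iR_, iS, iNai, iKi,
       iCai, iCaSR, iCass, iLcc0, iRyr0 = iLcc0 + 7, NSTATE = iRyr0 + 4 };

const int NLCCS = 7, NRYRS = 4;
// LCC states: 0 C, 1 Cp, 2 O, 3 If, 4 If2, 5 ICa, 6 IC
// RyR states: 0 R, 1 O, 2 I, 3 RI
const int LCC_EDGES = 12, RYR_EDGES = 8;
// C <-> Cp <-> O; serial voltage-inactivation ladder O <-> If2 <-> If;
// calcium inactivation O <-> ICa; closed-state inactivation Cp <-> IC
const int lccFrom[LCC_EDGES] = {0, 1, 1, 2, 2, 4, 4, 3, 2, 5, 1, 6};
const int lccTo[LCC_EDGES]   = {1, 0, 2, 1, 4, 2, 3, 4, 5, 2, 6, 1};
const int ryrFrom[RYR_EDGES] = {0, 1, 1, 2, 0, 3, 3, 2};
const int ryrTo[RYR_EDGES]   = {1, 0, 2, 1, 3, 0, 2, 3};

// per-state outgoing edge lists (derived from the tables above)
const int lccOutN[NLCCS] = {1, 3, 3, 1, 2, 1, 1};
const int lccOut[NLCCS][3] = {{0,-1,-1},{1,2,10},{3,4,8},{7,-1,-1},
                              {5,6,-1},{9,-1,-1},{11,-1,-1}};
const int ryrOutN[NRYRS] = {2, 2, 2, 2};
const int ryrOut[NRYRS][3] = {{0,4,-1},{1,2,-1},{3,7,-1},{5,6,-1}};

struct Rates {
  double lcc[LCC_EDGES];
  double ryr[RYR_EDGES];
};

void lccRatesC(double V, double Cass, const Params& q, double* k) {
  double dInf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  double aD = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  double bD = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  double gD = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  double tauD = aD * bD + gD;
  double fInf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  double tauF = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
    200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
    180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
  double f2Inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  double tauF2 = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
    31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
    80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  double csq = (Cass / 0.05) * (Cass / 0.05);
  double fcassInf = 0.6 / (1.0 + csq) + 0.4;
  double tauFcass = 80.0 / (1.0 + csq) + 2.0;

  double dPlus = dInf / tauD, dMinus = (1.0 - dInf) / tauD;
  double fMinus = q.eta * (1.0 - fInf) / tauF, fPlus = fInf / tauF;
  double f2Minus = q.eta * (1.0 - f2Inf) / tauF2, f2Plus = f2Inf / tauF2;
  double fcaMinus = (1.0 - fcassInf) / tauFcass;
  double fcaPlus = fcassInf / tauFcass;

  k[0] = dPlus;                    // C -> Cp
  k[1] = dMinus;                   // Cp -> C
  k[2] = q.phi * q.x7 * dPlus;     // Cp -> O
  k[3] = q.x7 * dMinus;            // O -> Cp
  k[4] = f2Minus; k[5] = f2Plus;   // O <-> If2 (fast V inactivation)
  k[6] = q.fSlowScale * fMinus;    // If2 -> If (slow, deep V inactivation)
  k[7] = q.fSlowScale * fPlus;     // If -> If2
  k[8] = fcaMinus; k[9] = fcaPlus; // O <-> ICa (calcium inactivation)
  k[10] = fMinus; k[11] = fPlus;   // Cp <-> IC (closed-state inactivation)
}

void ryrRatesC(double Cass, double CaSR, const Params& q, double* k) {
  double rr = q.EC / CaSR;
  double kcasr = q.maxsr - (q.maxsr - q.minsr) / (1.0 + rr * rr);
  double k1 = q.kcasrLiteral ? q.phi * q.k1p * kcasr : q.phi * q.k1p / kcasr;
  double k2 = q.k2p * kcasr * q.gammaRyR;
  double open = q.ryrTimeScale * k1 * Cass * Cass;
  double close = q.ryrTimeScale * q.k3;
  double inact = k2 * Cass;
  k[0] = open;   // R -> O
  k[1] = close;  // O -> R
  k[2] = inact;  // O -> I
  k[3] = q.k4;   // I -> O
  k[4] = inact;  // R -> RI
  k[5] = q.k4;   // RI -> R
  k[6] = open;   // RI -> I
  k[7] = close;  // I -> RI
}

double icalC(double openFrac, double V, double Cass, const Params& q) {
  double dV = V - q.VofsCaL;
  double x = 2.0 * dV * q.FRT;
  double scale = openFrac * q.gCaLScale * q.GCaL * 4.0 * q.F * q.FRT;
  if (std::fabs(x) < 1e-5) {
    double num0 = 0.25 * Cass - q.Cao;
    double val = num0 + x * (0.25 * Cass - num0 / 2.0);
    return scale * (q.R * q.T / (2.0 * q.F)) * val;
  }
  return scale * dV * (0.25 * Cass * std::exp(x) - q.Cao) / std::expm1(x);
}

double freeFromTotal(double total, double Buf, double Kbuf) {
  double b = Buf + Kbuf - total;
  return 0.5 * (-b + std::sqrt(b * b + 4.0 * Kbuf * total));
}
double totalFromFreeC(double free, double Buf, double Kbuf) {
  return free + free * Buf / (free + Kbuf);
}

struct Currents {
  double INa, IK1, Ito, IKr, IKs, ICaL, INaCa, INaK, IpCa, IpK, IbCa, IbNa;
  double Irel, Iup, Ileak, Ixfer;
  double Iion;
};

Currents computeCurrents(const double* s, const Params& q) {
  Currents c;
  double V = s[iV];
  double EK = q.R * q.T / q.F * std::log(q.Ko / s[iKi]);
  double ENa = q.R * q.T / q.F * std::log(q.Nao / s[iNai]);
  double EKs = q.R * q.T / q.F *
    std::log((q.Ko + q.pKNa * q.Nao) / (s[iKi] + q.pKNa * s[iNai]));
  double ECa = 0.5 * q.R * q.T / q.F * std::log(q.Cao / s[iCai]);

  c.INa = q.GNa * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - ENa);

  double aK1 = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
  double bK1 = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                std::exp(0.1 * (V - EK - 10.0))) /
               (1.0 + std::exp(-0.5 * (V - EK)));
  c.IK1 = q.GK1 * std::sqrt(q.Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK);

  c.Ito = q.Gto * s[iR_] * s[iS] * (V - EK);
  c.IKr = q.GKr * std::sqrt(q.Ko / 5.4) * s[iXr1] * s[iXr2] * (V - EK);
  c.IKs = q.GKs * s[iXs] * s[iXs] * (V - EKs);

  c.INaK = q.PNaK * (q.Ko / (q.Ko + q.KmK)) *
    (s[iNai] / (s[iNai] + q.KmNa)) /
    (1.0 + 0.1245 * std::exp(-0.1 * V * q.FRT) +
     0.0353 * std::exp(-V * q.FRT));

  double g = q.gammaNCX;
  c.INaCa = q.kNaCa *
    (std::exp(g * V * q.FRT) * s[iNai] * s[iNai] * s[iNai] * q.Cao -
     std::exp((g - 1.0) * V * q.FRT) * q.Nao * q.Nao * q.Nao * s[iCai] *
       q.alphaNCX) /
    ((q.KmNai * q.KmNai * q.KmNai + q.Nao * q.Nao * q.Nao) *
     (q.KmCa + q.Cao) *
     (1.0 + q.ksat * std::exp((g - 1.0) * V * q.FRT)));

  c.IpCa = q.GpCa * s[iCai] / (q.KpCa + s[iCai]);
  c.IpK = q.GpK * (V - EK) / (1.0 + std::exp((25.0 - V) / 5.98));
  c.IbNa = q.GbNa * (V - ENa);
  c.IbCa = q.GbCa * (V - ECa);

  double oLcc = s[iLcc0 + 2];
  c.ICaL = icalC(oLcc, V, s[iCass], q);

  double oRyr = s[iRyr0 + 1];
  c.Irel = oRyr * q.Vrel * (s[iCaSR] - s[iCass]);
  double keff = q.Kup / q.phi;
  c.Iup = (s[iCai] <= 0.0) ? 0.0 :
    q.Vmaxup / (1.0 + keff * keff / (s[iCai] * s[iCai]));
  c.Ileak = q.Vleak * (s[iCaSR] - s[iCai]);
  c.Ixfer = q.Vxfer * (s[iCass] - s[iCai]);

  c.Iion = c.INa + c.IK1 + c.Ito + c.IKr + c.IKs + c.ICaL + c.INaCa +
    c.INaK + c.IpCa + c.IpK + c.IbCa + c.IbNa;
  return c;
}

struct GateTargets { double inf[9], tau[9]; };  // m h j xr1 xr2 xs r s

void gateCurves(double V, GateTargets& gt) {
  double mInf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
  double aM = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  double bM = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
    0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  double hInf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
  double aH, bH, aJ, bJ;
  if (V >= -40.0) {
    aH = 0.0;
    bH = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aJ = 0.0;
    bJ = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    aH = 0.057 * std::exp(-(V + 80.0) / 6.8);
    bH = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    aJ = (-2.5428e4 * std::exp(0.2444 * V) -
          6.948e-6 * std::exp(-0.04391 * V)) * (V + 37.78) /
         (1.0 + std::exp(0.311 * (V + 79.23)));
    bJ = 0.02424 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  double xr1Inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  double aXr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  double bXr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  double xr2Inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  double aXr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  double bXr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  double xsInf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  double aXs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
  double bXs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
  double rInf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  double tauR = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  double sInf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));  // epicardial
  double tauS = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
    5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;

  gt.inf[0] = mInf;   gt.tau[0] = aM * bM;
  gt.inf[1] = hInf;   gt.tau[1] = 1.0 / (aH + bH);
  gt.inf[2] = hInf;   gt.tau[2] = 1.0 / (aJ + bJ);
  gt.inf[3] = xr1Inf; gt.tau[3] = aXr1 * bXr1;
  gt.inf[4] = xr2Inf; gt.tau[4] = aXr2 * bXr2;
  gt.inf[5] = xsInf;  gt.tau[5] = aXs * bXs + 80.0;
  gt.inf[6] = rInf;   gt.tau[6] = tauR;
  gt.inf[7] = sInf;   gt.tau[7] = tauS;
}

// binomial sampler: plain inversion for small means (the overwhelmingly
// common case at dt = 0.001 ms), R's full sampler otherwise; both draw
// from R's seeded random stream, so runs stay reproducible
inline int fastBinom(int n, double p) {
  if (p <= 0.0 || n <= 0) return 0;
  if (p >= 1.0) return n;
  double np = n * p;
  if (np < 10.0 && n * (1.0 - p) > np) {
    double odds = p / (1.0 - p);
    double f = std::exp(n * std::log1p(-p));   // P(X = 0)
    double u = unif_rand();
    int x = 0;
    while (u > f && x < n) {
      u -= f;
      ++x;
      f *= odds * (n - x + 1) / x;
    }
    return x;
  }
  return (int) R::rbinom((double) n, p);
}

// multinomial tau-leap update of one population given the per-edge rates;
// counts is modified in place, total conserved by construction
void tauLeapPop(int* counts, int nStates, const int (*outIdxTab)[3],
                const int* outN, const int* eTo, const double* k,
                double dt) {
  int delta[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  for (int s = 0; s < nStates; ++s) {
    int n = counts[s];
    if (n == 0) continue;
    const int* outIdx = outIdxTab[s];
    int nOut = outN[s];
    double ktot = 0.0;
    for (int m = 0; m < nOut; ++m) ktot += k[outIdx[m]];
    if (ktot <= 0.0) continue;
    // nLeave ~ Binomial(n, 1 - exp(-ktot*dt)); inversion started at
    // P(0) = exp(-n*ktot*dt), falling back to the generic sampler when
    // the expected number of movers is large
    int nLeave;
    double lam = n * ktot * dt;
    if (lam < 10.0) {
      double u = unif_rand();
      double f = std::exp(-lam);
      double odds = std::expm1(ktot * dt);
      nLeave = 0;
      while (u > f && nLeave < n) {
        u -= f;
        ++nLeave;
        f *= odds * (n - nLeave + 1) / nLeave;
      }
    } else {
      nLeave = fastBinom(n, -std::expm1(-ktot * dt));
    }
    if (nLeave == 0) continue;
    delta[s] -= nLeave;
    // multinomial partition over the outgoing edges via conditional
    // binomials; the final edge takes whatever remains
    double kRem = ktot;
    int left = nLeave;
    for (int m = 0; m < nOut - 1 && left > 0; ++m) {
      int e = outIdx[m];
      int x = fastBinom(left, k[e] / kRem);
      delta[eTo[e]] += x;
      left -= x;
      kRem -= k[e];
    }
    if (left > 0) delta[eTo[outIdx[nOut - 1]]] += left;
  }
  for (int s = 0; s < nStates; ++s) counts[s] += delta[s];
}

void eulerPop(double* frac, int nStates, const int* eFrom, const int* eTo,
              int nEdges, const double* k, double dt) {
  double d[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  for (int e = 0; e < nEdges; ++e) {
    double flux = k[e] * frac[eFrom[e]];
    d[eFrom[e]] -= flux;
    d[eTo[e]] += flux;
  }
  for (int s = 0; s < nStates; ++s) frac[s] += dt * d[s];
}

void roundCounts(const double* frac, int n, int N, int* counts) {
  // largest-remainder rounding of frac*N to integers summing to N
  double rem[8];
  int tot = 0;
  for (int i = 0; i < n; ++i) {
    double x = frac[i] * N;
    counts[i] = (int) std::floor(x + 1e-12);
    if (counts[i] < 0) counts[i] = 0;
    rem[i] = x - counts[i];
    tot += counts[i];
  }
  while (tot < N) {
    int best = 0;
    for (int i = 1; i < n; ++i) if (rem[i] > rem[best]) best = i;
    counts[best] += 1; rem[best] = -1.0; tot += 1;
  }
  while (tot > N) {
    int best = -1;
    for (int i = 0; i < n; ++i)
      if (counts[i] > 0 && (best < 0 || rem[i] < rem[best])) best = i;
    counts[best] -= 1; rem[best] = 2.0; tot -= 1;
  }
}

double interpCross(double t0, double v0, double t1, double v1, double thr) {
  return t0 + (thr - v0) / (v1 - v0) * (t1 - t0);
}

// APD at repolarization fraction f from a sampled V trace of one beat
double apdFromTrace(const std::vector<double>& v, double dts,
                    int iStim, double frac) {
  int n = (int) v.size();
  if (iStim >= n - 1) return NA_REAL;
  double vDias = v[iStim];
  int iPeak = iStim;
  for (int i = iStim; i < n; ++i) if (v[i] > v[iPeak]) iPeak = i;
  double vPeak = v[iPeak];
  if (vPeak - vDias < 5.0) return NA_REAL;  // no upstroke this beat
  double thr = vPeak - frac * (vPeak - vDias);
  double tUp = NA_REAL, tDown = NA_REAL;
  for (int i = iStim; i < iPeak; ++i) {
    if (v[i] <= thr && v[i + 1] > thr) {
      tUp = interpCross(i * dts, v[i], (i + 1) * dts, v[i + 1], thr);
      break;
    }
  }
  if (!R_finite(tUp)) tUp = iStim * dts;   // stimulus jumped the threshold
  for (int i = iPeak; i < n - 1; ++i) {
    if (v[i] >= thr && v[i + 1] < thr) {
      tDown = interpCross(i * dts, v[i], (i + 1) * dts, v[i + 1], thr);
      break;
    }
  }
  if (!R_finite(tDown)) return NA_REAL;    // no repolarization crossing
  return tDown - tUp;
}

} // namespace

// [[Rcpp::export(name = ".cellRun")]]
List cellRun(NumericVector p, NumericVector state0, double dt, double period,
             int nBeats, double stimStart, double stimAmplitude,
             double stimDuration, bool stochastic, int nLcc, int nRyr,
             int traceEvery = 0, int vSampleEvery = 100) {
  Params q = readParams(p);
  if (state0.size() != NSTATE) stop("state vector has wrong length");
  if (dt <= 0) stop("dt must be positive");
  if (nBeats < 1) stop("at least one beat is required");

  double s[NSTATE];
  for (int i = 0; i < NSTATE; ++i) s[i] = state0[i];

  int lccN[NLCCS], ryrN[NRYRS];
  if (stochastic) {
    if (nLcc < 1 || nRyr < 1) stop("channel counts must be >= 1");
    roundCounts(&s[iLcc0], NLCCS, nLcc, lccN);
    roundCounts(&s[iRyr0], NRYRS, nRyr, ryrN);
  }

  const int stepsPerBeat = (int) std::lround(period / dt);
  const long totalSteps = (long) stepsPerBeat * nBeats;

  // per-beat summaries
  NumericVector bSbar(nBeats), bApd50(nBeats), bApd90(nBeats),
    bPeakCai(nBeats), bDiasCaSR(nBeats), bPeakV(nBeats), bMinCai(nBeats),
    bPeakIrel(nBeats);

  // optional downsampled trace of the full run
  long nTrace = traceEvery > 0 ? totalSteps / traceEvery + 1 : 0;
  NumericVector trT(nTrace), trV(nTrace), trCai(nTrace), trCass(nTrace),
    trCaSR(nTrace), trICaL(nTrace), trIrel(nTrace), trLccO(nTrace),
    trRyrO(nTrace);
  long iTrace = 0;

  // V buffer for APD, reused per beat
  int nVBuf = stepsPerBeat / vSampleEvery + 1;
  std::vector<double> vBuf((size_t) nVBuf);
  double dts = dt * vSampleEvery;
  int iStimSample = (int) std::floor(stimStart / dts);

  Rates rt;
  double sbar = 0.0, peakCai = 0.0, minCai = 1e9, peakV = -1e9,
    diasCaSR = s[iCaSR], peakIrel = 0.0;
  int iv = 0;
  GateTargets gt;

  for (int beat = 0; beat < nBeats; ++beat) {
    sbar = 0.0; peakCai = 0.0; minCai = 1e9; peakV = -1e9;
    peakIrel = 0.0; diasCaSR = s[iCaSR];
    iv = 0;
    for (int k = 0; k < stepsPerBeat; ++k) {
      double tBeat = k * dt;
      double Ist = (tBeat >= stimStart && tBeat < stimStart + stimDuration)
        ? stimAmplitude : 0.0;

      if (stochastic) {
        for (int i = 0; i < NLCCS; ++i) s[iLcc0 + i] = (double) lccN[i] / nLcc;
        for (int i = 0; i < NRYRS; ++i) s[iRyr0 + i] = (double) ryrN[i] / nRyr;
      }

      Currents c = computeCurrents(s, q);
      gateCurves(s[iV], gt);
      lccRatesC(s[iV], s[iCass], q, rt.lcc);
      ryrRatesC(s[iCass], s[iCaSR], q, rt.ryr);

      // beat accumulators (rates frozen at step start, Eq-21 Riemann sum)
      sbar += c.Irel;
      if (s[iCai] > peakCai) peakCai = s[iCai];
      if (s[iCai] < minCai) minCai = s[iCai];
      if (s[iV] > peakV) peakV = s[iV];
      if (c.Irel > peakIrel) peakIrel = c.Irel;
      if (k % vSampleEvery == 0 && iv < nVBuf) vBuf[(size_t) iv++] = s[iV];
      if (traceEvery > 0 && ((long) beat * stepsPerBeat + k) % traceEvery == 0
          && iTrace < nTrace) {
        trT[iTrace] = beat * period + tBeat;
        trV[iTrace] = s[iV]; trCai[iTrace] = s[iCai];
        trCass[iTrace] = s[iCass]; trCaSR[iTrace] = s[iCaSR];
        trICaL[iTrace] = c.ICaL; trIrel[iTrace] = c.Irel;
        trLccO[iTrace] = s[iLcc0 + 2]; trRyrO[iTrace] = s[iRyr0 + 1];
        ++iTrace;
      }

      // --- advance ---
      // HH gates (explicit Euler)
      for (int gi = 0; gi < 8; ++gi) {
        double& x = s[iM + gi];
        x += dt * (gt.inf[gi] - x) / gt.tau[gi];
        if (x < 0.0) x = 0.0; else if (x > 1.0) x = 1.0;
      }

      // channel populations
      if (stochastic) {
        tauLeapPop(lccN, NLCCS, lccOut, lccOutN, lccTo, rt.lcc, dt);
        tauLeapPop(ryrN, NRYRS, ryrOut, ryrOutN, ryrTo, rt.ryr, dt);
        int sl = 0, sr = 0;
        for (int i = 0; i < NLCCS; ++i) { sl += lccN[i];
          if (lccN[i] < 0) stop("internal error: negative LCC count"); }
        for (int i = 0; i < NRYRS; ++i) { sr += ryrN[i];
          if (ryrN[i] < 0) stop("internal error: negative RyR count"); }
        if (sl != nLcc || sr != nRyr)
          stop("internal error: channel number not conserved");
      } else {
        eulerPop(&s[iLcc0], NLCCS, lccFrom, lccTo, LCC_EDGES, rt.lcc, dt);
        eulerPop(&s[iRyr0], NRYRS, ryrFrom, ryrTo, RYR_EDGES, rt.ryr, dt);
      }

      // calcium: advance totals, recover free by the buffering quadratic
      double cf = q.Cm / (2.0 * q.F);
      double dCai = -(c.IbCa + c.IpCa - 2.0 * c.INaCa) * cf / q.Vc +
        q.Vsr / q.Vc * (c.Ileak - c.Iup) + c.Ixfer;
      double dCaSR = c.Iup - c.Ileak - c.Irel;
      double dCass = -c.ICaL * cf / q.Vss + q.Vsr / q.Vss * c.Irel -
        q.Vc / q.Vss * c.Ixfer;
      double caiTot = totalFromFreeC(s[iCai], q.Bufc, q.Kbufc) + dt * dCai;
      double casrTot = totalFromFreeC(s[iCaSR], q.Bufsr, q.Kbufsr) +
        dt * dCaSR;
      double cassTot = totalFromFreeC(s[iCass], q.Bufss, q.Kbufss) +
        dt * dCass;
      if (caiTot < 0.0 || casrTot < 0.0 || cassTot < 0.0)
        stop("numerical instability: negative calcium at beat %d (V=%g, "
             "Cai=%g, CaSR=%g, Cass=%g)", beat + 1, s[iV], s[iCai],
             s[iCaSR], s[iCass]);
      s[iCai] = freeFromTotal(caiTot, q.Bufc, q.Kbufc);
      s[iCaSR] = freeFromTotal(casrTot, q.Bufsr, q.Kbufsr);
      s[iCass] = freeFromTotal(cassTot, q.Bufss, q.Kbufss);

      // Na+/K+ bookkeeping and membrane potential
      s[iNai] += dt * (-(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) *
                       q.Cm / (q.Vc * q.F));
      s[iKi] += dt * (-(c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK +
                        c.IpK - Ist) * q.Cm / (q.Vc * q.F));
      s[iV] += dt * (-c.Iion + Ist);
      if (!R_finite(s[iV]) || s[iV] < -150.0 || s[iV] > 150.0)
        stop("numerical instability: V=%g at beat %d step %d", s[iV],
             beat + 1, k);
    }
    bSbar[beat] = sbar * dt;
    bPeakCai[beat] = peakCai; bMinCai[beat] = minCai;
    bPeakV[beat] = peakV; bDiasCaSR[beat] = diasCaSR;
    bPeakIrel[beat] = peakIrel;
    vBuf.resize((size_t) iv);
    bApd50[beat] = apdFromTrace(vBuf, dts, iStimSample, 0.5);
    bApd90[beat] = apdFromTrace(vBuf, dts, iStimSample, 0.9);
    vBuf.resize((size_t) nVBuf);
  }

  if (stochastic) {
    for (int i = 0; i < NLCCS; ++i) s[iLcc0 + i] = (double) lccN[i] / nLcc;
    for (int i = 0; i < NRYRS; ++i) s[iRyr0 + i] = (double) ryrN[i] / nRyr;
  }
  NumericVector finalState(NSTATE);
  for (int i = 0; i < NSTATE; ++i) finalState[i] = s[i];
  finalState.names() = state0.names();

  DataFrame beats = DataFrame::create(
    _["beat"] = seq_len(nBeats), _["sbar"] = bSbar,
    _["apd50"] = bApd50, _["apd90"] = bApd90,
    _["peakCai"] = bPeakCai, _["minCai"] = bMinCai,
    _["peakV"] = bPeakV, _["diasCaSR"] = bDiasCaSR,
    _["peakIrel"] = bPeakIrel);

  List out = List::create(_["beats"] = beats, _["finalState"] = finalState);
  if (traceEvery > 0) {
    auto head = [iTrace](const NumericVector& v) {
      return NumericVector(v.begin(), v.begin() + iTrace);
    };
    out["trace"] = DataFrame::create(
      _["t"] = head(trT), _["V"] = head(trV), _["CaiFree"] = head(trCai),
      _["CassFree"] = head(trCass), _["CaSRFree"] = head(trCaSR),
      _["ICaL"] = head(trICaL), _["Irel"] = head(trIrel),
      _["lccOpen"] = head(trLccO), _["ryrOpen"] = head(trRyrO));
  }
  return out;
}

// single evaluation of all currents and fluxes at a state; used by the R
// surface backgroundCurrents()/cellCurrents() and the cross-checking tests
// [[Rcpp::export(name = ".cellCurrents")]]
List cellCurrents(NumericVector p, NumericVector state) {
  Params q = readParams(p);
  if (state.size() != NSTATE) stop("state vector has wrong length");
  double s[NSTATE];
  for (int i = 0; i < NSTATE; ++i) s[i] = state[i];
  Currents c = computeCurrents(s, q);
  return List::create(
    _["INa"] = c.INa, _["IK1"] = c.IK1, _["Ito"] = c.Ito, _["IKr"] = c.IKr,
    _["IKs"] = c.IKs, _["ICaL"] = c.ICaL, _["INaCa"] = c.INaCa,
    _["INaK"] = c.INaK, _["IpCa"] = c.IpCa, _["IpK"] = c.IpK,
    _["IbCa"] = c.IbCa, _["IbNa"] = c.IbNa, _["Irel"] = c.Irel,
    _["Iup"] = c.Iup, _["Ileak"] = c.Ileak, _["Ixfer"] = c.Ixfer,
    _["Iion"] = c.Iion);
}

// [[Rcpp::export(name = ".lccRatesC")]]
NumericVector lccRatesExport(NumericVector p, double V, double Cass) {
  Params q = readParams(p);
  NumericVector out(LCC_EDGES);
  double k[LCC_EDGES];
  lccRatesC(V, Cass, q, k);
  for (int i = 0; i < LCC_EDGES; ++i) out[i] = k[i];
  return out;
}

// [[Rcpp::export(name = ".ryrRatesC")]]
NumericVector ryrRatesExport(NumericVector p, double Cass, double CaSR) {
  Params q = readParams(p);
  NumericVector out(RYR_EDGES);
  double k[RYR_EDGES];
  ryrRatesC(Cass, CaSR, q, k);
  for (int i = 0; i < RYR_EDGES; ++i) out[i] = k[i];
  return out;
}
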