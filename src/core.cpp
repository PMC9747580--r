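// Core numerics for pulsed-illumination smFRET inference:
//  - per-pulse observation densities (exponential decays convolved with a
//    Gaussian IRF) with incremental caches keyed on which rate changed,
//  - forward trace likelihood with empty-pulse grouping through cached
//    dyadic powers of the empty-pulse propagator,
//  - grouped forward-filtering backward-sampling with Markov-bridge fills
//    of empty runs (counts sampled exactly, never by expectation),
//  - the Gibbs chain driver (MH rate blocks, conjugate Dirichlet updates,
//    FFBS, initial-probability update, optional HDP base-measure resampling),
//  - the pulse-by-pulse trace simulator.
// All randomness comes from R's RNG so runs are reproducible via set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// observation model
// ---------------------------------------------------------------------------

// convolution of exp(-lam*t) (t >= 0) with N(m, s^2), evaluated at mu;
// goes through pnorm's log tail so it is stable for any argument
static inline double expg(double mu, double lam, double m, double s) {
  if (s <= 0.0) return (mu >= m) ? std::exp(-lam * (mu - m)) : 0.0;
  const double a = lam * (m - mu + 0.5 * lam * s * s);
  const double u = (m + lam * s * s - mu) / s;
  return std::exp(a + R::pnorm(u, 0.0, 1.0, 0, 1));
}

// convolution of t*exp(-lam*t) with N(m, s^2): the equal-rate (Erlang) limit
static inline double expgT(double mu, double lam, double m, double s) {
  const double g = expg(mu, lam, m, s);
  if (s <= 0.0) return (mu > m ? (mu - m) : 0.0) * g;
  return (mu - m - lam * s * s) * g + s * s * R::dnorm(mu, m, s, 0);
}

static const double EQUAL_RATE_TOL = 1e-7;

struct Phys {
  double lamD, lamA, piEx, tau, irfM, irfS, bg0, bg1;
  double r00, r01, r10, r11; // route: band (row) -> channel (col)
  std::vector<double> lamF;
  int M;
};

static Phys parsePhys(const List& args) {
  Phys ph;
  ph.lamD = as<double>(args["lambdaD"]);
  ph.lamA = as<double>(args["lambdaA"]);
  ph.lamF = as<std::vector<double>>(args["lambdaFret"]);
  ph.piEx = as<double>(args["piEx"]);
  ph.tau = as<double>(args["tau"]);
  NumericMatrix r = args["route"];
  ph.r00 = r(0, 0); ph.r01 = r(0, 1); ph.r10 = r(1, 0); ph.r11 = r(1, 1);
  ph.irfM = as<double>(args["irfMean"]);
  ph.irfS = as<double>(args["irfSigma"]);
  NumericVector bg = args["bgProb"];
  ph.bg0 = bg[0]; ph.bg1 = bg[1];
  ph.M = (int)ph.lamF.size();
  return ph;
}

struct Epochs {
  std::vector<double> gap;       // empty pulses before each photon pulse
  std::vector<double> muD, muA;  // microtimes (-1 when absent)
  std::vector<int> hasD, hasA;
  double tailGap;                // empty pulses after the last photon pulse
  int P;
};

static Epochs parseEpochs(const List& ep) {
  Epochs e;
  e.gap = as<std::vector<double>>(ep["gap"]);
  e.muD = as<std::vector<double>>(ep["muD"]);
  e.muA = as<std::vector<double>>(ep["muA"]);
  e.hasD = as<std::vector<int>>(ep["hasD"]);
  e.hasA = as<std::vector<int>>(ep["hasA"]);
  e.tailGap = as<double>(ep["tailGap"]);
  e.P = (int)e.gap.size();
  return e;
}

// Evaluated-density caches.  Row-major P x M blocks (epoch fastest over
// states) so the forward pass touches contiguous memory.
struct Cache {
  int M = 0, P = 0;
  std::vector<double> gDtot, gAtot; // expg(mu., lamD + lamF[m])
  std::vector<double> gDa, gAa;     // expg(mu., lamA)
  std::vector<double> SD, SA;       // unit-piEx signal densities per channel
  std::vector<double> G;            // per-epoch observation density
  std::vector<double> Pd, Pa, Q, dEmpty;
  void resize(int P_, int M_) {
    P = P_; M = M_;
    gDtot.assign((size_t)P * M, 0.0); gAtot.assign((size_t)P * M, 0.0);
    gDa.assign(P, 0.0); gAa.assign(P, 0.0);
    SD.assign((size_t)P * M, 0.0); SA.assign((size_t)P * M, 0.0);
    G.assign((size_t)P * M, 0.0);
    Pd.assign(M, 0.0); Pa.assign(M, 0.0); Q.assign(M, 0.0);
    dEmpty.assign(M, 0.0);
  }
};

// acceptor-band density at mu from cached kernels
static inline double accBand(double gTot, double gA, double mu,
                             const Phys& ph, double lamTot, double lamF) {
  if (lamF <= 0.0) return 0.0;
  double d;
  if (std::fabs(ph.lamA - lamTot) <= EQUAL_RATE_TOL * lamTot) {
    d = lamF * lamTot * expgT(mu, lamTot, ph.irfM, ph.irfS);
  } else {
    d = lamF * ph.lamA / (ph.lamA - lamTot) * (gTot - gA);
  }
  return d > 0.0 ? d : 0.0;
}

static void cacheScalars(Cache& c, const Phys& ph, int m) {
  const double lamTot = ph.lamD + ph.lamF[m];
  const double pbD = ph.lamD / lamTot, pbA = ph.lamF[m] / lamTot;
  c.Pd[m] = ph.piEx * (ph.r00 * pbD + ph.r10 * pbA);
  c.Pa[m] = ph.piEx * (ph.r01 * pbD + ph.r11 * pbA);
  c.Q[m] = 1.0 - c.Pd[m] - c.Pa[m];
  c.dEmpty[m] = c.Q[m] * (1.0 - ph.bg0) * (1.0 - ph.bg1) +
    c.Pd[m] * ph.bg0 * (1.0 - ph.bg1) + c.Pa[m] * ph.bg1 * (1.0 - ph.bg0);
}

static void cacheGCol(Cache& c, const Epochs& e, const Phys& ph, int m) {
  const double tau = ph.tau, bg0 = ph.bg0, bg1 = ph.bg1;
  const double q = c.Q[m], piEx = ph.piEx;
  for (int i = 0; i < e.P; ++i) {
    const size_t k = (size_t)i * c.M + m;
    double g;
    if (e.hasD[i] && !e.hasA[i]) {
      g = (piEx * c.SD[k] * (1.0 - bg0) + q * bg0 / tau) * (1.0 - bg1);
    } else if (!e.hasD[i] && e.hasA[i]) {
      g = (piEx * c.SA[k] * (1.0 - bg1) + q * bg1 / tau) * (1.0 - bg0);
    } else {
      g = piEx * c.SD[k] * bg1 / tau + piEx * c.SA[k] * bg0 / tau +
        q * bg0 * bg1 / (tau * tau);
    }
    c.G[k] = g;
  }
}

// rebuild everything that depends on lamF[m] (and, transitively, lamD)
static void cacheStateCol(Cache& c, const Epochs& e, const Phys& ph, int m) {
  const double lamTot = ph.lamD + ph.lamF[m];
  for (int i = 0; i < e.P; ++i) {
    const size_t k = (size_t)i * c.M + m;
    if (e.hasD[i]) {
      c.gDtot[k] = expg(e.muD[i], lamTot, ph.irfM, ph.irfS);
      const double fD = ph.lamD * c.gDtot[k];
      const double fA = accBand(c.gDtot[k], c.gDa[i], e.muD[i], ph, lamTot,
                                ph.lamF[m]);
      c.SD[k] = ph.r00 * fD + ph.r10 * fA;
    }
    if (e.hasA[i]) {
      c.gAtot[k] = expg(e.muA[i], lamTot, ph.irfM, ph.irfS);
      const double fD = ph.lamD * c.gAtot[k];
      const double fA = accBand(c.gAtot[k], c.gAa[i], e.muA[i], ph, lamTot,
                                ph.lamF[m]);
      c.SA[k] = ph.r01 * fD + ph.r11 * fA;
    }
  }
  cacheScalars(c, ph, m);
  cacheGCol(c, e, ph, m);
}

// rebuild after a change of lamA: acceptor kernels, then arithmetic only
static void cacheAcceptor(Cache& c, const Epochs& e, const Phys& ph) {
  for (int i = 0; i < e.P; ++i) {
    if (e.hasD[i]) c.gDa[i] = expg(e.muD[i], ph.lamA, ph.irfM, ph.irfS);
    if (e.hasA[i]) c.gAa[i] = expg(e.muA[i], ph.lamA, ph.irfM, ph.irfS);
  }
  for (int m = 0; m < c.M; ++m) {
    const double lamTot = ph.lamD + ph.lamF[m];
    for (int i = 0; i < e.P; ++i) {
      const size_t k = (size_t)i * c.M + m;
      if (e.hasD[i]) {
        const double fD = ph.lamD * c.gDtot[k];
        const double fA = accBand(c.gDtot[k], c.gDa[i], e.muD[i], ph, lamTot,
                                  ph.lamF[m]);
        c.SD[k] = ph.r00 * fD + ph.r10 * fA;
      }
      if (e.hasA[i]) {
        const double fD = ph.lamD * c.gAtot[k];
        const double fA = accBand(c.gAtot[k], c.gAa[i], e.muA[i], ph, lamTot,
                                  ph.lamF[m]);
        c.SA[k] = ph.r01 * fD + ph.r11 * fA;
      }
    }
    cacheScalars(c, ph, m);
    cacheGCol(c, e, ph, m);
  }
}

// rebuild after a change of piEx only (pure arithmetic)
static void cachePiEx(Cache& c, const Epochs& e, const Phys& ph) {
  for (int m = 0; m < c.M; ++m) {
    cacheScalars(c, ph, m);
    cacheGCol(c, e, ph, m);
  }
}

static void cacheAll(Cache& c, const Epochs& e, const Phys& ph) {
  c.resize(e.P, ph.M);
  for (int i = 0; i < e.P; ++i) {
    if (e.hasD[i]) c.gDa[i] = expg(e.muD[i], ph.lamA, ph.irfM, ph.irfS);
    if (e.hasA[i]) c.gAa[i] = expg(e.muA[i], ph.lamA, ph.irfM, ph.irfS);
  }
  for (int m = 0; m < ph.M; ++m) cacheStateCol(c, e, ph, m);
}

// empty-pulse probability of state m, directly from the physics
static inline double dEmptyOf(const Phys& ph, int m) {
  const double lamTot = ph.lamD + ph.lamF[m];
  const double pbD = ph.lamD / lamTot, pbA = ph.lamF[m] / lamTot;
  const double pd = ph.piEx * (ph.r00 * pbD + ph.r10 * pbA);
  const double pa = ph.piEx * (ph.r01 * pbD + ph.r11 * pbA);
  const double q = 1.0 - pd - pa;
  return q * (1.0 - ph.bg0) * (1.0 - ph.bg1) +
    pd * ph.bg0 * (1.0 - ph.bg1) + pa * ph.bg1 * (1.0 - ph.bg0);
}

// epoch observation density computed from scratch (no caches); used to
// evaluate proposals against the trajectory-conditional likelihood
static double freshG(const Epochs& e, const Phys& ph, int i, int m) {
  const double lamTot = ph.lamD + ph.lamF[m];
  double sd = 0.0, sa = 0.0;
  if (e.hasD[i]) {
    const double gTot = expg(e.muD[i], lamTot, ph.irfM, ph.irfS);
    const double gA = expg(e.muD[i], ph.lamA, ph.irfM, ph.irfS);
    const double fD = ph.lamD * gTot;
    const double fA = accBand(gTot, gA, e.muD[i], ph, lamTot, ph.lamF[m]);
    sd = ph.r00 * fD + ph.r10 * fA;
  }
  if (e.hasA[i]) {
    const double gTot = expg(e.muA[i], lamTot, ph.irfM, ph.irfS);
    const double gA = expg(e.muA[i], ph.lamA, ph.irfM, ph.irfS);
    const double fD = ph.lamD * gTot;
    const double fA = accBand(gTot, gA, e.muA[i], ph, lamTot, ph.lamF[m]);
    sa = ph.r01 * fD + ph.r11 * fA;
  }
  const double pbD = ph.lamD / lamTot, pbA = ph.lamF[m] / lamTot;
  const double pd = ph.piEx * (ph.r00 * pbD + ph.r10 * pbA);
  const double pa = ph.piEx * (ph.r01 * pbD + ph.r11 * pbA);
  const double q = 1.0 - pd - pa;
  const double tau = ph.tau, bg0 = ph.bg0, bg1 = ph.bg1;
  if (e.hasD[i] && !e.hasA[i])
    return (ph.piEx * sd * (1.0 - bg0) + q * bg0 / tau) * (1.0 - bg1);
  if (!e.hasD[i] && e.hasA[i])
    return (ph.piEx * sa * (1.0 - bg1) + q * bg1 / tau) * (1.0 - bg0);
  return ph.piEx * sd * bg1 / tau + ph.piEx * sa * bg0 / tau +
    q * bg0 * bg1 / (tau * tau);
}

// epoch density under a changed piEx only: reuses the cached unit-piEx
// signal densities, so no exponentials are evaluated
static double freshGFromSignal(const Epochs& e, const Phys& ph,
                               const Cache& c, int i, int m) {
  const double lamTot = ph.lamD + ph.lamF[m];
  const double pbD = ph.lamD / lamTot, pbA = ph.lamF[m] / lamTot;
  const double pd = ph.piEx * (ph.r00 * pbD + ph.r10 * pbA);
  const double pa = ph.piEx * (ph.r01 * pbD + ph.r11 * pbA);
  const double q = 1.0 - pd - pa;
  const double tau = ph.tau, bg0 = ph.bg0, bg1 = ph.bg1;
  const size_t k = (size_t)i * c.M + m;
  if (e.hasD[i] && !e.hasA[i])
    return (ph.piEx * c.SD[k] * (1.0 - bg0) + q * bg0 / tau) * (1.0 - bg1);
  if (!e.hasD[i] && e.hasA[i])
    return (ph.piEx * c.SA[k] * (1.0 - bg1) + q * bg1 / tau) * (1.0 - bg0);
  return ph.piEx * c.SD[k] * bg1 / tau + ph.piEx * c.SA[k] * bg0 / tau +
    q * bg0 * bg1 / (tau * tau);
}

// ---------------------------------------------------------------------------
// dyadic powers of the empty-pulse propagator A = diag(dEmpty) * Pi
// ---------------------------------------------------------------------------

struct Pow {
  int M = 0, J = 0;
  std::vector<double> B;     // (J+1) levels of M x M, each scaled to max 1
  std::vector<double> logc;  // log of the true scale of each level
  std::vector<double> A;     // level-0 unscaled matrix (row-major)

  void build(const std::vector<double>& Pi, const std::vector<double>& d,
             int M_, double maxGap) {
    M = M_;
    J = 0;
    while ((double)(1LL << J) < maxGap && J < 62) ++J;
    A.assign((size_t)M * M, 0.0);
    double amax = 0.0;
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < M; ++j) {
        A[(size_t)i * M + j] = d[i] * Pi[(size_t)i * M + j];
        if (A[(size_t)i * M + j] > amax) amax = A[(size_t)i * M + j];
      }
    B.assign((size_t)(J + 1) * M * M, 0.0);
    logc.assign(J + 1, 0.0);
    if (amax <= 0.0) amax = 1.0;
    for (size_t k = 0; k < (size_t)M * M; ++k) B[k] = A[k] / amax;
    logc[0] = std::log(amax);
    std::vector<double> tmp((size_t)M * M);
    for (int lev = 1; lev <= J; ++lev) {
      const double* Bp = &B[(size_t)(lev - 1) * M * M];
      double mx = 0.0;
      for (int i = 0; i < M; ++i)
        for (int j = 0; j < M; ++j) {
          double s = 0.0;
          for (int k = 0; k < M; ++k)
            s += Bp[(size_t)i * M + k] * Bp[(size_t)k * M + j];
          tmp[(size_t)i * M + j] = s;
          if (s > mx) mx = s;
        }
      if (mx <= 0.0) mx = 1.0;
      double* Bn = &B[(size_t)lev * M * M];
      for (size_t k = 0; k < (size_t)M * M; ++k) Bn[k] = tmp[k] / mx;
      logc[lev] = 2.0 * logc[lev - 1] + std::log(mx);
    }
  }

  // f <- f * A^gap (row vector), renormalised; adds the true log scale
  void applyRow(std::vector<double>& f, double gap, double& logacc,
                std::vector<double>& scratch) const {
    long long k = (long long)gap;
    int lev = 0;
    while (k > 0) {
      if (k & 1LL) {
        const double* Bp = &B[(size_t)lev * M * M];
        double s = 0.0;
        for (int j = 0; j < M; ++j) {
          double v = 0.0;
          for (int i = 0; i < M; ++i) v += f[i] * Bp[(size_t)i * M + j];
          scratch[j] = v;
          s += v;
        }
        if (s <= 0.0) { logacc = R_NegInf; return; }
        for (int j = 0; j < M; ++j) f[j] = scratch[j] / s;
        logacc += logc[lev] + std::log(s);
      }
      k >>= 1;
      ++lev;
    }
  }

  // v <- A^gap * v (column vector), renormalised; adds the true log scale
  void applyCol(std::vector<double>& v, double gap, double& logacc,
                std::vector<double>& scratch) const {
    long long k = (long long)gap;
    int lev = 0;
    while (k > 0) {
      if (k & 1LL) {
        const double* Bp = &B[(size_t)lev * M * M];
        double s = 0.0;
        for (int i = 0; i < M; ++i) {
          double w = 0.0;
          for (int j = 0; j < M; ++j) w += Bp[(size_t)i * M + j] * v[j];
          scratch[i] = w;
          s += w;
        }
        if (s <= 0.0) { logacc = R_NegInf; return; }
        for (int i = 0; i < M; ++i) v[i] = scratch[i] / s;
        logacc += logc[lev] + std::log(s);
      }
      k >>= 1;
      ++lev;
    }
  }

  // log of (A^gap)[a, b]
  double logEntry(int a, int b, double gap, std::vector<double>& f,
                  std::vector<double>& scratch) const {
    std::fill(f.begin(), f.end(), 0.0);
    f[a] = 1.0;
    double la = 0.0;
    applyRow(f, gap, la, scratch);
    if (f[b] <= 0.0 || la == R_NegInf) return R_NegInf;
    return la + std::log(f[b]);
  }
};

// ---------------------------------------------------------------------------
// forward pass and FFBS
// ---------------------------------------------------------------------------

static double forwardPass(const Epochs& e, const Cache& c,
                          const std::vector<double>& Pi,
                          const std::vector<double>& rho, const Pow& pw,
                          double* abar /* P x M or nullptr */) {
  const int M = c.M;
  std::vector<double> f(rho), tmp(M), scratch(M);
  double loglik = 0.0;
  for (int i = 0; i < e.P; ++i) {
    pw.applyRow(f, e.gap[i], loglik, scratch);
    if (loglik == R_NegInf) return R_NegInf;
    const double* Gi = &c.G[(size_t)i * M];
    double sg = 0.0;
    for (int s = 0; s < M; ++s) { tmp[s] = f[s] * Gi[s]; sg += tmp[s]; }
    if (!(sg > 0.0) || !std::isfinite(sg)) return R_NegInf;
    if (abar) {
      double* ab = abar + (size_t)i * M;
      for (int s = 0; s < M; ++s) ab[s] = tmp[s] / sg;
    }
    double sf = 0.0;
    for (int j = 0; j < M; ++j) {
      double v = 0.0;
      for (int s = 0; s < M; ++s) v += tmp[s] * Pi[(size_t)s * M + j];
      f[j] = v;
      sf += v;
    }
    if (!(sf > 0.0)) return R_NegInf;
    loglik += std::log(sf);
    for (int j = 0; j < M; ++j) f[j] /= sf;
  }
  pw.applyRow(f, e.tailGap, loglik, scratch);
  return loglik;
}

static inline int sampleIndex(const std::vector<double>& w, int M) {
  double s = 0.0;
  for (int i = 0; i < M; ++i) s += w[i];
  double u = unif_rand() * s, acc = 0.0;
  for (int i = 0; i < M; ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return M - 1;
}

struct Traj {
  std::vector<double> counts; // M x M transition counts (double: can be huge)
  std::vector<double> occ;    // pulses per state
  std::vector<int> sEpoch;    // sampled state at each photon epoch
  int s1 = 0, sN = 0;
};

// Exact samplers for empty-pulse runs under the kernel A.  Constant runs
// (the overwhelmingly common case for slow kinetics) are accepted in
// O(log k); on rejection the bisection samples the midpoint with the
// constant path's weight removed and recurses into explicitly
// "non-constant" variants so the decomposition stays exact.
struct RunSampler {
  const Pow& pw;
  const std::vector<double>& dEmpty;
  Traj& tr;
  int M;
  std::vector<double> f, v, scratch, w;

  RunSampler(const Pow& pw_, const std::vector<double>& d_, Traj& tr_)
    : pw(pw_), dEmpty(d_), tr(tr_), M(pw_.M),
      f(pw_.M), v(pw_.M), scratch(pw_.M), w(pw_.M) {}

  double logAk(int a, int b, long long k) {
    return pw.logEntry(a, b, (double)k, f, scratch);
  }
  // log of (A^r * dEmpty)[a]
  double logAd(int a, long long r) {
    std::copy(dEmpty.begin(), dEmpty.end(), v.begin());
    double l = 0.0;
    pw.applyCol(v, (double)r, l, scratch);
    if (v[a] <= 0.0 || l == R_NegInf) return R_NegInf;
    return l + std::log(v[a]);
  }
  double logConst(int a, long long k) {
    const double aa = pw.A[(size_t)a * M + a];
    return aa > 0.0 ? k * std::log(aa) : R_NegInf;
  }

  // fixed endpoints, k steps; counts k transitions, k-1 intermediates
  void bridge(int a, int b, long long k) {
    if (k <= 0) return;
    if (k == 1) {
      tr.counts[(size_t)a * M + b] += 1.0;
      return;
    }
    if (a == b) {
      const double lq = logConst(a, k) - logAk(a, a, k);
      if (std::log(unif_rand()) < lq) {
        tr.counts[(size_t)a * M + a] += (double)k;
        tr.occ[a] += (double)(k - 1);
      } else {
        bridgeNC(a, k);
      }
      return;
    }
    const long long h = k / 2;
    std::fill(f.begin(), f.end(), 0.0);
    f[a] = 1.0;
    double l1 = 0.0;
    pw.applyRow(f, (double)h, l1, scratch);
    std::fill(v.begin(), v.end(), 0.0);
    v[b] = 1.0;
    double l2 = 0.0;
    pw.applyCol(v, (double)(k - h), l2, scratch);
    for (int m = 0; m < M; ++m) w[m] = f[m] * v[m];
    const int mid = sampleIndex(w, M);
    tr.occ[mid] += 1.0;
    bridge(a, mid, h);
    bridge(mid, b, k - h);
  }

  // equal endpoints, conditioned on not being entirely constant; k >= 2
  void bridgeNC(int a, long long k) {
    const long long h = k / 2;
    std::fill(f.begin(), f.end(), 0.0);
    f[a] = 1.0;
    double l1 = 0.0;
    pw.applyRow(f, (double)h, l1, scratch);
    std::fill(v.begin(), v.end(), 0.0);
    v[a] = 1.0;
    double l2 = 0.0;
    pw.applyCol(v, (double)(k - h), l2, scratch);
    for (int m = 0; m < M; ++m) w[m] = f[m] * v[m];
    // remove the all-constant path's weight from the mid == a bucket
    const double cw = std::exp(logConst(a, k) - l1 - l2);
    w[a] = std::max(w[a] - cw, 0.0);
    const int mid = sampleIndex(w, M);
    tr.occ[mid] += 1.0;
    if (mid != a) {
      bridge(a, mid, h);
      bridge(mid, a, k - h);
      return;
    }
    // both halves pin a; at least one of them must be non-constant
    const double qL = std::exp(logConst(a, h) - logAk(a, a, h));
    const double qR = std::exp(logConst(a, k - h) - logAk(a, a, k - h));
    double w3[3] = {qL * (1.0 - qR), (1.0 - qL) * qR,
                    (1.0 - qL) * (1.0 - qR)};
    const double tot = w3[0] + w3[1] + w3[2];
    double u = unif_rand() * tot;
    int pick = u <= w3[0] ? 0 : (u <= w3[0] + w3[1] ? 1 : 2);
    if (pick == 0 || pick == 2) { // right half non-constant
      if (pick == 0) {
        tr.counts[(size_t)a * M + a] += (double)h;
        tr.occ[a] += (double)(h - 1);
      } else {
        bridgeNC(a, h);
      }
      bridgeNC(a, k - h);
    } else { // left non-constant, right constant
      bridgeNC(a, h);
      tr.counts[(size_t)a * M + a] += (double)(k - h);
      tr.occ[a] += (double)(k - h - 1);
    }
  }

  // free right end after state a: samples the r following states under A
  // with terminal weight dEmpty; counts r transitions and r occupancies
  void freeRun(int a, long long r) {
    if (r <= 0) {
      tr.sN = a;
      return;
    }
    const double lq = logConst(a, r) + std::log(dEmpty[a]) - logAd(a, r);
    if (std::log(unif_rand()) < lq) {
      tr.counts[(size_t)a * M + a] += (double)r;
      tr.occ[a] += (double)r;
      tr.sN = a;
      return;
    }
    freeNC(a, r);
  }

  // free run conditioned on not being entirely constant
  void freeNC(int a, long long r) {
    if (r == 1) { // single step that must leave a
      for (int b = 0; b < M; ++b)
        w[b] = b == a ? 0.0 : pw.A[(size_t)a * M + b] * dEmpty[b];
      const int b = sampleIndex(w, M);
      tr.counts[(size_t)a * M + b] += 1.0;
      tr.occ[b] += 1.0;
      tr.sN = b;
      return;
    }
    const long long h = r / 2;
    std::fill(f.begin(), f.end(), 0.0);
    f[a] = 1.0;
    double l1 = 0.0;
    pw.applyRow(f, (double)h, l1, scratch);
    std::copy(dEmpty.begin(), dEmpty.end(), v.begin());
    double l2 = 0.0;
    pw.applyCol(v, (double)(r - h), l2, scratch);
    for (int m = 0; m < M; ++m) w[m] = f[m] * v[m];
    const double cw =
      std::exp(logConst(a, r) + std::log(dEmpty[a]) - l1 - l2);
    w[a] = std::max(w[a] - cw, 0.0);
    const int mid = sampleIndex(w, M);
    tr.occ[mid] += 1.0;
    if (mid != a) {
      bridge(a, mid, h);
      freeRun(mid, r - h);
      return;
    }
    const double qL = std::exp(logConst(a, h) - logAk(a, a, h));
    const double qR =
      std::exp(logConst(a, r - h) + std::log(dEmpty[a]) - logAd(a, r - h));
    double w3[3] = {qL * (1.0 - qR), (1.0 - qL) * qR,
                    (1.0 - qL) * (1.0 - qR)};
    const double tot = w3[0] + w3[1] + w3[2];
    double u = unif_rand() * tot;
    int pick = u <= w3[0] ? 0 : (u <= w3[0] + w3[1] ? 1 : 2);
    if (pick == 1) { // right (free) half constant
      bridgeNC(a, h);
      tr.counts[(size_t)a * M + a] += (double)(r - h);
      tr.occ[a] += (double)(r - h);
      tr.sN = a;
    } else {
      if (pick == 0) {
        tr.counts[(size_t)a * M + a] += (double)h;
        tr.occ[a] += (double)(h - 1);
      } else {
        bridgeNC(a, h);
      }
      freeNC(a, r - h);
    }
  }
};


// backward sampling given stored filtered distributions at photon epochs
static void backwardSample(const Epochs& e, const Cache& c,
                           const std::vector<double>& Pi,
                           const std::vector<double>& rho, const Pow& pw,
                           const double* abar, double nPulses, Traj& tr) {
  const int M = c.M;
  tr.counts.assign((size_t)M * M, 0.0);
  tr.occ.assign(M, 0.0);
  tr.sEpoch.assign(e.P, 0);
  std::vector<double> v(M), scratch(M), w(M);
  RunSampler rs(pw, c.dEmpty, tr);
  if (e.P == 0) {
    // fully empty trace: rho, then N - 1 steps of A with terminal dEmpty
    std::vector<double> vv(c.dEmpty);
    double lv = 0.0;
    pw.applyCol(vv, nPulses - 1.0, lv, scratch);
    for (int s = 0; s < M; ++s) w[s] = rho[s] * vv[s];
    tr.s1 = sampleIndex(w, M);
    tr.occ[tr.s1] += 1.0;
    tr.sN = tr.s1;
    rs.freeRun(tr.s1, (long long)(nPulses - 1.0));
    return;
  }
  // last photon epoch and the empty tail
  int b;
  const double* abP = abar + (size_t)(e.P - 1) * M;
  if (e.tailGap <= 0.0) {
    for (int s = 0; s < M; ++s) w[s] = abP[s];
    b = sampleIndex(w, M);
    tr.sN = b;
  } else {
    std::vector<double> z(M, 1.0);
    double lz = 0.0;
    pw.applyCol(z, e.tailGap, lz, scratch);
    for (int s = 0; s < M; ++s) {
      double y = 0.0;
      for (int cix = 0; cix < M; ++cix) y += Pi[(size_t)s * M + cix] * z[cix];
      w[s] = abP[s] * y;
    }
    b = sampleIndex(w, M);
    for (int cix = 0; cix < M; ++cix)
      w[cix] = Pi[(size_t)b * M + cix] * z[cix];
    const int cst = sampleIndex(w, M);
    tr.counts[(size_t)b * M + cst] += 1.0;
    tr.occ[cst] += 1.0;
    tr.sN = cst;
    rs.freeRun(cst, (long long)e.tailGap - 1LL);
  }
  tr.occ[b] += 1.0;
  tr.sEpoch[e.P - 1] = b;
  // interior epochs
  for (int i = e.P - 2; i >= 0; --i) {
    const double k = e.gap[i + 1];
    const double* abi = abar + (size_t)i * M;
    int a;
    if (k <= 0.0) {
      for (int s = 0; s < M; ++s) w[s] = abi[s] * Pi[(size_t)s * M + b];
      a = sampleIndex(w, M);
      tr.counts[(size_t)a * M + b] += 1.0;
    } else {
      std::fill(v.begin(), v.end(), 0.0);
      v[b] = 1.0;
      double lv = 0.0;
      pw.applyCol(v, k, lv, scratch);
      for (int s = 0; s < M; ++s) {
        double u = 0.0;
        for (int cix = 0; cix < M; ++cix)
          u += Pi[(size_t)s * M + cix] * v[cix];
        w[s] = abi[s] * u;
      }
      a = sampleIndex(w, M);
      for (int cix = 0; cix < M; ++cix)
        w[cix] = Pi[(size_t)a * M + cix] * v[cix];
      const int cst = sampleIndex(w, M);
      tr.counts[(size_t)a * M + cst] += 1.0;
      tr.occ[cst] += 1.0;
      rs.bridge(cst, b, (long long)k);
    }
    tr.occ[a] += 1.0;
    tr.sEpoch[i] = a;
    b = a;
  }
  // head: empty pulses before the first photon pulse
  const double g = e.gap[0];
  if (g > 0.0) {
    std::fill(v.begin(), v.end(), 0.0);
    v[b] = 1.0;
    double lv = 0.0;
    pw.applyCol(v, g, lv, scratch);
    for (int s = 0; s < M; ++s) w[s] = rho[s] * v[s];
    tr.s1 = sampleIndex(w, M);
    tr.occ[tr.s1] += 1.0;
    rs.bridge(tr.s1, b, (long long)g);
  } else {
    tr.s1 = b;
  }
}

static double maxGapOf(const Epochs& e) {
  double mg = e.tailGap > 1.0 ? e.tailGap : 1.0;
  for (double g : e.gap) if (g > mg) mg = g;
  return mg;
}

// ---------------------------------------------------------------------------
// exported: trace log likelihood
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_trace_loglik(List epochs, NumericMatrix Pi, NumericVector rho,
                        List modelArgs, double nPulses) {
  Phys ph = parsePhys(modelArgs);
  Epochs e = parseEpochs(epochs);
  const int M = ph.M;
  std::vector<double> piv((size_t)M * M), rhov(M);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < M; ++j) piv[(size_t)i * M + j] = Pi(i, j);
  for (int i = 0; i < M; ++i) rhov[i] = rho[i];
  Cache c;
  cacheAll(c, e, ph);
  Pow pw;
  pw.build(piv, c.dEmpty, M, maxGapOf(e));
  return forwardPass(e, c, piv, rhov, pw, nullptr);
}

// ---------------------------------------------------------------------------
// exported: grouped FFBS draws (counts / occupancy / endpoint summaries)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ffbs_grouped(List epochs, NumericMatrix Pi, NumericVector rho,
                      List modelArgs, double nPulses, int nDraws) {
  Phys ph = parsePhys(modelArgs);
  Epochs e = parseEpochs(epochs);
  const int M = ph.M;
  std::vector<double> piv((size_t)M * M), rhov(M);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < M; ++j) piv[(size_t)i * M + j] = Pi(i, j);
  for (int i = 0; i < M; ++i) rhov[i] = rho[i];
  Cache c;
  cacheAll(c, e, ph);
  Pow pw;
  pw.build(piv, c.dEmpty, M, maxGapOf(e));
  std::vector<double> abar((size_t)std::max(e.P, 1) * M);
  const double ll = forwardPass(e, c, piv, rhov, pw, abar.data());
  if (ll == R_NegInf) stop("trace has zero likelihood under these parameters");
  NumericVector countsOut((R_xlen_t)M * M * nDraws);
  NumericMatrix occOut(nDraws, M);
  IntegerVector s1Out(nDraws), sNOut(nDraws);
  Traj tr;
  for (int d = 0; d < nDraws; ++d) {
    backwardSample(e, c, piv, rhov, pw, abar.data(), nPulses, tr);
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < M; ++j)
        countsOut[(R_xlen_t)d * M * M + (R_xlen_t)j * M + i] =
          tr.counts[(size_t)i * M + j];
    for (int m = 0; m < M; ++m) occOut(d, m) = tr.occ[m];
    s1Out[d] = tr.s1 + 1;
    sNOut[d] = tr.sN + 1;
    if ((d & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  countsOut.attr("dim") = IntegerVector::create(M, M, nDraws);
  return List::create(_["counts"] = countsOut, _["occupancy"] = occOut,
                      _["s1"] = s1Out, _["sN"] = sNOut,
                      _["logLik"] = ll);
}

// ---------------------------------------------------------------------------
// exported: Gibbs chain driver
// ---------------------------------------------------------------------------

static double logDirichlet(const std::vector<double>& x,
                           const std::vector<double>& a, int M) {
  double lp = 0.0, sa = 0.0;
  for (int i = 0; i < M; ++i) {
    sa += a[i];
    lp -= R::lgammafn(a[i]);
    lp += (a[i] - 1.0) * std::log(x[i] > 0.0 ? x[i] : 1e-300);
  }
  return lp + R::lgammafn(sa);
}

static void rdirichlet(const double* shape, int M, double* out) {
  double s = 0.0;
  for (int i = 0; i < M; ++i) {
    out[i] = R::rgamma(shape[i] > 0.0 ? shape[i] : 1e-8, 1.0);
    s += out[i];
  }
  if (s <= 0.0) {
    for (int i = 0; i < M; ++i) out[i] = 1.0 / M;
    return;
  }
  for (int i = 0; i < M; ++i) out[i] /= s;
}

// [[Rcpp::export]]
List cpp_run_chain(List epochs, double nPulses, int M,
                   NumericVector rowPriorInit, NumericVector rhoConc,
                   NumericVector ratePrior, NumericVector piExPrior,
                   List init, int nSweeps, int nTune,
                   NumericVector initScales, bool sampleBeta,
                   double gammaConc, double alphaConc, List modelArgs,
                   int progressEvery) {
  Phys ph = parsePhys(modelArgs);
  if (ph.M != M) stop("lambdaFret length must equal the state count");
  Epochs e = parseEpochs(epochs);
  const double maxGap = maxGapOf(e);

  // state
  ph.lamD = as<double>(init["lambdaD"]);
  ph.lamA = as<double>(init["lambdaA"]);
  ph.lamF = as<std::vector<double>>(init["lambdaFret"]);
  ph.piEx = as<double>(init["piEx"]);
  NumericMatrix Pi0 = init["transProb"];
  NumericVector rho0 = init["rhoStart"];
  std::vector<double> Pi((size_t)M * M), rho(M);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < M; ++j) Pi[(size_t)i * M + j] = Pi0(i, j);
  for (int i = 0; i < M; ++i) rho[i] = rho0[i];

  std::vector<double> beta(M, 1.0 / M);
  std::vector<double> rowPrior(M);
  for (int i = 0; i < M; ++i) rowPrior[i] = rowPriorInit[i];
  std::vector<double> rhoc(M);
  for (int i = 0; i < M; ++i) rhoc[i] = rhoConc[i];

  const double dShape = ratePrior[0], dRate = ratePrior[1];
  const double aShape = ratePrior[2], aRate = ratePrior[3];
  const double fShape = ratePrior[4], fRate = ratePrior[5];
  const double pexA = piExPrior[0], pexB = piExPrior[1];

  Cache cur;
  cacheAll(cur, e, ph);
  Pow pw;
  pw.build(Pi, cur.dEmpty, M, maxGap);
  double llCur = forwardPass(e, cur, Pi, rho, pw, nullptr);
  if (!std::isfinite(llCur))
    stop("initial parameters give the trace zero likelihood");

  std::vector<double> abar((size_t)std::max(e.P, 1) * M);
  Traj tr;
  {
    forwardPass(e, cur, Pi, rho, pw, abar.data());
    backwardSample(e, cur, Pi, rho, pw, abar.data(), nPulses, tr);
  }

  const int nBlocks = M + 3; // lamD, lamA, lamF x M, piEx
  std::vector<double> scales(nBlocks);
  for (int b = 0; b < nBlocks; ++b) scales[b] = initScales[b];
  std::vector<int> accWin(nBlocks, 0), tryWin(nBlocks, 0);
  std::vector<double> accTot(nBlocks, 0.0), tryTot(nBlocks, 0.0);
  const int tuneEvery = 25;

  // output storage
  NumericVector outPi((R_xlen_t)M * M * nSweeps);
  NumericVector outLamD(nSweeps), outLamA(nSweeps), outPiEx(nSweeps);
  NumericMatrix outLamF(nSweeps, M), outRho(nSweeps, M), outOcc(nSweeps, M);
  NumericMatrix outBeta(sampleBeta ? nSweeps : 0, sampleBeta ? M : 0);
  IntegerVector outS1(nSweeps);
  NumericVector outLL(nSweeps), outLP(nSweeps);

  Phys phProp = ph;
  std::vector<std::vector<int>> byState(M);
  std::vector<double> nEp(M);

  for (int sweep = 0; sweep < nSweeps; ++sweep) {
    // ---- 1) rate updates, conditional on the sampled trajectory ----------
    // Given s_1:N the likelihood factorises into per-photon-epoch terms
    // G[i, s_i] and per-state empty-pulse terms dEmpty[m]^E_m, so each
    // block is O(#photons in the affected states), with no forward pass.
    for (int m = 0; m < M; ++m) {
      byState[m].clear();
      nEp[m] = 0.0;
    }
    for (int i = 0; i < e.P; ++i) {
      byState[tr.sEpoch[i]].push_back(i);
      nEp[tr.sEpoch[i]] += 1.0;
    }
    for (int b = 0; b < nBlocks; ++b) {
      phProp = ph;
      double dPrior = 0.0, jac = 0.0, dll = 0.0;
      bool direct = false;
      if (b == 0) { // lamD: touches every photon epoch and every dEmpty
        const double nv = ph.lamD * std::exp(scales[b] * norm_rand());
        phProp.lamD = nv;
        for (int i = 0; i < e.P; ++i) {
          const int s = tr.sEpoch[i];
          const double gn = freshG(e, phProp, i, s);
          if (gn <= 0.0) { dll = R_NegInf; break; }
          dll += std::log(gn) - std::log(cur.G[(size_t)i * M + s]);
        }
        if (std::isfinite(dll)) {
          for (int m = 0; m < M; ++m) {
            const double em = tr.occ[m] - nEp[m];
            if (em > 0.0)
              dll += em * (std::log(dEmptyOf(phProp, m)) -
                           std::log(cur.dEmpty[m]));
          }
        }
        dPrior = R::dgamma(nv, dShape, 1.0 / dRate, 1) -
          R::dgamma(ph.lamD, dShape, 1.0 / dRate, 1);
        jac = std::log(nv / ph.lamD);
      } else if (b == 1) { // lamA: photon terms only (dEmpty is lamA-free)
        const double nv = ph.lamA * std::exp(scales[b] * norm_rand());
        phProp.lamA = nv;
        for (int i = 0; i < e.P; ++i) {
          const int s = tr.sEpoch[i];
          const double gn = freshG(e, phProp, i, s);
          if (gn <= 0.0) { dll = R_NegInf; break; }
          dll += std::log(gn) - std::log(cur.G[(size_t)i * M + s]);
        }
        dPrior = R::dgamma(nv, aShape, 1.0 / aRate, 1) -
          R::dgamma(ph.lamA, aShape, 1.0 / aRate, 1);
        jac = std::log(nv / ph.lamA);
      } else if (b < M + 2) { // lamF[m]
        const int m = b - 2;
        if (tr.occ[m] <= 0.0) {
          // state unvisited by the trajectory: conditional equals the
          // prior, draw directly
          ph.lamF[m] = R::rgamma(fShape, 1.0 / fRate);
          cacheStateCol(cur, e, ph, m);
          direct = true;
        } else {
          const double nv = ph.lamF[m] * std::exp(scales[b] * norm_rand());
          phProp.lamF[m] = nv;
          for (int i : byState[m]) {
            const double gn = freshG(e, phProp, i, m);
            if (gn <= 0.0) { dll = R_NegInf; break; }
            dll += std::log(gn) - std::log(cur.G[(size_t)i * M + m]);
          }
          const double em = tr.occ[m] - nEp[m];
          if (std::isfinite(dll) && em > 0.0)
            dll += em * (std::log(dEmptyOf(phProp, m)) -
                         std::log(cur.dEmpty[m]));
          dPrior = R::dgamma(nv, fShape, 1.0 / fRate, 1) -
            R::dgamma(ph.lamF[m], fShape, 1.0 / fRate, 1);
          jac = std::log(nv / ph.lamF[m]);
        }
      } else { // piEx, logit walk; pure arithmetic via the signal caches
        const double x = std::log(ph.piEx / (1.0 - ph.piEx)) +
          scales[b] * norm_rand();
        const double nv = 1.0 / (1.0 + std::exp(-x));
        phProp.piEx = nv;
        for (int i = 0; i < e.P; ++i) {
          const int s = tr.sEpoch[i];
          const double gn = freshGFromSignal(e, phProp, cur, i, s);
          if (gn <= 0.0) { dll = R_NegInf; break; }
          dll += std::log(gn) - std::log(cur.G[(size_t)i * M + s]);
        }
        if (std::isfinite(dll)) {
          for (int m = 0; m < M; ++m) {
            const double em = tr.occ[m] - nEp[m];
            if (em > 0.0)
              dll += em * (std::log(dEmptyOf(phProp, m)) -
                           std::log(cur.dEmpty[m]));
          }
        }
        dPrior = R::dbeta(nv, pexA, pexB, 1) - R::dbeta(ph.piEx, pexA, pexB, 1);
        jac = std::log(nv * (1.0 - nv)) - std::log(ph.piEx * (1.0 - ph.piEx));
      }
      if (direct) continue;
      bool acc = false;
      if (std::isfinite(dll)) {
        const double la = dll + dPrior + jac;
        acc = (la >= 0.0) || (std::log(unif_rand()) < la);
      }
      ++tryWin[b];
      if (sweep >= nTune) tryTot[b] += 1.0;
      if (acc) {
        ph = phProp;
        if (b == 0) {
          for (int m = 0; m < M; ++m) cacheStateCol(cur, e, ph, m);
        } else if (b == 1) {
          cacheAcceptor(cur, e, ph);
        } else if (b < M + 2) {
          cacheStateCol(cur, e, ph, b - 2);
        } else {
          cachePiEx(cur, e, ph);
        }
        ++accWin[b];
        if (sweep >= nTune) accTot[b] += 1.0;
      }
    }
    // adapt proposal scales during the tuning window only
    if (sweep < nTune && (sweep + 1) % tuneEvery == 0) {
      for (int b = 0; b < nBlocks; ++b) {
        if (tryWin[b] > 0) {
          const double r = (double)accWin[b] / tryWin[b];
          scales[b] *= std::exp(1.2 * (r - 0.3));
          if (scales[b] < 1e-4) scales[b] = 1e-4;
          if (scales[b] > 3.0) scales[b] = 3.0;
        }
        accWin[b] = tryWin[b] = 0;
      }
    }
    // ---- 2) conjugate transition-matrix rows ------------------------------
    {
      std::vector<double> shape(M), row(M);
      for (int m = 0; m < M; ++m) {
        for (int j = 0; j < M; ++j)
          shape[j] = tr.counts[(size_t)m * M + j] + rowPrior[j];
        rdirichlet(shape.data(), M, row.data());
        for (int j = 0; j < M; ++j) Pi[(size_t)m * M + j] = row[j];
      }
    }
    // ---- 2b) optional HDP base-measure resampling -------------------------
    if (sampleBeta) {
      std::vector<double> tables(M, 0.0);
      for (int m = 0; m < M; ++m)
        for (int j = 0; j < M; ++j) {
          const double n = tr.counts[(size_t)m * M + j];
          const double ab = alphaConc * beta[j];
          const long long nn = (long long)n;
          for (long long i = 0; i < nn; ++i) {
            if (unif_rand() < ab / (ab + (double)i)) tables[j] += 1.0;
          }
        }
      std::vector<double> shape(M);
      for (int j = 0; j < M; ++j) shape[j] = gammaConc / M + tables[j];
      rdirichlet(shape.data(), M, beta.data());
      for (int j = 0; j < M; ++j) rowPrior[j] = alphaConc * beta[j];
    }
    // ---- 3) FFBS trajectory ----------------------------------------------
    pw.build(Pi, cur.dEmpty, M, maxGap);
    llCur = forwardPass(e, cur, Pi, rho, pw, abar.data());
    if (!std::isfinite(llCur))
      stop("trajectory update encountered a zero-likelihood state");
    backwardSample(e, cur, Pi, rho, pw, abar.data(), nPulses, tr);
    // ---- 4) initial probabilities -----------------------------------------
    {
      std::vector<double> shape(rhoc);
      shape[tr.s1] += 1.0;
      rdirichlet(shape.data(), M, rho.data());
    }
    llCur = forwardPass(e, cur, Pi, rho, pw, nullptr);
    // ---- record -----------------------------------------------------------
    double lp = llCur;
    lp += R::dgamma(ph.lamD, dShape, 1.0 / dRate, 1);
    lp += R::dgamma(ph.lamA, aShape, 1.0 / aRate, 1);
    for (int m = 0; m < M; ++m)
      lp += R::dgamma(ph.lamF[m], fShape, 1.0 / fRate, 1);
    lp += R::dbeta(ph.piEx, pexA, pexB, 1);
    {
      std::vector<double> row(M);
      for (int m = 0; m < M; ++m) {
        for (int j = 0; j < M; ++j) row[j] = Pi[(size_t)m * M + j];
        lp += logDirichlet(row, rowPrior, M);
      }
      lp += logDirichlet(rho, rhoc, M);
    }
    for (int i = 0; i < M; ++i)
      for (int j = 0; j < M; ++j)
        outPi[(R_xlen_t)sweep * M * M + (R_xlen_t)j * M + i] =
          Pi[(size_t)i * M + j];
    outLamD[sweep] = ph.lamD;
    outLamA[sweep] = ph.lamA;
    outPiEx[sweep] = ph.piEx;
    for (int m = 0; m < M; ++m) {
      outLamF(sweep, m) = ph.lamF[m];
      outRho(sweep, m) = rho[m];
      outOcc(sweep, m) = tr.occ[m];
      if (sampleBeta) outBeta(sweep, m) = beta[m];
    }
    outS1[sweep] = tr.s1 + 1;
    outLL[sweep] = llCur;
    outLP[sweep] = lp;
    if (progressEvery > 0 && (sweep + 1) % progressEvery == 0)
      Rprintf("  sweep %d / %d (log posterior %.4g)\n", sweep + 1, nSweeps, lp);
    if ((sweep & 63) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector accRate(nBlocks), scalesOut(nBlocks);
  for (int b = 0; b < nBlocks; ++b) {
    accRate[b] = tryTot[b] > 0.0 ? accTot[b] / tryTot[b] : NA_REAL;
    scalesOut[b] = scales[b];
  }
  outPi.attr("dim") = IntegerVector::create(M, M, nSweeps);
  return List::create(
    _["transProb"] = outPi, _["lambdaD"] = outLamD, _["lambdaA"] = outLamA,
    _["lambdaFret"] = outLamF, _["piEx"] = outPiEx, _["rhoStart"] = outRho,
    _["occupancy"] = outOcc, _["s1"] = outS1, _["beta"] = outBeta,
    _["logLik"] = outLL, _["logPost"] = outLP,
    _["acceptance"] = accRate, _["proposalScales"] = scalesOut);
}

// ---------------------------------------------------------------------------
// exported: simulators
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_trajectory(NumericMatrix Pi, NumericVector rho,
                             double nPulses) {
  const int M = Pi.nrow();
  std::vector<double> cum((size_t)M * M);
  for (int i = 0; i < M; ++i) {
    double a = 0.0;
    for (int j = 0; j < M; ++j) {
      a += Pi(i, j);
      cum[(size_t)i * M + j] = a;
    }
  }
  std::vector<double> cr(M);
  double a = 0.0;
  for (int j = 0; j < M; ++j) { a += rho[j]; cr[j] = a; }
  const long long N = (long long)nPulses;
  std::vector<int> rleState;
  std::vector<double> rleLen;
  double u = unif_rand();
  int s = 0;
  while (s < M - 1 && u > cr[s]) ++s;
  int curState = s;
  double runLen = 1.0;
  for (long long n = 1; n < N; ++n) {
    u = unif_rand();
    const double* ci = &cum[(size_t)curState * M];
    if (u <= ci[curState] &&
        (curState == 0 || u > ci[curState - 1])) {
      runLen += 1.0; // stayed (fast path for the common case)
      continue;
    }
    int ns = 0;
    while (ns < M - 1 && u > ci[ns]) ++ns;
    if (ns == curState) {
      runLen += 1.0;
    } else {
      rleState.push_back(curState + 1);
      rleLen.push_back(runLen);
      curState = ns;
      runLen = 1.0;
    }
  }
  rleState.push_back(curState + 1);
  rleLen.push_back(runLen);
  return List::create(_["state"] = wrap(rleState), _["length"] = wrap(rleLen));
}

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix Pi, NumericVector rho, List modelArgs,
                  double nPulses) {
  Phys ph = parsePhys(modelArgs);
  const int M = ph.M;
  std::vector<double> cum((size_t)M * M);
  for (int i = 0; i < M; ++i) {
    double a = 0.0;
    for (int j = 0; j < M; ++j) { a += Pi(i, j); cum[(size_t)i * M + j] = a; }
  }
  std::vector<double> cr(M);
  {
    double a = 0.0;
    for (int j = 0; j < M; ++j) { a += rho[j]; cr[j] = a; }
  }
  const long long N = (long long)nPulses;
  std::vector<double> pIdx, mu;
  std::vector<int> chan, phState;
  std::vector<int> rleState;
  std::vector<double> rleLen;
  const double tauEdge = ph.tau * (1.0 - 1e-12);

  double u = unif_rand();
  int s = 0;
  while (s < M - 1 && u > cr[s]) ++s;
  int curState = s;
  double runLen = 0.0;

  for (long long n = 0; n < N; ++n) {
    if (n > 0) {
      u = unif_rand();
      const double* ci = &cum[(size_t)curState * M];
      int ns = 0;
      while (ns < M - 1 && u > ci[ns]) ++ns;
      if (ns != curState) {
        rleState.push_back(curState + 1);
        rleLen.push_back(runLen);
        curState = ns;
        runLen = 0.0;
      }
    }
    runLen += 1.0;
    double muD = -1.0, muA = -1.0;
    // signal photon
    if (unif_rand() < ph.piEx) {
      const double lamTot = ph.lamD + ph.lamF[curState];
      int band;
      double t;
      if (unif_rand() < ph.lamD / lamTot) {
        band = 0;
        t = exp_rand() / lamTot;
      } else {
        band = 1;
        t = exp_rand() / lamTot + exp_rand() / ph.lamA;
      }
      const double p0 = band == 0 ? ph.r00 : ph.r10;
      const double p1 = band == 0 ? ph.r01 : ph.r11;
      const double ur = unif_rand();
      int ch = -1;
      if (ur < p0) ch = 0;
      else if (ur < p0 + p1) ch = 1;
      if (ch >= 0) {
        double m = t + ph.irfM;
        if (ph.irfS > 0.0) m += ph.irfS * norm_rand();
        if (m < 0.0) m = 0.0;
        if (m >= ph.tau) m = tauEdge;
        if (ch == 0) muD = m; else muA = m;
      }
    }
    // background photons; on a collision the earlier arrival is kept
    if (ph.bg0 > 0.0 && unif_rand() < ph.bg0) {
      const double m = unif_rand() * ph.tau;
      if (muD < 0.0 || m < muD) muD = m;
    }
    if (ph.bg1 > 0.0 && unif_rand() < ph.bg1) {
      const double m = unif_rand() * ph.tau;
      if (muA < 0.0 || m < muA) muA = m;
    }
    if (muD >= 0.0) {
      pIdx.push_back((double)(n + 1));
      chan.push_back(1);
      mu.push_back(muD);
      phState.push_back(curState + 1);
    }
    if (muA >= 0.0) {
      pIdx.push_back((double)(n + 1));
      chan.push_back(2);
      mu.push_back(muA);
      phState.push_back(curState + 1);
    }
    if ((n & 1048575LL) == 0) Rcpp::checkUserInterrupt();
  }
  rleState.push_back(curState + 1);
  rleLen.push_back(runLen);
  return List::create(
    _["pulseIndex"] = wrap(pIdx), _["channel"] = wrap(chan),
    _["microtime"] = wrap(mu), _["photonState"] = wrap(phState),
    _["rleState"] = wrap(rleState), _["rleLength"] = wrap(rleLen));
}
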