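// Metropolis-within-Gibbs sampler for the data-augmented Jolly-Seber model
// with integrated capture-resight histories and unmarked counts.
//
// Latent states are updated by exact per-individual Gibbs draws: each
// augmented individual's trajectory is summarized by (b, d, a1) -- entry
// year b in 1..T+1 (T+1 = never enters), first dead year d in b+1..T+1
// (d = T+1 = alive through the last year), and the first-year age indicator
// a1 (used only when b = 1).  Because survival is an absorbing Bernoulli
// chain, (b, d, a1) enumerates every latent trajectory, so the full
// conditional of one individual given the rest is a finite categorical
// distribution that can be sampled exactly.  Entry probabilities follow the
// realized-abundance convention pi_t = N_{t-1} * gamma_{t-1} / M, so moving
// one individual changes the entry weights of all individuals; the update
// accounts for this through the summed entry term.
//
// Continuous parameters (and the latent true covariate values for climate
// variants) are updated by adaptive random-walk Metropolis on transformed
// scales, using sufficient statistics of the current latent configuration.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// parameter indices
enum { P_ALPHA = 0, P_B0G, P_B1G1, P_B1G2, P_B2G, P_B0PSY, P_B0PASY,
       P_B1P1, P_B1P2, P_B0C, P_B1C, P_K, P_TAU, P_PETA, P_PR, P_PI1,
       NPAR };

struct Model {
  int M, T;
  double area, logM;
  int dd_power, ncp, variant;          // variant: 0 time, 1 climate
  IntegerVector u;
  std::vector<int> single;             // 0/1 per year
  std::vector<int> period;             // 0-based period index per year
  NumericVector mu, sig;               // covariate estimates (climate)
  NumericVector syear;                 // centered/scaled year index
  // priors
  double sd_beta, sd_b2, rate_alpha, pr_a, pr_b, sd_w;
  // per-individual data summaries (1-based years; 0 = none)
  std::vector<int> f, l, ac;           // first capture, last detection, age class
  std::vector<std::vector<int>> y;     // resight data [i][t-1]
};

struct State {
  std::vector<int> b, d, a1;
  // sufficient statistics (1-based year indexing, slot 0 unused)
  std::vector<int> e;                  // entries per year, size T+2
  std::vector<int> n1, n2, N, U;       // size T+1
  std::vector<int> sS, fS, sA, fA;     // survival transitions, size T (use 1..T-1)
  long nS1, nA1;                       // first-year age tallies
  long RYn, RNn, RYs, RNs;             // resights: normal / single-day years
  long CA, CH;                         // aged-specific / AHY captures (constant)
  std::vector<int> capPY;              // captures per year (constant)
};

static inline bool sy_at(int b, int a1, int t) {
  return t == 1 ? (b == 1 && a1 == 0) : (b == t);
}

// add (sgn=+1) or remove (sgn=-1) individual i's contributions
static void apply_individual(const Model& m, State& s, int i, int sgn) {
  int b = s.b[i], d = s.d[i], a1 = s.a1[i];
  int T = m.T;
  if (b == T + 1) { s.e[T + 1] += sgn; return; }
  s.e[b] += sgn;
  if (b == 1) { if (a1) s.nA1 += sgn; else s.nS1 += sgn; }
  int lastAlive = d - 1;
  for (int t = b; t <= lastAlive; ++t) {
    s.N[t] += sgn;
    if (sy_at(b, a1, t)) s.n1[t] += sgn; else s.n2[t] += sgn;
  }
  int uEnd = (m.f[i] > 0) ? std::min(lastAlive, m.f[i] - 1) : lastAlive;
  for (int t = b; t <= uEnd; ++t) s.U[t] += sgn;
  for (int t = b; t <= lastAlive - 1; ++t) {
    if (sy_at(b, a1, t)) s.sS[t] += sgn; else s.sA[t] += sgn;
  }
  if (d <= T) {
    int t = d - 1;
    if (sy_at(b, a1, t)) s.fS[t] += sgn; else s.fA[t] += sgn;
  }
  if (m.f[i] > 0) {
    for (int t = m.f[i]; t <= lastAlive; ++t) {
      bool yy = m.y[i][t - 1] == 1;
      if (m.single[t - 1]) { if (yy) s.RYs += sgn; else s.RNs += sgn; }
      else                 { if (yy) s.RYn += sgn; else s.RNn += sgn; }
    }
  }
}

static inline double safe_log(double x) {
  return x > 0 ? std::log(x) : NEG_INF;
}

// numerical clipping: probabilities derived from logistic transforms are
// kept strictly inside (0, 1) so that saturation of the logit scale cannot
// produce spurious -Inf log-terms; structural zeros (dead individuals,
// counts exceeding availability, entries without abundance) remain exact
static const double P_EPS = 1e-15;
static inline double clamp01(double p) {
  if (p < P_EPS) return P_EPS;
  if (p > 1.0 - P_EPS) return 1.0 - P_EPS;
  return p;
}
static inline double inv_logit_c(double x) {
  return clamp01(1.0 / (1.0 + std::exp(-x)));
}

// conditional log-likelihood + prior of the continuous parameters given the
// latent sufficient statistics (everything that depends on theta/w)
static double cond_loglik(const Model& m, const State& s,
                          const std::vector<double>& th,
                          const std::vector<double>& w) {
  int T = m.T;
  double alpha = th[P_ALPHA], b2g = th[P_B2G];
  double k = th[P_K], tau = th[P_TAU], peta = th[P_PETA], pr = th[P_PR],
         pi1 = th[P_PI1];
  if (alpha <= 0 || b2g < 0) return NEG_INF;
  if (k < 0 || k > 1 || tau < 0 || tau > 1 || peta < 0 || peta > 1 ||
      pr < 0 || pr > 1 || pi1 < 0 || pi1 > 1) return NEG_INF;

  k = clamp01(k); tau = clamp01(tau); peta = clamp01(peta);
  pr = clamp01(pr); pi1 = clamp01(pi1);

  double lp = 0.0;
  // priors
  double sb2 = 2.0 * m.sd_beta * m.sd_beta;
  double betas[] = { th[P_B0G], th[P_B1G1], th[P_B0PSY], th[P_B0PASY],
                     th[P_B1P1], th[P_B0C], th[P_B1C] };
  for (double b : betas) lp += -b * b / sb2;
  if (m.ncp == 2) lp += -(th[P_B1G2] * th[P_B1G2] +
                          th[P_B1P2] * th[P_B1P2]) / sb2;
  lp += -b2g * b2g / (2.0 * m.sd_b2 * m.sd_b2); // half-normal (constant dropped)
  lp += -m.rate_alpha * alpha;                  // exponential
  lp += (m.pr_a - 1.0) * safe_log(pr) + (m.pr_b - 1.0) * safe_log(1.0 - pr);
  if (!std::isfinite(lp)) return NEG_INF;

  // entry term with realized abundances
  double P = pi1;
  if (s.e[1] > 0) {
    double l1 = safe_log(pi1);
    if (!std::isfinite(l1)) return NEG_INF;
    lp += s.e[1] * l1;
  }
  for (int t = 2; t <= T; ++t) {
    int Np = s.N[t - 1];
    double b1 = (m.ncp == 2 && m.period[t - 2]) ? th[P_B1G2] : th[P_B1G1];
    double eta = th[P_B0G] + b1 * w[t - 2] -
                 b2g * std::pow((double)Np / m.area, (double)m.dd_power);
    double gam = alpha * inv_logit_c(eta);
    double pit = Np * gam / m.M;
    P += pit;
    if (s.e[t] > 0) {
      double lt = safe_log(pit);
      if (!std::isfinite(lt)) return NEG_INF;
      lp += s.e[t] * lt;
    }
  }
  double rem = 1.0 - P;
  if (rem < 0) return NEG_INF;
  if (s.e[T + 1] > 0) {
    double lr = safe_log(rem);
    if (!std::isfinite(lr)) return NEG_INF;
    lp += s.e[T + 1] * lr;
  }

  // first-year ages
  if (s.nA1 > 0) lp += s.nA1 * safe_log(tau);
  if (s.nS1 > 0) lp += s.nS1 * safe_log(1.0 - tau);
  if (!std::isfinite(lp)) return NEG_INF;

  // survival
  for (int t = 1; t <= T - 1; ++t) {
    double b1 = (m.ncp == 2 && m.period[t - 1]) ? th[P_B1P2] : th[P_B1P1];
    double phS = inv_logit_c(th[P_B0PSY] + b1 * w[t - 1]);
    double phA = inv_logit_c(th[P_B0PASY] + b1 * w[t - 1]);
    if (s.sS[t] > 0) lp += s.sS[t] * safe_log(phS);
    if (s.fS[t] > 0) lp += s.fS[t] * safe_log(1.0 - phS);
    if (s.sA[t] > 0) lp += s.sA[t] * safe_log(phA);
    if (s.fA[t] > 0) lp += s.fA[t] * safe_log(1.0 - phA);
    if (!std::isfinite(lp)) return NEG_INF;
  }

  // captures
  for (int t = 1; t <= T; ++t) {
    double pc = inv_logit_c(th[P_B0C] + th[P_B1C] * m.syear[t - 1]);
    if (s.capPY[t] > 0) lp += s.capPY[t] * safe_log(pc);
    if (s.U[t] > 0) lp += s.U[t] * safe_log(1.0 - pc);
    if (!std::isfinite(lp)) return NEG_INF;
  }
  if (s.CA > 0) lp += s.CA * safe_log(k);
  if (s.CH > 0) lp += s.CH * safe_log(1.0 - k);
  if (!std::isfinite(lp)) return NEG_INF;

  // resights
  if (s.RYn > 0) lp += s.RYn * safe_log(peta);
  if (s.RNn > 0) lp += s.RNn * safe_log(1.0 - peta);
  double ps = clamp01(peta * pr);
  if (s.RYs > 0) lp += s.RYs * safe_log(ps);
  if (s.RNs > 0) lp += s.RNs * safe_log(1.0 - ps);
  if (!std::isfinite(lp)) return NEG_INF;

  // unmarked counts
  for (int t = 1; t <= T; ++t) {
    int ut = m.u[t - 1], Ut = s.U[t];
    if (ut > Ut) return NEG_INF;
    double p = clamp01(peta * (m.single[t - 1] ? pr : 1.0));
    lp += R::dbinom((double)ut, (double)Ut, p, 1);
    if (!std::isfinite(lp)) return NEG_INF;
  }

  // covariate measurement model + prior on latent covariate values
  if (m.variant == 1) {
    for (int t = 0; t < T; ++t) {
      lp += R::dnorm(m.mu[t], w[t], m.sig[t], 1);
      lp += -w[t] * w[t] / (2.0 * m.sd_w * m.sd_w);
    }
  }
  return lp;
}

struct Tables {
  std::vector<double> gam, lgam;       // [t-1][N], t = 1..T-1, N = 0..M
  std::vector<double> lphiS, l1phiS, lphiA, l1phiA;  // t = 1..T-1
  std::vector<double> lpc, l1pc, lpdet, l1pdet, pdet; // t = 1..T
  std::vector<double> lgN;             // log(n), n = 0..M
  std::vector<double> lgfact;          // lgamma(n+1), n = 0..M
  double ltau, l1tau, lpi1, pi1;
};

static void refresh_tables(const Model& m, const std::vector<double>& th,
                           const std::vector<double>& w, Tables& tb) {
  int T = m.T, M = m.M;
  tb.gam.assign((size_t)(T - 1) * (M + 1), 0.0);
  tb.lgam.assign((size_t)(T - 1) * (M + 1), 0.0);
  for (int t = 1; t <= T - 1; ++t) {
    double b1 = (m.ncp == 2 && m.period[t - 1]) ? th[P_B1G2] : th[P_B1G1];
    double base = th[P_B0G] + b1 * w[t - 1];
    for (int n = 0; n <= M; ++n) {
      double dens = (double)n / m.area;
      double eta = base - th[P_B2G] *
        (m.dd_power == 2 ? dens * dens : dens);
      double g = th[P_ALPHA] * inv_logit_c(eta);
      tb.gam[(size_t)(t - 1) * (M + 1) + n] = g;
      tb.lgam[(size_t)(t - 1) * (M + 1) + n] = std::log(g);
    }
  }
  tb.lphiS.assign(T, 0.0); tb.l1phiS.assign(T, 0.0);
  tb.lphiA.assign(T, 0.0); tb.l1phiA.assign(T, 0.0);
  for (int t = 1; t <= T - 1; ++t) {
    double b1 = (m.ncp == 2 && m.period[t - 1]) ? th[P_B1P2] : th[P_B1P1];
    double phS = inv_logit_c(th[P_B0PSY] + b1 * w[t - 1]);
    double phA = inv_logit_c(th[P_B0PASY] + b1 * w[t - 1]);
    tb.lphiS[t - 1] = safe_log(phS); tb.l1phiS[t - 1] = safe_log(1 - phS);
    tb.lphiA[t - 1] = safe_log(phA); tb.l1phiA[t - 1] = safe_log(1 - phA);
  }
  tb.lpc.assign(T, 0.0); tb.l1pc.assign(T, 0.0);
  tb.lpdet.assign(T, 0.0); tb.l1pdet.assign(T, 0.0); tb.pdet.assign(T, 0.0);
  for (int t = 0; t < T; ++t) {
    double pc = inv_logit_c(th[P_B0C] + th[P_B1C] * m.syear[t]);
    tb.lpc[t] = safe_log(pc); tb.l1pc[t] = safe_log(1 - pc);
    double p = clamp01(th[P_PETA] * (m.single[t] ? th[P_PR] : 1.0));
    tb.pdet[t] = p;
    tb.lpdet[t] = safe_log(p); tb.l1pdet[t] = safe_log(1 - p);
  }
  double tau_c = clamp01(th[P_TAU]), pi1_c = clamp01(th[P_PI1]);
  tb.ltau = std::log(tau_c); tb.l1tau = std::log(1 - tau_c);
  tb.lpi1 = std::log(pi1_c);
  tb.pi1 = pi1_c;
}

// one exact Gibbs draw of individual i's (b, d, a1).
//
// After removing i, every remaining quantity the candidate trajectory
// touches changes only over the contiguous alive span [b, d-1], so all
// span sums are precomputed as prefix sums and each candidate is scored in
// O(1) (plus one log for the never-enter mass).
static void update_individual(const Model& m, State& s, const Tables& tb,
                              int i, std::vector<double>& wlog,
                              std::vector<int>& cb, std::vector<int>& cd,
                              std::vector<int>& ca) {
  int T = m.T, M = m.M;
  apply_individual(m, s, i, -1);

  // ---- per-year base quantities without i ----
  // counts: cnt0 = binomial count term without i, cnt1 = with i in U_t;
  // years where u exceeds U without i must be covered by the candidate.
  static std::vector<double> cumDD, cumDpi, cumDlp, cumPhiA, cumL1pc, cumRes,
                             lpi_own;
  static std::vector<int> req_;
  cumDD.assign(T + 2, 0.0);    // prefix over U-membership deltas (count term)
  cumDpi.assign(T + 2, 0.0);   // prefix over pi deltas (entry masses)
  cumDlp.assign(T + 2, 0.0);   // prefix over entry log-prob deltas
  cumPhiA.assign(T + 2, 0.0);  // prefix of log phi_ASY
  cumL1pc.assign(T + 2, 0.0);  // prefix of log(1 - p_cap)
  lpi_own.assign(T + 2, NEG_INF); // own entry log-probability at year b
  req_.clear();

  double S0 = 0.0, P0 = tb.pi1;
  for (int t = 1; t <= T; ++t) {
    // count-term deltas (i alive & unmarked at t shifts U_t by +1)
    int ut = m.u[t - 1], U0 = s.U[t];
    double c0, c1, ddt;
    double lut = tb.lgfact[ut];
    c1 = (ut > U0 + 1) ? NEG_INF
         : tb.lgfact[U0 + 1] - lut - tb.lgfact[U0 + 1 - ut] +
           (ut > 0 ? ut * tb.lpdet[t - 1] : 0.0) +
           ((U0 + 1 - ut) > 0 ? (U0 + 1 - ut) * tb.l1pdet[t - 1] : 0.0);
    if (ut > U0) { req_.push_back(t); ddt = c1; }
    else {
      c0 = tb.lgfact[U0] - lut - tb.lgfact[U0 - ut] +
           (ut > 0 ? ut * tb.lpdet[t - 1] : 0.0) +
           ((U0 - ut) > 0 ? (U0 - ut) * tb.l1pdet[t - 1] : 0.0);
      ddt = c1 - c0;
    }
    cumDD[t] = cumDD[t - 1] + ddt;
    // entry deltas for year t+1 (driven by N_t)
    double dpi = 0.0, dlp = 0.0;
    if (t <= T - 1) {
      int Np = s.N[t];
      const double* gv = &tb.gam[(size_t)(t - 1) * (M + 1)];
      const double* lg = &tb.lgam[(size_t)(t - 1) * (M + 1)];
      double pi0 = Np * gv[Np] / M;
      double pi1m = (Np + 1) * gv[Np + 1] / M;
      dpi = pi1m - pi0;
      P0 += pi0;
      if (s.e[t + 1] > 0) {
        if (Np == 0) {
          // entries at t+1 impossible without i alive at t: candidate must
          // cover year t; store the absolute term for covered candidates
          req_.push_back(-(t));        // negative marks an entry requirement
          dlp = s.e[t + 1] * (tb.lgN[Np + 1] + lg[Np + 1] - m.logM);
        } else {
          double l0 = tb.lgN[Np] + lg[Np] - m.logM;
          double l1 = tb.lgN[Np + 1] + lg[Np + 1] - m.logM;
          S0 += s.e[t + 1] * l0;
          dlp = s.e[t + 1] * (l1 - l0);
        }
      }
    }
    cumDpi[t] = cumDpi[t - 1] + dpi;
    cumDlp[t] = cumDlp[t - 1] + dlp;
    // survival / capture prefixes
    cumPhiA[t] = cumPhiA[t - 1] + ((t <= T - 1) ? tb.lphiA[t - 1] : 0.0);
    cumL1pc[t] = cumL1pc[t - 1] + tb.l1pc[t - 1];
    // own entry log-probability at b = t (uses N_{t-1} without i)
    if (t == 1) lpi_own[1] = tb.lpi1;
    else {
      int Np = s.N[t - 1];
      if (Np > 0)
        lpi_own[t] = tb.lgN[Np] +
          tb.lgam[(size_t)(t - 2) * (M + 1) + Np] - m.logM;
    }
  }
  if (s.e[1] > 0) S0 += s.e[1] * tb.lpi1;

  int f = m.f[i], l = m.l[i], acl = m.ac[i];
  // own resight-term prefix (only meaningful from f onward)
  cumRes.assign(T + 2, 0.0);
  if (f > 0)
    for (int t = f; t <= T; ++t)
      cumRes[t] = cumRes[t - 1] +
        (m.y[i][t - 1] ? tb.lpdet[t - 1] : tb.l1pdet[t - 1]);

  wlog.clear(); cb.clear(); cd.clear(); ca.clear();
  int rej_own = 0, rej_rem = 0, rej_req = 0, rej_fin = 0;

  int bmax = (f > 0) ? f : T + 1;
  for (int b = 1; b <= bmax; ++b) {
    if (f > 0) {
      if (acl == 1 && b != f) continue;           // aged SY: entered at capture
      if (acl == 2 && f > 1 && b >= f) continue;  // aged ASY: entered earlier
      if (acl == 2 && f == 1 && b != 1) continue;
    }
    int dmin = (b == T + 1) ? T + 1 : std::max(b + 1, l + 1);
    for (int d = dmin; d <= T + 1; ++d) {
      int lastAlive = (b == T + 1) ? 0 : d - 1;
      // span-dependent but a1-independent pieces
      int affEnd = std::min(lastAlive, T - 1);     // entry years affected
      double entS = S0, entP = P0;
      if (b <= T && affEnd >= b) {
        entS += cumDlp[affEnd] - cumDlp[b - 1];
        entP += cumDpi[affEnd] - cumDpi[b - 1];
      }
      double own = (b <= T) ? lpi_own[b] : 0.0;
      if (b <= T && own == NEG_INF) { ++rej_own; continue; } // no abundance to recruit from
      double rem = 1.0 - entP;
      int cntT1 = s.e[T + 1] + (b == T + 1 ? 1 : 0);
      if (rem < -1e-12) { ++rej_rem; continue; }
      double lw0 = entS + own;
      if (cntT1 > 0) {
        if (rem <= 0) { ++rej_rem; continue; }
        lw0 += cntT1 * std::log(rem);
      }
      if (b <= T) {
        int uEnd = (f > 0) ? std::min(lastAlive, f - 1) : lastAlive;
        // coverage of required years (counts: t must be in [b, uEnd];
        // entries: stored as -t, i must be alive at t)
        if (!req_.empty()) {
          bool ok = true;
          for (int r : req_) {
            if (r > 0) { if (!(b <= r && r <= uEnd)) { ok = false; break; } }
            else { int t = -r; if (!(b <= t && t <= lastAlive)) { ok = false; break; } }
          }
          if (!ok) { ++rej_req; continue; }
        }
        if (uEnd >= b) lw0 += (cumDD[uEnd] - cumDD[b - 1]) +
                              (cumL1pc[uEnd] - cumL1pc[b - 1]);
        if (f > 0 && lastAlive >= f) lw0 += cumRes[lastAlive] - cumRes[f - 1];
        // ASY survival over the whole span; the SY correction at year b is
        // a1-dependent and added below
        if (lastAlive - 1 >= b) lw0 += cumPhiA[lastAlive - 1] - cumPhiA[b - 1];
        if (d <= T) lw0 += tb.l1phiA[d - 2];       // death term (ASY default)
      } else if (!req_.empty()) { ++rej_req; continue; }

      int a1lo = 0, a1hi = 0;
      if (b == 1) {
        a1lo = 0; a1hi = 1;
        if (f == 1) {
          if (acl == 1) { a1lo = a1hi = 0; }
          else if (acl == 2) { a1lo = a1hi = 1; }
        }
      }
      for (int a1 = a1lo; a1 <= a1hi; ++a1) {
        double lw = lw0;
        if (b <= T) {
          if (b == 1) lw += a1 ? tb.ltau : tb.l1tau;
          bool sy_entry = (b > 1) || (a1 == 0);    // SY in the entry year?
          if (sy_entry && b <= T - 1) {
            if (d - 1 > b)            // survived the entry-year transition
              lw += tb.lphiS[b - 1] - tb.lphiA[b - 1];
            else if (d == b + 1 && d <= T)  // died at the first transition
              lw += tb.l1phiS[b - 1] - tb.l1phiA[b - 1];
          }
        }
        if (!std::isfinite(lw)) { ++rej_fin; continue; }
        wlog.push_back(lw); cb.push_back(b); cd.push_back(d); ca.push_back(a1);
      }
      if (b == T + 1) break;            // single d for "never"
    }
  }
  if (wlog.empty())
    stop("latent update found no admissible trajectory for individual %d "
         "(first capture %d, last detection %d, age class %d, "
         "current b=%d d=%d; rejections: entry %d, mass %d, coverage %d, "
         "non-finite %d)", i + 1, f, l, acl, s.b[i], s.d[i],
         rej_own, rej_rem, rej_req, rej_fin);

  // categorical draw
  double mx = NEG_INF;
  for (double v : wlog) if (v > mx) mx = v;
  double tot = 0.0;
  for (size_t j = 0; j < wlog.size(); ++j) {
    wlog[j] = std::exp(wlog[j] - mx);
    tot += wlog[j];
  }
  double uu = R::runif(0.0, tot), acc = 0.0;
  size_t pick = wlog.size() - 1;
  for (size_t j = 0; j < wlog.size(); ++j) {
    acc += wlog[j];
    if (uu <= acc) { pick = j; break; }
  }
  s.b[i] = cb[pick]; s.d[i] = cd[pick]; s.a1[i] = ca[pick];
  apply_individual(m, s, i, +1);
}

// parameter-conditional log-density at a fixed latent state; exposed for
// cross-validation against the R reference implementation
// [[Rcpp::export]]
double cpp_cond_loglik(List data, List covs, List priors, List init) {
  Model m;
  IntegerMatrix capture = data["capture"], agecl = data["age_class"],
                resight = data["resight"];
  m.M = capture.nrow(); m.T = capture.ncol();
  m.area = as<double>(data["area"]);
  m.logM = std::log((double)m.M);
  m.u = as<IntegerVector>(data["u"]);
  LogicalVector sgl = data["single_day"];
  m.single.assign(m.T, 0);
  for (int t = 0; t < m.T; ++t) m.single[t] = sgl[t] ? 1 : 0;
  m.dd_power = as<int>(covs["dd_power"]);
  m.ncp = as<int>(covs["ncp"]);
  m.variant = as<int>(covs["variant"]);
  IntegerVector per = covs["period"];
  m.period.assign(m.T, 0);
  for (int t = 0; t < m.T; ++t) m.period[t] = per[t];
  m.mu = as<NumericVector>(covs["mu"]);
  m.sig = as<NumericVector>(covs["sigma"]);
  m.syear = as<NumericVector>(covs["syear"]);
  m.sd_beta = as<double>(priors["sd_beta"]);
  m.sd_b2 = as<double>(priors["sd_b2"]);
  m.rate_alpha = as<double>(priors["rate_alpha"]);
  m.pr_a = as<double>(priors["pr_shape1"]);
  m.pr_b = as<double>(priors["pr_shape2"]);
  m.sd_w = as<double>(priors["sd_w"]);
  m.f.assign(m.M, 0); m.l.assign(m.M, 0); m.ac.assign(m.M, 0);
  m.y.assign(m.M, std::vector<int>(m.T, 0));
  for (int i = 0; i < m.M; ++i)
    for (int t = 0; t < m.T; ++t) {
      m.y[i][t] = resight(i, t);
      if (capture(i, t) == 1 && m.f[i] == 0) { m.f[i] = t + 1; m.ac[i] = agecl(i, t); }
      if (capture(i, t) == 1 || resight(i, t) == 1) m.l[i] = t + 1;
    }
  State s;
  s.b = as<std::vector<int>>(init["b"]);
  s.d = as<std::vector<int>>(init["d"]);
  s.a1 = as<std::vector<int>>(init["a1"]);
  s.e.assign(m.T + 2, 0);
  s.n1.assign(m.T + 1, 0); s.n2.assign(m.T + 1, 0);
  s.N.assign(m.T + 1, 0); s.U.assign(m.T + 1, 0);
  s.sS.assign(m.T + 1, 0); s.fS.assign(m.T + 1, 0);
  s.sA.assign(m.T + 1, 0); s.fA.assign(m.T + 1, 0);
  s.nS1 = s.nA1 = s.RYn = s.RNn = s.RYs = s.RNs = 0;
  s.CA = s.CH = 0;
  s.capPY.assign(m.T + 1, 0);
  for (int i = 0; i < m.M; ++i) {
    if (m.f[i] > 0) {
      s.capPY[m.f[i]] += 1;
      if (m.ac[i] == 1 || m.ac[i] == 2) s.CA += 1; else s.CH += 1;
    }
    apply_individual(m, s, i, +1);
  }
  std::vector<double> th = as<std::vector<double>>(init["theta"]);
  std::vector<double> w = as<std::vector<double>>(init["w"]);
  return cond_loglik(m, s, th, w);
}

// [[Rcpp::export]]
List cpp_js_chain(List data, List covs, List priors, List init,
                  int n_adapt, int n_keep, bool fix_params,
                  bool record_b, int param_passes, bool fix_latent) {
  Model m;
  IntegerMatrix capture = data["capture"], agecl = data["age_class"],
                resight = data["resight"];
  m.M = capture.nrow(); m.T = capture.ncol();
  m.area = as<double>(data["area"]);
  m.logM = std::log((double)m.M);
  m.u = as<IntegerVector>(data["u"]);
  LogicalVector sgl = data["single_day"];
  m.single.assign(m.T, 0);
  for (int t = 0; t < m.T; ++t) m.single[t] = sgl[t] ? 1 : 0;
  m.dd_power = as<int>(covs["dd_power"]);
  m.ncp = as<int>(covs["ncp"]);
  m.variant = as<int>(covs["variant"]);
  IntegerVector per = covs["period"];
  m.period.assign(m.T, 0);
  for (int t = 0; t < m.T; ++t) m.period[t] = per[t];
  m.mu = as<NumericVector>(covs["mu"]);
  m.sig = as<NumericVector>(covs["sigma"]);
  m.syear = as<NumericVector>(covs["syear"]);
  m.sd_beta = as<double>(priors["sd_beta"]);
  m.sd_b2 = as<double>(priors["sd_b2"]);
  m.rate_alpha = as<double>(priors["rate_alpha"]);
  m.pr_a = as<double>(priors["pr_shape1"]);
  m.pr_b = as<double>(priors["pr_shape2"]);
  m.sd_w = as<double>(priors["sd_w"]);

  // per-individual data summaries
  m.f.assign(m.M, 0); m.l.assign(m.M, 0); m.ac.assign(m.M, 0);
  m.y.assign(m.M, std::vector<int>(m.T, 0));
  for (int i = 0; i < m.M; ++i) {
    for (int t = 0; t < m.T; ++t) {
      m.y[i][t] = resight(i, t);
      if (capture(i, t) == 1 && m.f[i] == 0) {
        m.f[i] = t + 1; m.ac[i] = agecl(i, t);
      }
      if (capture(i, t) == 1 || resight(i, t) == 1) m.l[i] = t + 1;
    }
  }

  State s;
  s.b = as<std::vector<int>>(init["b"]);
  s.d = as<std::vector<int>>(init["d"]);
  s.a1 = as<std::vector<int>>(init["a1"]);
  s.e.assign(m.T + 2, 0);
  s.n1.assign(m.T + 1, 0); s.n2.assign(m.T + 1, 0);
  s.N.assign(m.T + 1, 0); s.U.assign(m.T + 1, 0);
  s.sS.assign(m.T + 1, 0); s.fS.assign(m.T + 1, 0);
  s.sA.assign(m.T + 1, 0); s.fA.assign(m.T + 1, 0);
  s.nS1 = s.nA1 = s.RYn = s.RNn = s.RYs = s.RNs = 0;
  s.CA = s.CH = 0;
  s.capPY.assign(m.T + 1, 0);
  for (int i = 0; i < m.M; ++i) {
    if (m.f[i] > 0) {
      s.capPY[m.f[i]] += 1;
      if (m.ac[i] == 1 || m.ac[i] == 2) s.CA += 1; else s.CH += 1;
    }
    apply_individual(m, s, i, +1);
  }

  std::vector<double> th = as<std::vector<double>>(init["theta"]);
  std::vector<double> w = as<std::vector<double>>(init["w"]);

  double cur = cond_loglik(m, s, th, w);
  if (!std::isfinite(cur))
    stop("initial state has non-finite joint density");

  // RWM proposal scales (log) and acceptance tallies
  std::vector<double> ls(NPAR, std::log(0.3)), lsw(m.T, std::log(0.3));
  std::vector<int> accN(NPAR, 0), accW(m.T, 0), tries(NPAR, 0), triesW(m.T, 0);
  // transform codes: 0 identity, 1 log, 2 logit
  int tf[NPAR] = {1, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 2, 2, 2, 2, 2};
  // parameters not updated for this configuration
  std::vector<bool> skip(NPAR, false);
  if (m.ncp != 2) { skip[P_B1G2] = skip[P_B1P2] = true; }
  // b2g has a half-normal prior: log transform would exclude 0, identity
  // with rejection at <0 keeps the boundary reachable
  tf[P_B2G] = 0;

  Tables tb;
  tb.lgN.assign(m.M + 1, 0.0);
  tb.lgN[0] = NEG_INF;
  for (int n = 1; n <= m.M; ++n) tb.lgN[n] = std::log((double)n);
  tb.lgfact.assign(m.M + 2, 0.0);
  for (int n = 0; n <= m.M + 1; ++n) tb.lgfact[n] = std::lgamma(n + 1.0);

  int n_iter = n_adapt + n_keep;
  int ncol_w = (m.variant == 1) ? m.T : 0;
  NumericMatrix draws(n_keep, NPAR + ncol_w + 3 * m.T);
  IntegerMatrix bdraws(record_b ? n_keep : 0, record_b ? m.M : 0);

  std::vector<double> wlog; std::vector<int> cb, cd, ca;
  wlog.reserve(400); cb.reserve(400); cd.reserve(400); ca.reserve(400);

  auto transform_fwd = [&](double v, int code) {
    if (code == 1) return std::log(v);
    if (code == 2) return std::log(v / (1.0 - v));
    return v;
  };
  auto transform_bwd = [&](double x, int code) {
    if (code == 1) return std::exp(x);
    if (code == 2) return 1.0 / (1.0 + std::exp(-x));
    return x;
  };
  auto log_jac = [&](double v, int code) {
    if (code == 1) return std::log(v);
    if (code == 2) return std::log(v) + std::log(1.0 - v);
    return 0.0;
  };

  for (int it = 0; it < n_iter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
    if (!fix_params) {
      // several cheap parameter passes per (expensive) latent sweep: the
      // recruitment block (alpha, intercept, density dependence) is highly
      // correlated in its full conditional and needs the extra movement
      for (int pass = 0; pass < param_passes; ++pass) {
        for (int j = 0; j < NPAR; ++j) {
          if (skip[j]) continue;
          tries[j] += 1;
          double old = th[j];
          // heavy-tailed mixture proposal: occasional wide jumps let the
          // chain cross between modes of weakly identified blocks
          double sc = std::exp(ls[j]) * (R::unif_rand() < 0.1 ? 8.0 : 1.0);
          double x = transform_fwd(old, tf[j]) + R::rnorm(0.0, sc);
          double prop = transform_bwd(x, tf[j]);
          th[j] = prop;
          double nl = cond_loglik(m, s, th, w);
          double lr = (nl + log_jac(prop, tf[j])) -
                      (cur + log_jac(old, tf[j]));
          if (std::isfinite(nl) && std::log(R::runif(0.0, 1.0)) < lr) {
            cur = nl; accN[j] += 1;
          } else th[j] = old;
        }
        if (m.variant == 1) {
          for (int t = 0; t < m.T; ++t) {
            triesW[t] += 1;
            double old = w[t];
            double scw = std::exp(lsw[t]) * (R::unif_rand() < 0.1 ? 8.0 : 1.0);
            w[t] = old + R::rnorm(0.0, scw);
            double nl = cond_loglik(m, s, th, w);
            if (std::isfinite(nl) &&
                std::log(R::runif(0.0, 1.0)) < nl - cur) {
              cur = nl; accW[t] += 1;
            } else w[t] = old;
          }
        }
      }
      // proposal adaptation in batches of 50 during the adaptive phase
      if (it < n_adapt && (it + 1) % 50 == 0) {
        double step = 0.15;
        for (int j = 0; j < NPAR; ++j) {
          if (skip[j] || tries[j] == 0) continue;
          double rate = (double)accN[j] / tries[j];
          ls[j] += (rate > 0.44 ? step : -step);
          accN[j] = 0; tries[j] = 0;
        }
        for (int t = 0; t < m.T && m.variant == 1; ++t) {
          double rate = (double)accW[t] / triesW[t];
          lsw[t] += (rate > 0.44 ? step : -step);
          accW[t] = 0; triesW[t] = 0;
        }
      }
    }

    // latent sweep
    if (!fix_latent) {
      refresh_tables(m, th, w, tb);
      for (int i = 0; i < m.M; ++i)
        update_individual(m, s, tb, i, wlog, cb, cd, ca);
      cur = cond_loglik(m, s, th, w);
    }
    if (!std::isfinite(cur))
      stop("sampler reached a non-finite joint density");

    if (it >= n_adapt) {
      int r = it - n_adapt;
      for (int j = 0; j < NPAR; ++j) draws(r, j) = th[j];
      int off = NPAR;
      if (m.variant == 1) {
        for (int t = 0; t < m.T; ++t) draws(r, off + t) = w[t];
        off += m.T;
      }
      for (int t = 1; t <= m.T; ++t) {
        draws(r, off + t - 1) = s.n1[t];
        draws(r, off + m.T + t - 1) = s.n2[t];
        draws(r, off + 2 * m.T + t - 1) = s.N[t];
      }
      if (record_b)
        for (int i = 0; i < m.M; ++i) bdraws(r, i) = s.b[i];
    }
  }

  return List::create(_["draws"] = draws,
                      _["b_draws"] = bdraws,
                      _["final_loglik"] = cur);
}
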