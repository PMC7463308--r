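// Coalescent machinery: structured-scenario SNP simulator, finite-island
// simulator with migration, and the reversible-jump FST-decomposition MCMC.
// All randomness goes through R's RNG so set.seed() controls everything.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Fast local RNG (xoroshiro128+) seeded from R's RNG at construction, so
// set.seed() still controls every simulation while the hot loops avoid the
// overhead of R's generator.
struct XRng {
  uint64_t s0, s1;
  XRng() {
    s0 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
         (uint64_t)(unif_rand() * 4294967296.0);
    s1 = ((uint64_t)(unif_rand() * 4294967296.0) << 32) ^
         (uint64_t)(unif_rand() * 4294967296.0);
    if (!(s0 | s1)) s0 = 0x9E3779B97F4A7C15ULL;
  }
  inline uint64_t next() {
    uint64_t a = s0, b = s1, r = a + b;
    b ^= a;
    s0 = ((a << 24) | (a >> 40)) ^ b ^ (b << 16);
    s1 = (b << 37) | (b >> 27);
    return r;
  }
  inline double u() { return (next() >> 11) * 1.1102230246251565e-16; }
  inline double e() { return -std::log1p(-u()); }
};

// Sample one coalescent gene tree for a structured scenario and drop a single
// mutation uniformly on total branch length. Any branch subtends a proper
// subset of leaves, so the locus is polymorphic in the pooled sample by
// construction (SNP-style locus, no rejection needed).
//
// events: rows sorted by time; columns (time, type, a, b, c, x) with
//   type 1: merge   — lineages in pop a move to pop b
//   type 2: admix   — lineages in pop a move to pop b w.p. x, else to pop c
//   type 3: resize  — diploid size of pop a becomes x
// Pop indices are 0-based here (converted in the R wrapper).
// Genes are paired into diploids in input order (exchangeable leaves make
// fixed pairing equivalent in law to random pairing).
// [[Rcpp::export]]
IntegerMatrix rg_sim_snp_genotypes(IntegerVector genes_per_pop,
                                   NumericVector pop_sizes,
                                   NumericMatrix events,
                                   int n_loci) {
  const int npop = genes_per_pop.size();
  int n = 0;
  for (int p = 0; p < npop; ++p) {
    if (genes_per_pop[p] % 2 != 0) stop("genes per population must be even (diploids)");
    n += genes_per_pop[p];
  }
  if (n < 2) stop("need at least 2 genes");
  const int n_ind = n / 2;
  const int nev = events.nrow();
  const int nnodes = 2 * n - 1;

  IntegerMatrix G(n_ind, n_loci);
  XRng rng;
  std::vector<double> ntime(nnodes);
  std::vector<int> left(nnodes), right(nnodes), par(nnodes);
  std::vector<std::vector<int>> act(npop);
  std::vector<double> N0(pop_sizes.begin(), pop_sizes.end());

  for (int l = 0; l < n_loci; ++l) {
    std::vector<double> N(N0);
    for (int p = 0; p < npop; ++p) act[p].clear();
    int g = 0;
    for (int p = 0; p < npop; ++p)
      for (int k = 0; k < genes_per_pop[p]; ++k) act[p].push_back(g++);
    for (int v = 0; v < n; ++v) { ntime[v] = 0.0; left[v] = right[v] = -1; par[v] = -1; }
    int nxt = n, total = n, ev = 0;
    double t = 0.0;

    while (total > 1) {
      double rate = 0.0;
      for (int p = 0; p < npop; ++p) {
        double k = (double)act[p].size();
        if (k >= 2.0 && N[p] > 0.0) rate += k * (k - 1.0) / (4.0 * N[p]);
      }
      double dt = (rate > 0.0) ? rng.e() / rate : R_PosInf;
      if (ev < nev && events(ev, 0) <= t + dt) {
        t = events(ev, 0);
        int type = (int)events(ev, 1);
        int a = (int)events(ev, 2);
        if (type == 1) {
          int b = (int)events(ev, 3);
          for (size_t i = 0; i < act[a].size(); ++i) act[b].push_back(act[a][i]);
          act[a].clear();
        } else if (type == 2) {
          int b = (int)events(ev, 3), c = (int)events(ev, 4);
          double x = events(ev, 5);
          for (size_t i = 0; i < act[a].size(); ++i) {
            if (rng.u() < x) act[b].push_back(act[a][i]);
            else act[c].push_back(act[a][i]);
          }
          act[a].clear();
        } else if (type == 3) {
          N[a] = events(ev, 5);
        } else stop("unknown event type");
        ++ev;
        continue;
      }
      if (!R_FINITE(dt)) stop("coalescent cannot complete: isolated lineages remain after all events");
      t += dt;
      double u = rng.u() * rate, cum = 0.0;
      int p = -1;
      for (int q = 0; q < npop; ++q) {
        double k = (double)act[q].size();
        if (k >= 2.0 && N[q] > 0.0) {
          cum += k * (k - 1.0) / (4.0 * N[q]);
          if (u <= cum) { p = q; break; }
        }
      }
      if (p < 0) p = npop - 1;
      int k = (int)act[p].size();
      int i = (int)(rng.u() * k); if (i >= k) i = k - 1;
      int j = (int)(rng.u() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      int ci = act[p][i], cj = act[p][j];
      int v = nxt++;
      ntime[v] = t; left[v] = ci; right[v] = cj; par[v] = -1;
      par[ci] = v; par[cj] = v;
      // replace child i with v, remove child j (order within pop irrelevant)
      act[p][i] = v;
      act[p][j] = act[p].back();
      act[p].pop_back();
      --total;
    }

    // total branch length and uniform mutation placement
    double L = 0.0;
    for (int v = 0; v < nnodes - 1; ++v) L += ntime[par[v]] - ntime[v];
    double u = rng.u() * L, cum = 0.0;
    int mut = nnodes - 2;
    for (int v = 0; v < nnodes - 1; ++v) {
      cum += ntime[par[v]] - ntime[v];
      if (u <= cum) { mut = v; break; }
    }
    // collect derived leaves under `mut`
    std::vector<int> stack; stack.push_back(mut);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (left[v] < 0) G(v / 2, l) += 1;
      else { stack.push_back(left[v]); stack.push_back(right[v]); }
    }
  }
  return G;
}

// Finite-island coalescent: `npop` sampled demes among `n_demes` total, each
// sampled population occupying its own deme; per-lineage migration rate `m`
// per generation to a uniformly chosen other deme; demes of diploid size
// `deme_size`. One SNP per locus (uniform on branches). Returns derived
// allele counts per sampled population (n_loci x npop).
// [[Rcpp::export]]
IntegerMatrix rg_sim_island_counts(IntegerVector genes_per_pop,
                                   int n_demes, double deme_size,
                                   double m, int n_loci) {
  const int npop = genes_per_pop.size();
  if (n_demes < npop) stop("n_demes must be >= number of sampled populations");
  int n = 0;
  for (int p = 0; p < npop; ++p) n += genes_per_pop[p];
  if (n < 2) stop("need at least 2 genes");
  const int nnodes = 2 * n - 1;

  IntegerMatrix C(n_loci, npop);
  XRng rng;
  std::vector<double> ntime(nnodes);
  std::vector<int> left(nnodes), right(nnodes), par(nnodes);
  std::vector<int> deme(nnodes);       // deme of each *active* node
  std::vector<int> active;             // active node ids
  std::vector<int> kd(n_demes);        // lineage count per deme
  std::vector<int> multi;              // demes with kd >= 2
  std::vector<int> multi_pos(n_demes); // position in `multi`, -1 if absent

  for (int l = 0; l < n_loci; ++l) {
    active.clear(); multi.clear();
    std::fill(kd.begin(), kd.end(), 0);
    std::fill(multi_pos.begin(), multi_pos.end(), -1);
    int g = 0;
    for (int p = 0; p < npop; ++p)
      for (int k = 0; k < genes_per_pop[p]; ++k) {
        ntime[g] = 0.0; left[g] = right[g] = -1; par[g] = -1;
        deme[g] = p; kd[p]++; active.push_back(g); ++g;
      }
    for (int d = 0; d < n_demes; ++d)
      if (kd[d] >= 2) { multi_pos[d] = (int)multi.size(); multi.push_back(d); }

    long s2 = 0;
    for (int d = 0; d < n_demes; ++d) s2 += (long)kd[d] * (kd[d] - 1);
    int nxt = n;
    double t = 0.0;

    auto bump = [&](int d, int delta) {
      s2 -= (long)kd[d] * (kd[d] - 1);
      kd[d] += delta;
      s2 += (long)kd[d] * (kd[d] - 1);
      bool in = multi_pos[d] >= 0, want = kd[d] >= 2;
      if (want && !in) { multi_pos[d] = (int)multi.size(); multi.push_back(d); }
      else if (!want && in) {
        int pos = multi_pos[d], last = multi.back();
        multi[pos] = last; multi_pos[last] = pos;
        multi.pop_back(); multi_pos[d] = -1;
      }
    };

    while (active.size() > 1) {
      double coal = (double)s2 / (4.0 * deme_size);
      double mig = (double)active.size() * m;
      double rate = coal + mig;
      t += rng.e() / rate;
      if (rng.u() * rate < coal) {
        // coalescence: deme proportional to kd*(kd-1)
        double u = rng.u() * (double)s2, cum = 0.0;
        int d = multi.back();
        for (size_t q = 0; q < multi.size(); ++q) {
          int dd = multi[q];
          cum += (double)kd[dd] * (kd[dd] - 1);
          if (u <= cum) { d = dd; break; }
        }
        // pick two active lineages in deme d
        int k = kd[d];
        int i = (int)(rng.u() * k); if (i >= k) i = k - 1;
        int j = (int)(rng.u() * (k - 1)); if (j >= k - 1) j = k - 2;
        if (j >= i) ++j;
        int ai = -1, aj = -1, seen = 0;
        for (size_t q = 0; q < active.size(); ++q) {
          if (deme[active[q]] == d) {
            if (seen == i) ai = (int)q;
            if (seen == j) aj = (int)q;
            ++seen;
          }
        }
        int ci = active[ai], cj = active[aj];
        int v = nxt++;
        ntime[v] = t; left[v] = ci; right[v] = cj; par[v] = -1;
        par[ci] = v; par[cj] = v; deme[v] = d;
        active[ai] = v;
        active[aj] = active.back(); active.pop_back();
        bump(d, -1);
      } else {
        int q = (int)(rng.u() * active.size());
        if (q >= (int)active.size()) q = (int)active.size() - 1;
        int v = active[q], d = deme[v];
        int d2 = (int)(rng.u() * (n_demes - 1));
        if (d2 >= n_demes - 1) d2 = n_demes - 2;
        if (d2 >= d) ++d2;
        bump(d, -1); bump(d2, +1); deme[v] = d2;
      }
    }

    double L = 0.0;
    for (int v = 0; v < nnodes - 1; ++v) L += ntime[par[v]] - ntime[v];
    double u = rng.u() * L, cum = 0.0;
    int mut = nnodes - 2;
    for (int v = 0; v < nnodes - 1; ++v) {
      cum += ntime[par[v]] - ntime[v];
      if (u <= cum) { mut = v; break; }
    }
    // per-pop derived counts; leaf -> pop from input order
    std::vector<int> popof(n);
    g = 0;
    for (int p = 0; p < npop; ++p)
      for (int k = 0; k < genes_per_pop[p]; ++k) popof[g++] = p;
    std::vector<int> stack; stack.push_back(mut);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (left[v] < 0) C(l, popof[v]) += 1;
      else { stack.push_back(left[v]); stack.push_back(right[v]); }
    }
  }
  return C;
}

// ---- FST-decomposition reversible-jump MCMC -------------------------------
// Allele counts a_ij ~ BetaBinomial(n_ij, theta_ij p_i, theta_ij (1-p_i))
// with theta_ij = 1/f_ij - 1 and f_ij = plogis(alpha_i + beta_j); the
// population frequencies are integrated out analytically. alpha_i carries a
// point mass at zero toggled by reversible jump with prior odds for
// neutrality; when included, alpha_i ~ N(0, sd_alpha). beta_j ~ N(-1, 1.8).
// p_i (ancestral frequency) ~ U(0,1), updated on the logit scale.

static inline double bb_ll(int a, int nn, double p, double eta) {
  // log BetaBinomial(a | nn, theta*p, theta*q) without the binomial coefficient
  double f = 1.0 / (1.0 + std::exp(-eta));
  if (f < 1e-12) f = 1e-12;
  if (f > 1.0 - 1e-12) f = 1.0 - 1e-12;
  double th = 1.0 / f - 1.0;
  double ap = th * p, bq = th * (1.0 - p);
  return R::lbeta(a + ap, nn - a + bq) - R::lbeta(ap, bq);
}

// [[Rcpp::export]]
List rg_bayescan_mcmc(IntegerMatrix a, IntegerMatrix nmat,
                      double prior_odds, int n_iter, int thin,
                      int n_pilot, int pilot_len, int burnin,
                      double sd_alpha) {
  const int I = a.nrow(), J = a.ncol();
  std::vector<double> p(I), alpha(I, 0.0), beta(J, -1.0);
  std::vector<int> incl(I, 0);
  for (int i = 0; i < I; ++i) {
    double num = 1.0, den = 2.0;
    for (int j = 0; j < J; ++j) { num += a(i, j); den += nmat(i, j); }
    p[i] = num / den;
  }
  double sp = 0.5, sa = 0.5, sb = 0.3; // proposal sds, pilot-adapted

  std::vector<double> sum_alpha(I, 0.0), sum_incl(I, 0.0), sum_beta(J, 0.0);
  long acc_p = 0, try_p = 0, acc_a = 0, try_a = 0, acc_b = 0, try_b = 0;
  int kept = 0;

  auto row_ll = [&](int i, double pi, double ai) {
    double s = 0.0;
    for (int j = 0; j < J; ++j)
      if (nmat(i, j) > 0) s += bb_ll(a(i, j), nmat(i, j), pi, ai + beta[j]);
    return s;
  };

  auto sweep = [&]() {
    for (int i = 0; i < I; ++i) {
      // p_i on logit scale
      double lo = std::log(p[i] / (1.0 - p[i])) + norm_rand() * sp;
      double pn = 1.0 / (1.0 + std::exp(-lo));
      double lr = row_ll(i, pn, alpha[i]) - row_ll(i, p[i], alpha[i]) +
        std::log(pn * (1.0 - pn)) - std::log(p[i] * (1.0 - p[i]));
      ++try_p;
      if (std::log(unif_rand()) < lr) { p[i] = pn; ++acc_p; }
      // within-model alpha walk
      if (incl[i]) {
        double an = alpha[i] + norm_rand() * sa;
        double lr2 = row_ll(i, p[i], an) - row_ll(i, p[i], alpha[i]) +
          R::dnorm(an, 0.0, sd_alpha, 1) - R::dnorm(alpha[i], 0.0, sd_alpha, 1);
        ++try_a;
        if (std::log(unif_rand()) < lr2) { alpha[i] = an; ++acc_a; }
      }
      // reversible jump (prior as proposal)
      if (incl[i]) {
        double lr3 = row_ll(i, p[i], 0.0) - row_ll(i, p[i], alpha[i]) +
          std::log(prior_odds);
        if (std::log(unif_rand()) < lr3) { incl[i] = 0; alpha[i] = 0.0; }
      } else {
        double an = norm_rand() * sd_alpha;
        double lr3 = row_ll(i, p[i], an) - row_ll(i, p[i], 0.0) -
          std::log(prior_odds);
        if (std::log(unif_rand()) < lr3) { incl[i] = 1; alpha[i] = an; }
      }
    }
    for (int j = 0; j < J; ++j) {
      double bn = beta[j] + norm_rand() * sb;
      double cur = 0.0, prop = 0.0;
      for (int i = 0; i < I; ++i) {
        if (nmat(i, j) == 0) continue;
        cur += bb_ll(a(i, j), nmat(i, j), p[i], alpha[i] + beta[j]);
        prop += bb_ll(a(i, j), nmat(i, j), p[i], alpha[i] + bn);
      }
      double lr = prop - cur +
        R::dnorm(bn, -1.0, 1.8, 1) - R::dnorm(beta[j], -1.0, 1.8, 1);
      ++try_b;
      if (std::log(unif_rand()) < lr) { beta[j] = bn; ++acc_b; }
    }
  };

  for (int pil = 0; pil < n_pilot; ++pil) {
    acc_p = try_p = acc_a = try_a = acc_b = try_b = 0;
    for (int it = 0; it < pilot_len; ++it) sweep();
    auto tune = [](double& s, long acc, long tries) {
      if (tries == 0) return;
      double r = (double)acc / (double)tries;
      if (r < 0.25) s *= 0.8;
      else if (r > 0.45) s *= 1.25;
    };
    tune(sp, acc_p, try_p); tune(sa, acc_a, try_a); tune(sb, acc_b, try_b);
    Rcpp::checkUserInterrupt();
  }
  acc_p = try_p = acc_a = try_a = acc_b = try_b = 0;
  for (int it = 0; it < burnin; ++it) {
    sweep();
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  for (int s = 0; s < n_iter; ++s) {
    for (int it = 0; it < thin; ++it) sweep();
    for (int i = 0; i < I; ++i) { sum_alpha[i] += alpha[i]; sum_incl[i] += incl[i]; }
    for (int j = 0; j < J; ++j) sum_beta[j] += beta[j];
    ++kept;
    if (s % 50 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector post_alpha(I), post_incl(I), post_beta(J);
  for (int i = 0; i < I; ++i) {
    post_alpha[i] = sum_alpha[i] / kept;
    post_incl[i] = sum_incl[i] / kept;
  }
  for (int j = 0; j < J; ++j) post_beta[j] = sum_beta[j] / kept;
  double accp = try_p ? (double)acc_p / try_p : NA_REAL;
  double acca = try_a ? (double)acc_a / try_a : NA_REAL;
  double accb = try_b ? (double)acc_b / try_b : NA_REAL;
  return List::create(_["prob"] = post_incl, _["alpha"] = post_alpha,
                      _["beta"] = post_beta,
                      _["acc"] = NumericVector::create(accp, acca, accb));
}
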