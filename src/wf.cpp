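// Individual-based Wright-Fisher engine for enhancer-runaway models.
//
// Life cycle per generation (all models): diploid selection (parents chosen
// by rejection sampling with acceptance probability equal to fitness),
// meiosis with recombination, mutation, syngamy.  Population size is
// constant.  Two engines are provided: a bi-allelic two-locus engine used
// for fixation trials (enhancer alleles E1/E2, gene alleles A/a), and an
// infinite-allele engine for long-term escalation runs (models 1-4), where
// enhancer/TF alleles carry a log strength z and gene alleles a fitness
// value w accumulated over exponential-effect mutations.
//
// RNG: xoshiro256++ seeded through splitmix64 from (seed, stream), so every
// replicate/trial draws from its own deterministic stream and runs are
// bit-reproducible for a given seed regardless of how work is split.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {  // splitmix64 expansion
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  inline int below(int n) {
    return (int)(((__uint128_t)next() * (uint64_t)n) >> 64);
  }
  // polar Box-Muller, one deviate cached
  bool has_cached = false;
  double cached = 0.0;
  inline double normal() {
    if (has_cached) { has_cached = false; return cached; }
    double u1, u2, r2;
    do {
      u1 = 2.0 * unif() - 1.0;
      u2 = 2.0 * unif() - 1.0;
      r2 = u1 * u1 + u2 * u2;
    } while (r2 >= 1.0 || r2 == 0.0);
    const double f = std::sqrt(-2.0 * std::log(r2) / r2);
    cached = u2 * f;
    has_cached = true;
    return u1 * f;
  }
  // Knuth's method; lambdas here are 2*N*u, at most a few tens
  inline int poisson(double lambda) {
    if (lambda <= 0.0) return 0;
    const double L = std::exp(-lambda);
    int k = 0;
    double prod = 1.0;
    do { ++k; prod *= unif(); } while (prod > L);
    return k - 1;
  }
  inline double exponential(double mean) {
    return -mean * std::log1p(-unif());
  }
};

inline uint64_t mix_seed(double seed, uint64_t stream) {
  uint64_t s = (uint64_t)(int64_t)seed;
  return s ^ (stream * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL);
}

// ---------------------------------------------------------------------------
// Two-allele engine.  One haplotype = one byte: bit 0 = gene allele
// (1 = deleterious a), bit 1 = enhancer allele (1 = focal E2).

struct TwoAlleleTable {
  double w[16];
};

TwoAlleleTable make_table(double e1, double e2, double h, double s) {
  const double beta = -std::log(h) / std::log(2.0);
  TwoAlleleTable t;
  for (int a = 0; a < 4; ++a) {
    for (int b = 0; b < 4; ++b) {
      const int ga = a & 1, gb = b & 1;
      const double ea = (a & 2) ? e2 : e1;
      const double eb = (b & 2) ? e2 : e1;
      double w;
      if (ga == gb) {
        w = ga ? 1.0 - s : 1.0;
      } else {
        const double ed = ga ? ea : eb;  // enhancer cis to the a copy
        const double fa = ed / (ea + eb);
        w = 1.0 - std::pow(fa, beta) * s;
      }
      t.w[a * 4 + b] = w;
    }
  }
  return t;
}

inline int pick_parent(Xoshiro& rng, const std::vector<double>& fit, int N) {
  for (;;) {
    const uint64_t bits = rng.next();
    const int i = (int)(((__uint128_t)(bits >> 32) * (uint64_t)N) >> 32);
    const double u = (double)(bits & 0xffffffffULL) * 0x1.0p-32;
    if (u < fit[i]) return i;
  }
}

// gamete from a two-allele individual: one 64-bit draw supplies the
// haplotype choice and the crossover test
inline uint8_t gamete2(Xoshiro& rng, const uint8_t* ind, double r) {
  const uint64_t bits = rng.next();
  const int hch = (int)(bits & 1);
  uint8_t hap = ind[hch];
  if (r > 0.0) {
    const double u = (double)(bits >> 11) * 0x1.0p-53;
    if (u < r) hap = (uint8_t)((hap & 2) | (ind[1 - hch] & 1));
  }
  return hap;
}

struct TwoAllelePop {
  int N;
  std::vector<uint8_t> pop, nxt;
  std::vector<double> fit;
  explicit TwoAllelePop(int N_) : N(N_), pop(2 * N_, 0), nxt(2 * N_, 0),
                                  fit(N_, 1.0) {}

  void compute_fitness(const TwoAlleleTable& tab) {
    bool any_pos = false;
    for (int i = 0; i < N; ++i) {
      fit[i] = tab.w[pop[2 * i] * 4 + pop[2 * i + 1]];
      if (fit[i] > 0.0) any_pos = true;
    }
    if (!any_pos) stop("extinction error: all fitnesses are zero");
  }

  void generation(const TwoAlleleTable& tab, double r, double u,
                  double p_self, Xoshiro& rng) {
    compute_fitness(tab);
    for (int i = 0; i < N; ++i) {
      const int p1 = pick_parent(rng, fit, N);
      nxt[2 * i] = gamete2(rng, &pop[2 * p1], r);
      const int p2 = (p_self > 0.0 && rng.unif() < p_self)
                         ? p1 : pick_parent(rng, fit, N);
      nxt[2 * i + 1] = gamete2(rng, &pop[2 * p2], r);
    }
    const int nmut = rng.poisson(2.0 * N * u);
    for (int m = 0; m < nmut; ++m) nxt[rng.below(2 * N)] |= 1;
    pop.swap(nxt);
  }

  int count_enh() const {
    int c = 0;
    for (uint8_t hp : pop) c += (hp >> 1) & 1;
    return c;
  }
  int count_del() const {
    int c = 0;
    for (uint8_t hp : pop) c += hp & 1;
    return c;
  }
  double mean_fitness(const TwoAlleleTable& tab) const {
    double tot = 0.0;
    for (int i = 0; i < N; ++i)
      tot += tab.w[pop[2 * i] * 4 + pop[2 * i + 1]];
    return tot / N;
  }

  // gene-locus-only generation, valid while the enhancer locus is
  // monomorphic (all enhancer bits zero): the gamete's gene allele is a fair
  // pick of the parent's two copies whatever r is, so recombination drops
  // out and one RNG draw serves both gametes' haplotype choices
  void generation_burnin(const double wg[3], double u, double p_self,
                         Xoshiro& rng) {
    bool any_pos = false;
    for (int i = 0; i < N; ++i) {
      fit[i] = wg[(pop[2 * i] & 1) + (pop[2 * i + 1] & 1)];
      if (fit[i] > 0.0) any_pos = true;
    }
    if (!any_pos) stop("extinction error: all fitnesses are zero");
    for (int i = 0; i < N; ++i) {
      const int p1 = pick_parent(rng, fit, N);
      const int p2 = (p_self > 0.0 && rng.unif() < p_self)
                         ? p1 : pick_parent(rng, fit, N);
      const uint64_t bits = rng.next();
      nxt[2 * i] = pop[2 * p1 + (bits & 1)];
      nxt[2 * i + 1] = pop[2 * p2 + ((bits >> 1) & 1)];
    }
    const int nmut = rng.poisson(2.0 * N * u);
    for (int m = 0; m < nmut; ++m) nxt[rng.below(2 * N)] |= 1;
    pop.swap(nxt);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_fixation_trials(int n_trials, int N, double s, double h, double u,
                         double r, double ratio, double p_self,
                         int burnin, double max_gen, double seed) {
  const TwoAlleleTable tab = make_table(1.0, ratio, h, s);
  const double wg[3] = {1.0, 1.0 - h * s, 1.0 - s};
  IntegerVector outcome(n_trials), gens(n_trials);
  for (int k = 0; k < n_trials; ++k) {
    Xoshiro rng(mix_seed(seed, (uint64_t)k + 1));
    TwoAllelePop P(N);
    for (int t = 0; t < burnin; ++t) P.generation_burnin(wg, u, p_self, rng);
    // introduce the mutant enhancer on one random chromosome (its gene
    // allele is kept)
    P.pop[rng.below(2 * N)] |= 2;
    double t = 0;
    int cnt = 1;
    while (cnt > 0 && cnt < 2 * N) {
      if (t >= max_gen)
        stop("timeout error: fixation trial exceeded max_gen generations");
      P.generation(tab, r, u, p_self, rng);
      cnt = P.count_enh();
      ++t;
    }
    outcome[k] = (cnt == 2 * N) ? 1 : 0;
    gens[k] = (int)t;
    if ((k & 0x3f) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["outcome"] = outcome, _["generations"] = gens);
}

// [[Rcpp::export]]
List cpp_two_allele_run(int N, double s, double h, double u, double r,
                        double e1, double e2, double p_self, int n_gen,
                        int record_every, double seed, double init_p_enh,
                        double init_p_a, std::string init_mode) {
  Xoshiro rng(mix_seed(seed, 0));
  const TwoAlleleTable tab = make_table(e1, e2, h, s);
  TwoAllelePop P(N);
  if (init_mode == "random") {
    for (int c = 0; c < 2 * N; ++c) {
      uint8_t hp = 0;
      if (rng.unif() < init_p_a) hp |= 1;
      if (rng.unif() < init_p_enh) hp |= 2;
      P.pop[c] = hp;
    }
  } else if (init_mode == "het_gene") {
    for (int i = 0; i < N; ++i) { P.pop[2 * i] = 0; P.pop[2 * i + 1] = 1; }
  } else if (init_mode == "monomorphic") {
    // all wild type, resident enhancer
  } else {
    stop("unknown init_mode");
  }
  const int n_rec = n_gen / record_every + 1;
  NumericMatrix rec(n_rec, 4);
  colnames(rec) = CharacterVector::create("generation", "p_enh", "p_a",
                                          "mean_fitness");
  int row = 0;
  for (int t = 0; t <= n_gen; ++t) {
    if (t % record_every == 0 && row < n_rec) {
      rec(row, 0) = t;
      rec(row, 1) = P.count_enh() / (2.0 * N);
      rec(row, 2) = P.count_del() / (2.0 * N);
      rec(row, 3) = P.mean_fitness(tab);
      ++row;
    }
    if (t < n_gen) P.generation(tab, r, u, p_self, rng);
    if ((t & 0x3ff) == 0) Rcpp::checkUserInterrupt();
  }
  // final genotype counts at the gene locus
  int nAA = 0, nAa = 0, naa = 0;
  for (int i = 0; i < N; ++i) {
    const int k = (P.pop[2 * i] & 1) + (P.pop[2 * i + 1] & 1);
    if (k == 0) ++nAA; else if (k == 1) ++nAa; else ++naa;
  }
  return List::create(_["trajectory"] = rec,
                      _["genotype_counts"] =
                          IntegerVector::create(_["AA"] = nAA, _["Aa"] = nAa,
                                                _["aa"] = naa));
}

// ---------------------------------------------------------------------------
// Infinite-allele escalation engine (models 1-4).
//
// Per chromosome copy: z (log enhancer strength), e = exp(z) cached, and the
// cis gene-allele fitness w.  Model 2 adds a second independent
// enhancer/gene pair; model 3 adds a freely recombining TF locus with log
// strength zt.

namespace {

struct EscPop {
  int N, model;
  std::vector<double> z1, e1c, w1;      // pair 1 (all models)
  std::vector<double> z2, e2c, w2;      // pair 2 (model 2)
  std::vector<double> zt;               // TF locus (model 3)
  std::vector<double> z1n, e1n, w1n, z2n, e2n, w2n, ztn;
  std::vector<double> fit;

  EscPop(int N_, int model_) : N(N_), model(model_) {
    const int M = 2 * N;
    z1.assign(M, 0.0); e1c.assign(M, 1.0); w1.assign(M, 1.0);
    if (model == 2) { z2.assign(M, 0.0); e2c.assign(M, 1.0); w2.assign(M, 1.0); }
    if (model == 3) zt.assign(M, 0.0);
    z1n = z1; e1n = e1c; w1n = w1;
    if (model == 2) { z2n = z2; e2n = e2c; w2n = w2; }
    if (model == 3) ztn = zt;
    fit.assign(N, 1.0);
  }

  static inline double wa_pair(double ea, double wa, double eb, double wb,
                               double beta) {
    if (wa == wb) return wa;
    double whi = wa, wlo = wb, ehi_cis_lo = eb;
    if (wb > wa) { whi = wb; wlo = wa; ehi_cis_lo = ea; }
    const double fa = ehi_cis_lo / (ea + eb);
    return whi - std::pow(fa, beta) * (whi - wlo);
  }

  void compute_fitness(double beta, double I) {
    bool any_pos = false;
    for (int i = 0; i < N; ++i) {
      const int a = 2 * i, b = 2 * i + 1;
      double W = wa_pair(e1c[a], w1[a], e1c[b], w1[b], beta);
      if (model == 2) {
        W *= wa_pair(e2c[a], w2[a], e2c[b], w2[b], beta);
        if (I > 0.0) {
          const double d = (z1[a] + z1[b]) - (z2[a] + z2[b]);
          W *= std::exp(-I * d * d);
        }
      } else if (model == 3 && I > 0.0) {
        const double ssum = z1[a] + z1[b] + zt[a] + zt[b];
        W *= std::exp(-I * ssum * ssum);
      }
      if (W < 0.0) W = 0.0;
      if (W > 1.0) W = 1.0;
      fit[i] = W;
      if (W > 0.0) any_pos = true;
    }
    if (!any_pos) stop("extinction error: all fitnesses are zero");
  }

  // copy one gamete from parent `par` into offspring slot `c`
  inline void gamete(Xoshiro& rng, int par, int c, double r) {
    const int a = 2 * par;
    {
      const uint64_t bits = rng.next();
      const int hch = (int)(bits & 1);
      const int src = a + hch, oth = a + 1 - hch;
      z1n[c] = z1[src]; e1n[c] = e1c[src];
      int gsrc = src;
      if (r > 0.0 && (double)(bits >> 11) * 0x1.0p-53 < r) gsrc = oth;
      w1n[c] = w1[gsrc];
    }
    if (model == 2) {  // second pair segregates independently
      const uint64_t bits = rng.next();
      const int hch = (int)(bits & 1);
      const int src = a + hch, oth = a + 1 - hch;
      z2n[c] = z2[src]; e2n[c] = e2c[src];
      int gsrc = src;
      if (r > 0.0 && (double)(bits >> 11) * 0x1.0p-53 < r) gsrc = oth;
      w2n[c] = w2[gsrc];
    } else if (model == 3) {  // TF locus recombines freely
      ztn[c] = zt[a + (int)(rng.next() & 1)];
    }
  }

  void generation(Xoshiro& rng, double beta, double I, double r, double uA,
                  double uE, double uT, double sigmaE, double s_mean,
                  double p_self, bool replace_fitness) {
    compute_fitness(beta, I);
    for (int i = 0; i < N; ++i) {
      const int p1 = pick_parent(rng, fit, N);
      gamete(rng, p1, 2 * i, r);
      const int p2 = (p_self > 0.0 && rng.unif() < p_self)
                         ? p1 : pick_parent(rng, fit, N);
      gamete(rng, p2, 2 * i + 1, r);
    }
    const int M = 2 * N;
    const int n_loci_pairs = (model == 2) ? 2 : 1;
    for (int l = 0; l < n_loci_pairs; ++l) {
      std::vector<double>* w = (l == 0) ? &w1n : &w2n;
      const int nmA = rng.poisson((double)M * uA);
      for (int m = 0; m < nmA; ++m) {
        double si;
        do { si = rng.exponential(s_mean); } while (si >= 1.0);
        const int c = rng.below(M);
        (*w)[c] = replace_fitness ? 1.0 - si : (*w)[c] * (1.0 - si);
      }
      std::vector<double>* zz = (l == 0) ? &z1n : &z2n;
      std::vector<double>* ee = (l == 0) ? &e1n : &e2n;
      const int nmE = rng.poisson((double)M * uE);
      for (int m = 0; m < nmE; ++m) {
        const int c = rng.below(M);
        (*zz)[c] += sigmaE * rng.normal();
        (*ee)[c] = std::exp((*zz)[c]);
      }
    }
    if (model == 3) {
      const int nmT = rng.poisson((double)M * uT);
      for (int m = 0; m < nmT; ++m) ztn[rng.below(M)] += sigmaE * rng.normal();
    }
    z1.swap(z1n); e1c.swap(e1n); w1.swap(w1n);
    if (model == 2) { z2.swap(z2n); e2c.swap(e2n); w2.swap(w2n); }
    if (model == 3) zt.swap(ztn);
  }

  double mean_z1() const {
    double tot = 0.0;
    for (double v : z1) tot += v;
    return tot / z1.size();
  }
  double mean_z2() const {
    const std::vector<double>& v = (model == 2) ? z2 : zt;
    if (v.empty()) return NA_REAL;
    double tot = 0.0;
    for (double x : v) tot += x;
    return tot / v.size();
  }
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_escalation(int model, int N, double s_mean, double h,
                             double uA, double uE, double uT, double r,
                             double sigmaE, double I, double p_self,
                             int n_gen, int record_every, double seed,
                             bool replace_fitness) {
  if (model < 1 || model > 4) stop("model must be 1, 2, 3 or 4");
  const double beta = -std::log(h) / std::log(2.0);
  Xoshiro rng(mix_seed(seed, 0));
  const int layout = (model == 4) ? 1 : model;
  EscPop P(N, layout);
  const int n_rec = n_gen / record_every + 1;
  NumericMatrix rec(n_rec, 3);
  colnames(rec) = CharacterVector::create("generation", "mean_z", "mean_z2");
  int row = 0;
  for (int t = 0; t <= n_gen; ++t) {
    if (t % record_every == 0 && row < n_rec) {
      rec(row, 0) = t;
      rec(row, 1) = P.mean_z1();
      rec(row, 2) = P.mean_z2();
      ++row;
    }
    if (t < n_gen)
      P.generation(rng, beta, I, r, uA, uE, uT, sigmaE, s_mean, p_self,
                   replace_fitness);
    if ((t & 0xff) == 0) Rcpp::checkUserInterrupt();
  }
  return rec;
}

// [[Rcpp::export]]
NumericVector cpp_rng_draws(std::string kind, int n, double par1,
                            double seed) {
  Xoshiro rng(mix_seed(seed, 0));
  NumericVector out(n);
  if (kind == "normal") {
    for (int i = 0; i < n; ++i) out[i] = par1 * rng.normal();
  } else if (kind == "poisson") {
    for (int i = 0; i < n; ++i) out[i] = rng.poisson(par1);
  } else if (kind == "exponential") {
    for (int i = 0; i < n; ++i) out[i] = rng.exponential(par1);
  } else if (kind == "exp_trunc1") {
    for (int i = 0; i < n; ++i) {
      double si;
      do { si = rng.exponential(par1); } while (si >= 1.0);
      out[i] = si;
    }
  } else if (kind == "unif") {
    for (int i = 0; i < n; ++i) out[i] = rng.unif();
  } else {
    stop("unknown kind");
  }
  return out;
}
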