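// Individual-based stepping-stone engine.
//
// Haplotypes are bit-packed, 64 loci per word. Selected loci occupy the
// first Wsel words (padded to a word boundary), neutral loci the following
// words, so per-class masks are never needed: padding bits are never set.
// Fitness is multiplicative over selected loci and computed by iterating
// the set bits of (hom = a & b) and (het = a ^ b), summing per-locus log
// factors. Recombination masks are drawn one 64-bit word at a time, giving
// every locus an independent fair coin under free recombination.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Deme {
  std::vector<uint64_t> hap;  // n * 2W words
  std::vector<double> fit;    // n
  int n = 0;
  bool habitable = false;
};

struct Engine {
  int nrow, ncol, nd;
  int Lsel, Lneu, L;
  int Wsel, Wneu, W;          // words per haplotype
  std::vector<double> lhet, lhom;  // per selected locus, log factors
  std::vector<int> benef;          // selected-locus class flag (1 = beneficial)
  double U, uneu, m, R, K;
  bool hard;
  bool hardLinearR;   // R_eff = w*R instead of log R_eff = w*log R
  bool freerec;
  bool selfing;
  double wref = 1.0;
  long clampCount = 0;
  std::vector<Deme> demes;
  std::mt19937_64 rng;

  int demeIndex(int row, int col) const { return col * nrow + row; }
};

const double FITNESS_FLOOR = 1e-6;

inline double logistic(double N, double R, double K) {
  return N * R / (1.0 + N * (R - 1.0) / K);
}

Engine* eng(SEXP xp) {
  Rcpp::XPtr<Engine> p(xp);
  return p.get();
}

double indFitness(const Engine& E, const uint64_t* h) {
  const uint64_t* a = h;
  const uint64_t* b = h + E.W;
  double sum = 0.0;
  for (int w = 0; w < E.Wsel; ++w) {
    uint64_t hom = a[w] & b[w];
    uint64_t het = a[w] ^ b[w];
    while (hom) {
      int t = __builtin_ctzll(hom);
      sum += E.lhom[w * 64 + t];
      hom &= hom - 1;
    }
    while (het) {
      int t = __builtin_ctzll(het);
      sum += E.lhet[w * 64 + t];
      het &= het - 1;
    }
  }
  return std::exp(sum);
}

void refreshFitness(Engine& E) {
  for (auto& d : E.demes) {
    d.fit.resize(d.n);
    for (int i = 0; i < d.n; ++i)
      d.fit[i] = indFitness(E, d.hap.data() + (size_t)i * 2 * E.W);
  }
}

void migrationStep(Engine& E) {
  if (E.m <= 0) return;
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const int ndir = (E.nrow > 1) ? 4 : 2;
  std::uniform_int_distribution<int> dir(0, ndir - 1);
  // emigrants buffered per destination deme, appended after all removals
  std::vector<std::vector<uint64_t>> inHap(E.nd);
  std::vector<std::vector<double>> inFit(E.nd);
  const int stride = 2 * E.W;
  for (int col = 0; col < E.ncol; ++col) {
    for (int row = 0; row < E.nrow; ++row) {
      Deme& d = E.demes[E.demeIndex(row, col)];
      for (int i = d.n - 1; i >= 0; --i) {
        if (unif(E.rng) >= E.m) continue;
        int dr = row, dc = col;
        switch (dir(E.rng)) {
          case 0: dc = col - 1; break;
          case 1: dc = col + 1; break;
          case 2: dr = row - 1; break;
          case 3: dr = row + 1; break;
        }
        // off-grid or uninhabitable target: move cancelled (reflective
        // boundary / burn-in confinement)
        if (dc < 0 || dc >= E.ncol || dr < 0 || dr >= E.nrow) continue;
        int dd = E.demeIndex(dr, dc);
        if (!E.demes[dd].habitable) continue;
        uint64_t* src = d.hap.data() + (size_t)i * stride;
        inHap[dd].insert(inHap[dd].end(), src, src + stride);
        inFit[dd].push_back(d.fit[i]);
        // swap-remove individual i
        int last = d.n - 1;
        if (i != last) {
          std::copy(d.hap.data() + (size_t)last * stride,
                    d.hap.data() + (size_t)(last + 1) * stride, src);
          d.fit[i] = d.fit[last];
        }
        d.hap.resize((size_t)last * stride);
        d.fit.resize(last);
        d.n = last;
      }
    }
  }
  for (int dd = 0; dd < E.nd; ++dd) {
    if (inFit[dd].empty()) continue;
    Deme& d = E.demes[dd];
    d.hap.insert(d.hap.end(), inHap[dd].begin(), inHap[dd].end());
    d.fit.insert(d.fit.end(), inFit[dd].begin(), inFit[dd].end());
    d.n += (int)inFit[dd].size();
  }
}

void makeGameteInto(Engine& E, const uint64_t* parent, uint64_t* out) {
  const uint64_t* a = parent;
  const uint64_t* b = parent + E.W;
  if (E.freerec) {
    for (int w = 0; w < E.W; ++w) {
      uint64_t msk = E.rng();
      out[w] = (a[w] & msk) | (b[w] & ~msk);
    }
  } else {
    const uint64_t* src = (E.rng() & 1ull) ? a : b;
    std::copy(src, src + E.W, out);
  }
}

void reproductionStep(Engine& E) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const int stride = 2 * E.W;
  for (auto& d : E.demes) {
    if (d.n == 0) continue;
    if (!d.habitable) { d.n = 0; d.hap.clear(); d.fit.clear(); continue; }
    double tot = 0.0;
    for (double f : d.fit) tot += f;
    double wbar = tot / d.n;
    double Reff = E.R, Keff = E.K;
    if (E.hard) {
      double wrel = wbar / E.wref;
      if (wrel <= 0) { d.n = 0; d.hap.clear(); d.fit.clear(); continue; }
      Keff = E.K * wrel;
      Reff = E.hardLinearR ? wrel * E.R : std::exp(wrel * std::log(E.R));
    }
    int nOff = 0;
    if (Keff > 0 && Reff > 1) {
      double lambda = logistic((double)d.n, Reff, Keff);
      if (lambda > 0) {
        std::poisson_distribution<int> pois(lambda);
        nOff = pois(E.rng);
      }
    }
    // without selfing a lone individual cannot reproduce
    if (!E.selfing && d.n == 1) nOff = 0;
    if (nOff == 0) { d.n = 0; d.hap.clear(); d.fit.clear(); continue; }
    // cumulative fitness for fitness-proportional parent sampling
    std::vector<double> cum(d.n);
    double acc = 0.0;
    for (int i = 0; i < d.n; ++i) { acc += d.fit[i]; cum[i] = acc; }
    std::vector<uint64_t> newHap((size_t)nOff * stride);
    for (int o = 0; o < nOff; ++o) {
      int first = -1;
      for (int par = 0; par < 2; ++par) {
        int idx;
        do {
          double u = unif(E.rng) * acc;
          idx = (int)(std::upper_bound(cum.begin(), cum.end(), u) -
                      cum.begin());
          if (idx >= d.n) idx = d.n - 1;
        } while (!E.selfing && par == 1 && idx == first);
        if (par == 0) first = idx;
        makeGameteInto(E, d.hap.data() + (size_t)idx * stride,
                       newHap.data() + (size_t)o * stride + (size_t)par * E.W);
      }
    }
    d.hap.swap(newHap);
    d.n = nOff;
    d.fit.assign(nOff, 1.0);  // refreshed after mutation
  }
}

void mutationStep(Engine& E, bool suppressBeneficial) {
  std::uniform_int_distribution<int> pickSel(0, E.Lsel - 1);
  const int stride = 2 * E.W;
  for (auto& d : E.demes) {
    for (int i = 0; i < d.n; ++i) {
      uint64_t* h = d.hap.data() + (size_t)i * stride;
      if (E.U > 0 && E.Lsel > 0) {
        std::poisson_distribution<int> pois(E.U);
        int k = pois(E.rng);
        for (int e = 0; e < k; ++e) {
          int locus = pickSel(E.rng);
          if (suppressBeneficial && E.benef[locus]) continue;
          int hapIdx = (int)(E.rng() & 1ull);
          // setting an already-set bit is a silent no-op: no back-mutation
          h[hapIdx * E.W + locus / 64] |= (1ull << (locus % 64));
        }
      }
      if (E.Lneu > 0 && E.uneu > 0) {
        std::poisson_distribution<int> poisN(2.0 * E.Lneu * E.uneu);
        std::uniform_int_distribution<int> pickNeu(0, E.Lneu - 1);
        int k = poisN(E.rng);
        for (int e = 0; e < k; ++e) {
          int j = pickNeu(E.rng);
          int hapIdx = (int)(E.rng() & 1ull);
          h[hapIdx * E.W + E.Wsel + j / 64] |= (1ull << (j % 64));
        }
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
SEXP eng_create(int nrow, int ncol, NumericVector s, NumericVector h,
                int nNeutral, double U, double neutralRate, double m,
                double R, double K, bool hard, bool hardLinearR,
                bool freeRecombination, bool allowSelfing, double seed) {
  if (s.size() != h.size()) stop("s and h must have equal length");
  Engine* E = new Engine();
  E->nrow = nrow; E->ncol = ncol; E->nd = nrow * ncol;
  E->Lsel = s.size(); E->Lneu = nNeutral;
  E->L = E->Lsel + E->Lneu;
  E->Wsel = (E->Lsel + 63) / 64;
  E->Wneu = (E->Lneu + 63) / 64;
  E->W = E->Wsel + E->Wneu;
  E->lhet.assign((size_t)E->Wsel * 64, 0.0);
  E->lhom.assign((size_t)E->Wsel * 64, 0.0);
  E->benef.assign(E->Lsel, 0);
  for (int l = 0; l < E->Lsel; ++l) {
    double fh = 1.0 + h[l] * s[l];
    double fm = 1.0 + s[l];
    if (fh < FITNESS_FLOOR) { fh = FITNESS_FLOOR; E->clampCount++; }
    if (fm < FITNESS_FLOOR) { fm = FITNESS_FLOOR; E->clampCount++; }
    E->lhet[l] = std::log(fh);
    E->lhom[l] = std::log(fm);
    E->benef[l] = (s[l] > 0) ? 1 : 0;
  }
  E->U = U; E->uneu = neutralRate; E->m = m; E->R = R; E->K = K;
  E->hard = hard; E->hardLinearR = hardLinearR;
  E->freerec = freeRecombination;
  E->selfing = allowSelfing;
  E->rng.seed((uint64_t)seed);
  E->demes.assign(E->nd, Deme());
  Rcpp::XPtr<Engine> xp(E, true);
  return xp;
}

// [[Rcpp::export]]
void eng_seed_demes(SEXP xp, IntegerVector demes0, int nPerDeme) {
  Engine& E = *eng(xp);
  for (int d0 : demes0) {
    if (d0 < 0 || d0 >= E.nd) stop("deme index out of range");
    Deme& d = E.demes[d0];
    d.n = nPerDeme;
    d.hap.assign((size_t)nPerDeme * 2 * E.W, 0ull);
    d.fit.assign(nPerDeme, 1.0);
    d.habitable = true;
  }
}

// [[Rcpp::export]]
void eng_set_habitable(SEXP xp, LogicalVector mask) {
  Engine& E = *eng(xp);
  if (mask.size() != E.nd) stop("mask length must equal number of demes");
  for (int d0 = 0; d0 < E.nd; ++d0) {
    E.demes[d0].habitable = mask[d0];
    if (!mask[d0] && E.demes[d0].n > 0) {
      E.demes[d0].n = 0;
      E.demes[d0].hap.clear();
      E.demes[d0].fit.clear();
    }
  }
}

// [[Rcpp::export]]
LogicalVector eng_habitable(SEXP xp) {
  Engine& E = *eng(xp);
  LogicalVector out(E.nd);
  for (int d0 = 0; d0 < E.nd; ++d0) out[d0] = E.demes[d0].habitable;
  return out;
}

// [[Rcpp::export]]
double eng_step(SEXP xp, bool suppressBeneficial, bool doMigration,
                bool doReproduction, bool doMutation) {
  Engine& E = *eng(xp);
  if (doMigration) migrationStep(E);
  if (doReproduction) reproductionStep(E);
  if (doMutation) mutationStep(E, suppressBeneficial);
  if (doReproduction || doMutation) refreshFitness(E);
  double tot = 0;
  for (const auto& d : E.demes) tot += d.n;
  return tot;
}

// [[Rcpp::export]]
IntegerVector eng_census(SEXP xp) {
  Engine& E = *eng(xp);
  IntegerVector out(E.nd);
  for (int d0 = 0; d0 < E.nd; ++d0) out[d0] = E.demes[d0].n;
  return out;
}

// [[Rcpp::export]]
double eng_total_census(SEXP xp) {
  Engine& E = *eng(xp);
  double tot = 0;
  for (const auto& d : E.demes) tot += d.n;
  return tot;
}

// [[Rcpp::export]]
NumericVector eng_deme_fitness(SEXP xp, int deme0) {
  Engine& E = *eng(xp);
  if (deme0 < 0 || deme0 >= E.nd) stop("deme index out of range");
  const Deme& d = E.demes[deme0];
  return NumericVector(d.fit.begin(), d.fit.end());
}

// [[Rcpp::export]]
double eng_mean_fitness_all(SEXP xp) {
  Engine& E = *eng(xp);
  double tot = 0; long n = 0;
  for (const auto& d : E.demes) {
    for (double f : d.fit) tot += f;
    n += d.n;
  }
  if (n == 0) return NA_REAL;
  return tot / n;
}

// [[Rcpp::export]]
NumericVector eng_freqs(SEXP xp, IntegerVector demes0) {
  Engine& E = *eng(xp);
  std::vector<long> counts(E.L, 0);
  long n2 = 0;
  for (int d0 : demes0) {
    if (d0 < 0 || d0 >= E.nd) stop("deme index out of range");
    const Deme& d = E.demes[d0];
    n2 += 2L * d.n;
    for (int i = 0; i < 2 * d.n; ++i) {
      const uint64_t* hp = d.hap.data() + (size_t)i * E.W;
      for (int w = 0; w < E.W; ++w) {
        uint64_t x = hp[w];
        while (x) {
          int t = __builtin_ctzll(x);
          int pos = w * 64 + t;
          int locus = (w < E.Wsel) ? pos : E.Lsel + (pos - E.Wsel * 64);
          counts[locus]++;
          x &= x - 1;
        }
      }
    }
  }
  NumericVector out(E.L);
  if (n2 == 0) { out.fill(NA_REAL); return out; }
  for (int l = 0; l < E.L; ++l) out[l] = (double)counts[l] / n2;
  return out;
}

// [[Rcpp::export]]
IntegerVector eng_get_genotypes(SEXP xp, int deme0) {
  Engine& E = *eng(xp);
  if (deme0 < 0 || deme0 >= E.nd) stop("deme index out of range");
  const Deme& d = E.demes[deme0];
  IntegerVector out((R_xlen_t)d.n * 2 * E.L);
  out.attr("dim") = IntegerVector::create(d.n, 2, E.L);
  for (int i = 0; i < d.n; ++i) {
    for (int hp = 0; hp < 2; ++hp) {
      const uint64_t* hv = d.hap.data() + ((size_t)i * 2 + hp) * E.W;
      for (int l = 0; l < E.L; ++l) {
        int w = (l < E.Lsel) ? l / 64 : E.Wsel + (l - E.Lsel) / 64;
        int b = (l < E.Lsel) ? l % 64 : (l - E.Lsel) % 64;
        out[(R_xlen_t)i + (R_xlen_t)d.n * (hp + 2 * (R_xlen_t)l)] =
          (hv[w] >> b) & 1ull;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
void eng_set_deme(SEXP xp, int deme0, IntegerVector arr) {
  Engine& E = *eng(xp);
  if (deme0 < 0 || deme0 >= E.nd) stop("deme index out of range");
  IntegerVector dim = arr.attr("dim");
  if (dim.size() != 3 || dim[1] != 2 || dim[2] != E.L)
    stop("genotype array must be n x 2 x L");
  int n = dim[0];
  Deme& d = E.demes[deme0];
  d.n = n;
  d.habitable = true;
  d.hap.assign((size_t)n * 2 * E.W, 0ull);
  for (int i = 0; i < n; ++i) {
    for (int hp = 0; hp < 2; ++hp) {
      uint64_t* hv = d.hap.data() + ((size_t)i * 2 + hp) * E.W;
      for (int l = 0; l < E.L; ++l) {
        int val = arr[(R_xlen_t)i + (R_xlen_t)n * (hp + 2 * (R_xlen_t)l)];
        if (val != 0) {
          int w = (l < E.Lsel) ? l / 64 : E.Wsel + (l - E.Lsel) / 64;
          int b = (l < E.Lsel) ? l % 64 : (l - E.Lsel) % 64;
          hv[w] |= (1ull << b);
        }
      }
    }
  }
  d.fit.resize(n);
  for (int i = 0; i < n; ++i)
    d.fit[i] = indFitness(E, d.hap.data() + (size_t)i * 2 * E.W);
}

// [[Rcpp::export]]
void eng_set_wref(SEXP xp, double w) {
  if (w <= 0) stop("reference fitness must be positive");
  eng(xp)->wref = w;
}

// [[Rcpp::export]]
double eng_get_wref(SEXP xp) { return eng(xp)->wref; }

// [[Rcpp::export]]
double eng_clamp_count(SEXP xp) { return (double)eng(xp)->clampCount; }

// [[Rcpp::export]]
SEXP eng_clone(SEXP xp, double newSeed) {
  Engine* E = new Engine(*eng(xp));
  E->rng.seed((uint64_t)newSeed);
  Rcpp::XPtr<Engine> out(E, true);
  return out;
}

// [[Rcpp::export]]
void eng_reseed(SEXP xp, double newSeed) {
  eng(xp)->rng.seed((uint64_t)newSeed);
}
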