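// Individual-based forward simulator of Ne haploid binary genomes on a
// single linear chromosome: stochastic-acceptance mate choice under Gaussian
// stabilizing fitness, binomially placed crossovers, population-level
// Poisson mutation, and pheno-time snapshotting.
#include <Rcpp.h>
using namespace Rcpp;

// fitness of an individual carrying z copies of A: exp(-s/2 (gamma z - zopt)^2)
static inline double fitness_of(int z, double gamma, double sigma, double zopt) {
  double dz = gamma * (double)z - zopt;
  return std::exp(-0.5 * sigma * dz * dz);
}

// Fitness-proportional choice by stochastic acceptance: draw a uniform
// index, accept with probability W / Wmax.
static int choose_parent(const std::vector<double>& W, double Wmax) {
  int n = (int)W.size();
  for (int tries = 0; tries < 100000000; ++tries) {
    int i = (int)(unif_rand() * n);
    if (i == n) i = n - 1;
    if (unif_rand() < W[i] / Wmax) return i;
  }
  return -1; // unreachable unless all fitnesses are ~0 relative to Wmax
}

// [[Rcpp::export(name = ".ib_choose_cpp")]]
int ib_choose_cpp(NumericVector fitness) {
  int n = fitness.size();
  double Wmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (fitness[i] < 0) stop("fitness values must be nonnegative");
    if (fitness[i] > Wmax) Wmax = fitness[i];
  }
  if (Wmax <= 0) stop("all fitness values are zero");
  std::vector<double> W(fitness.begin(), fitness.end());
  return choose_parent(W, Wmax) + 1; // 1-based
}

// Recombine two genomes: crossover count ~ Binomial(L-1, r), crossover
// intervals drawn uniformly without replacement, segments alternate
// starting from a fair-coin parent.
static void recombine_into(const int* a, const int* b, int L, double r,
                           int* child, std::vector<int>& scratch) {
  int ncross = (L > 1 && r > 0) ? (int)R::rbinom(L - 1, r) : 0;
  // crossover indicator per interval (between locus j and j+1), via
  // partial Fisher-Yates over interval indices
  scratch.assign(L, 0); // scratch[j] == 1 -> crossover in interval j (1..L-1)
  if (ncross > 0) {
    std::vector<int> idx(L - 1);
    for (int j = 0; j < L - 1; ++j) idx[j] = j + 1;
    for (int k = 0; k < ncross; ++k) {
      int pick = k + (int)(unif_rand() * (L - 1 - k));
      if (pick > L - 2) pick = L - 2;
      std::swap(idx[k], idx[pick]);
      scratch[idx[k]] = 1;
    }
  }
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  for (int j = 0; j < L; ++j) {
    if (j > 0 && scratch[j]) cur = 1 - cur;
    child[j] = cur == 0 ? a[j] : b[j];
  }
}

// [[Rcpp::export(name = ".ib_recombine_cpp")]]
IntegerVector ib_recombine_cpp(IntegerVector a, IntegerVector b, double r) {
  if (a.size() != b.size()) stop("parent genomes must have equal length");
  if (r < 0 || r > 0.5) stop("'r' must be in [0, 0.5]");
  int L = a.size();
  IntegerVector child(L);
  std::vector<int> scratch;
  recombine_into(&a[0], &b[0], L, r, &child[0], scratch);
  return child;
}

// Population-level bidirectional mutation: M ~ Poisson(Ne*L*mu) allele
// toggles at uniformly chosen (individual, locus) cells.
// [[Rcpp::export(name = ".ib_mutate_cpp")]]
IntegerMatrix ib_mutate_cpp(IntegerMatrix pop, double mu) {
  if (mu < 0 || mu > 1) stop("'mu' must be in [0, 1]");
  IntegerMatrix out = clone(pop);
  int Ne = out.nrow(), L = out.ncol();
  int M = (int)R::rpois((double)Ne * L * mu);
  for (int m = 0; m < M; ++m) {
    int i = (int)(unif_rand() * Ne); if (i == Ne) i = Ne - 1;
    int j = (int)(unif_rand() * L);  if (j == L) j = L - 1;
    out(i, j) = 1 - out(i, j);
  }
  return out;
}

struct IbPop {
  int Ne, L;
  std::vector<int> g;      // Ne x L row-major
  std::vector<int> zsum;   // per-individual allele count
  int* row(int i) { return &g[(size_t)i * L]; }
};

static void ib_step(IbPop& pop, IbPop& next, double gamma, double sigma,
                    double zopt, double r, double mu,
                    std::vector<double>& W, std::vector<int>& scratch) {
  int Ne = pop.Ne, L = pop.L;
  double Wmax = 0.0;
  for (int i = 0; i < Ne; ++i) {
    W[i] = fitness_of(pop.zsum[i], gamma, sigma, zopt);
    if (W[i] > Wmax) Wmax = W[i];
  }
  if (Wmax <= 0) stop("population fitness underflowed to zero");
  for (int i = 0; i < Ne; ++i) {
    int pa = choose_parent(W, Wmax);
    int pb = choose_parent(W, Wmax);
    recombine_into(pop.row(pa), pop.row(pb), L, r, next.row(i), scratch);
  }
  // bidirectional mutation over the whole offspring population
  if (mu > 0) {
    int M = (int)R::rpois((double)Ne * L * mu);
    for (int m = 0; m < M; ++m) {
      int i = (int)(unif_rand() * Ne); if (i == Ne) i = Ne - 1;
      int j = (int)(unif_rand() * L);  if (j == L) j = L - 1;
      int* rowp = next.row(i);
      rowp[j] = 1 - rowp[j];
    }
  }
  for (int i = 0; i < Ne; ++i) {
    int s = 0;
    const int* rowp = next.row(i);
    for (int j = 0; j < L; ++j) s += rowp[j];
    next.zsum[i] = s;
  }
  std::swap(pop.g, next.g);
  std::swap(pop.zsum, next.zsum);
}

// One complete life cycle (selection, recombination, mutation) on an
// explicit genome matrix; used by the R-level ib_generation().
// [[Rcpp::export(name = ".ib_generation_cpp")]]
IntegerMatrix ib_generation_cpp(IntegerMatrix genomes, double gamma,
                                double sigma, double zopt, double r,
                                double mu) {
  int Ne = genomes.nrow(), L = genomes.ncol();
  IbPop pop, next;
  pop.Ne = next.Ne = Ne; pop.L = next.L = L;
  pop.g.resize((size_t)Ne * L); next.g.resize((size_t)Ne * L);
  pop.zsum.resize(Ne); next.zsum.resize(Ne);
  for (int i = 0; i < Ne; ++i) {
    int s = 0;
    for (int j = 0; j < L; ++j) { pop.row(i)[j] = genomes(i, j); s += genomes(i, j); }
    pop.zsum[i] = s;
  }
  std::vector<double> W(Ne);
  std::vector<int> scratch;
  ib_step(pop, next, gamma, sigma, zopt, r, mu, W, scratch);
  IntegerMatrix out(Ne, L);
  for (int i = 0; i < Ne; ++i)
    for (int j = 0; j < L; ++j) out(i, j) = pop.row(i)[j];
  return out;
}

// Full single-replicate run: initialization, burn-in under the ancestral
// optimum, environmental change, adaptation with snapshots at the first
// generation the mean allele count reaches (L - d) + cz.
// a_loci: 0-based indices of the d loci initialized with the a allele.
// [[Rcpp::export(name = ".ib_run_cpp")]]
List ib_run_cpp(int Ne, int L, double gamma, double mu, IntegerVector a_loci,
                double sigma_before, double sigma_after,
                double zopt0, double zopt_new,
                double r, int equilibration, NumericVector cz_values,
                int max_generations, bool sgv) {
  IbPop pop, next;
  pop.Ne = next.Ne = Ne; pop.L = next.L = L;
  pop.g.assign((size_t)Ne * L, 1); next.g.resize((size_t)Ne * L);
  pop.zsum.resize(Ne); next.zsum.resize(Ne);
  for (int k = 0; k < a_loci.size(); ++k)
    for (int i = 0; i < Ne; ++i) pop.row(i)[a_loci[k]] = 0;
  for (int i = 0; i < Ne; ++i) {
    int s = 0;
    for (int j = 0; j < L; ++j) s += pop.row(i)[j];
    pop.zsum[i] = s;
  }
  std::vector<double> W(Ne);
  std::vector<int> scratch;

  if (sgv) {
    for (int t = 0; t < equilibration; ++t) {
      ib_step(pop, next, gamma, sigma_before, zopt0, r, mu, W, scratch);
      if (t % 1024 == 0) Rcpp::checkUserInterrupt();
    }
  }

  int ncz = cz_values.size();
  NumericMatrix freqs(ncz, L);
  std::fill(freqs.begin(), freqs.end(), NA_REAL);
  IntegerVector generation(ncz, NA_INTEGER);
  LogicalVector completed(ncz, false);
  NumericVector vg(ncz, NA_REAL), vg_le(ncz, NA_REAL);
  NumericMatrix sgv_freqs(1, L);

  // frequencies and trait moments at t = 0 (the SGV snapshot)
  std::vector<double> p(L);
  auto col_freqs = [&](std::vector<double>& out) {
    for (int j = 0; j < L; ++j) out[j] = 0.0;
    for (int i = 0; i < Ne; ++i) {
      const int* rowp = pop.row(i);
      for (int j = 0; j < L; ++j) out[j] += rowp[j];
    }
    for (int j = 0; j < L; ++j) out[j] /= Ne;
  };
  col_freqs(p);
  for (int j = 0; j < L; ++j) sgv_freqs(0, j) = p[j];

  int nxt = 0;
  int t = 0;
  while (nxt < ncz && t <= max_generations) {
    // crossing check at the current (integer) generation
    double zbar = 0.0;
    for (int i = 0; i < Ne; ++i) zbar += pop.zsum[i];
    zbar /= Ne; // mean allele count; trait mean is gamma * zbar
    while (nxt < ncz && zbar >= (zopt0 / gamma) + cz_values[nxt]) {
      col_freqs(p);
      for (int j = 0; j < L; ++j) freqs(nxt, j) = p[j];
      generation[nxt] = t;
      completed[nxt] = true;
      // genetic variance of individual trait values (population moments,
      // units gamma^2) and genic (LE) variance sum p(1-p)
      double m1 = 0.0, m2 = 0.0;
      for (int i = 0; i < Ne; ++i) {
        m1 += pop.zsum[i];
        m2 += (double)pop.zsum[i] * pop.zsum[i];
      }
      m1 /= Ne; m2 /= Ne;
      vg[nxt] = m2 - m1 * m1;
      double vle = 0.0;
      for (int j = 0; j < L; ++j) vle += p[j] * (1.0 - p[j]);
      vg_le[nxt] = vle;
      ++nxt;
    }
    if (nxt >= ncz || t == max_generations) break;
    ib_step(pop, next, gamma, sigma_after, zopt_new, r, mu, W, scratch);
    ++t;
    if (t % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["freqs"] = freqs, _["generation"] = generation,
                      _["completed"] = completed, _["vg"] = vg,
                      _["vg_le"] = vg_le, _["sgv"] = sgv_freqs);
}
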