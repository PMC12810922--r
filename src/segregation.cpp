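// Agent-based nucleoid segregation core.
//
// A cell is an ordered string of N alleles (0 = reference mtDNA, 1 = the
// competing "other" variant).  At division the string is cut at nspl
// distinct internal boundaries and the nspl+1 segments are distributed
// alternately between mother and daughter (a fair coin decides which side
// receives the first segment), reflecting the roughly even partitioning of
// mitochondrial material between mother and bud.  Both cells then
// replenish back to N copies in balanced rounds: a uniformly chosen subset
// of residents -- every resident, when fewer copies are missing than
// residents present -- is duplicated once, mirroring the roughly
// once-per-cell-cycle replication of mtDNA; copies enter the string at
// uniform positions (see replenish below).  Mother and daughter are
// exchangeable and replenishment is unbiased, so expected heteroplasmy is
// conserved at every division.
// All randomness comes from R's RNG so set.seed() makes every run
// reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

typedef std::vector<signed char> Alleles;

static inline int runif_int(int n) {
  // uniform integer in [0, n)
  int j = (int)(unif_rand() * n);
  return j >= n ? n - 1 : j;
}

// balanced replenishment: duplicate a uniformly chosen subset of
// residents (all of them while more copies are missing than residents
// exist) until the cell holds N nucleoids.  Each copy is inserted at a
// uniformly chosen position in the string: between divisions the fused
// network's fusion/fission dynamics reorder nucleoids, so a fresh copy's
// position is not tied to its template's.
static void replenish(Alleles &v, int N) {
  while ((int)v.size() < N) {
    const int m = (int)v.size();
    const int need = N - m;
    const int k = need < m ? need : m;
    std::vector<int> idx(m);
    for (int i = 0; i < m; ++i) idx[i] = i;
    for (int i = 0; i < k; ++i) {  // partial Fisher-Yates draw
      int j = i + runif_int(m - i);
      std::swap(idx[i], idx[j]);
    }
    std::vector<signed char> copies(k);
    for (int i = 0; i < k; ++i) copies[i] = v[idx[i]];
    for (int i = 0; i < k; ++i) {
      int pos = runif_int((int)v.size() + 1);
      v.insert(v.begin() + pos, copies[i]);
    }
  }
}

// cut `parent` at nspl distinct internal boundaries; segments go
// alternately to mother and daughter, a fair coin deciding which side
// receives the first segment (both sides always receive >= 1 nucleoid)
static void split_alleles(const Alleles &parent, int nspl,
                          Alleles &mother, Alleles &daughter) {
  const int N = (int)parent.size();
  const int nb = N - 1;  // internal boundaries 1..N-1
  std::vector<int> pos(nb);
  for (int i = 0; i < nb; ++i) pos[i] = i + 1;
  for (int i = 0; i < nspl; ++i) {  // partial Fisher-Yates draw
    int j = i + runif_int(nb - i);
    std::swap(pos[i], pos[j]);
  }
  std::vector<int> cuts(pos.begin(), pos.begin() + nspl);
  std::sort(cuts.begin(), cuts.end());
  cuts.push_back(N);
  const int nseg = nspl + 1;
  mother.clear();
  daughter.clear();
  bool to_mother = unif_rand() < 0.5;
  int start = 0;
  for (int s = 0; s < nseg; ++s) {
    Alleles &dst = to_mother ? mother : daughter;
    dst.insert(dst.end(), parent.begin() + start, parent.begin() + cuts[s]);
    start = cuts[s];
    to_mother = !to_mother;
  }
}

static inline double mean_alleles(const Alleles &v) {
  long s = 0;
  for (size_t i = 0; i < v.size(); ++i) s += v[i];
  return (double)s / (double)v.size();
}

// [[Rcpp::export]]
List divide_cell_cpp(IntegerVector alleles, int nspl) {
  const int N = alleles.size();
  if (nspl < 1 || nspl > N - 1) stop("nspl must be in [1, N-1]");
  Alleles parent(N);
  for (int i = 0; i < N; ++i) parent[i] = (signed char)alleles[i];
  Alleles mother, daughter;
  split_alleles(parent, nspl, mother, daughter);
  IntegerVector m_pre(mother.begin(), mother.end());
  IntegerVector d_pre(daughter.begin(), daughter.end());
  replenish(mother, N);
  replenish(daughter, N);
  return List::create(
    _["mother"] = IntegerVector(mother.begin(), mother.end()),
    _["daughter"] = IntegerVector(daughter.begin(), daughter.end()),
    _["mother_presplit"] = m_pre,
    _["daughter_presplit"] = d_pre);
}

// One simulation run: all founders, ngen synchronous generations.
// founders: n_founders x N matrix of 0/1 alleles.
// Returns the unweighted mean of per-cell heteroplasmy over all final
// cells, the final cell count, and (optionally) the per-cell h values.
// [[Rcpp::export]]
List simulate_run_cpp(IntegerMatrix founders, int ngen, int ndau, int nspl,
                      double g_other, bool keep_h = false) {
  const int nf = founders.nrow();
  const int N = founders.ncol();
  if (N < 2 || N % 2 != 0) stop("N must be even and >= 2");
  if (nspl < 1 || nspl > N - 1) stop("nspl must be in [1, N-1]");
  if (ngen < 1) stop("ngen must be >= 1");
  if (g_other <= 0 || g_other > 2) stop("g_other must be in (0, 2]");

  std::vector<Alleles> cells;
  std::vector<int> divs;
  cells.reserve(1024);
  for (int f = 0; f < nf; ++f) {
    Alleles a(N);
    for (int j = 0; j < N; ++j) a[j] = (signed char)founders(f, j);
    cells.push_back(a);
    divs.push_back(0);
  }

  Alleles mother, daughter;
  for (int gen = 0; gen < ngen; ++gen) {
    const size_t ncur = cells.size();
    for (size_t i = 0; i < ncur; ++i) {
      if (divs[i] >= ndau) continue;  // post-replicative
      double h = mean_alleles(cells[i]);
      double g = 1.0 + (g_other - 1.0) * h;
      double p = std::pow(2.0, g) - 1.0;
      if (p > 1.0) p = 1.0;
      if (p < 0.0) p = 0.0;
      if (unif_rand() < p) {
        split_alleles(cells[i], nspl, mother, daughter);
        replenish(mother, N);
        replenish(daughter, N);
        cells[i] = mother;
        divs[i] += 1;
        cells.push_back(daughter);
        divs.push_back(0);
      }
    }
    checkUserInterrupt();
  }

  const size_t nc = cells.size();
  double sum_h = 0.0;
  NumericVector hvec(keep_h ? nc : (size_t)0);
  for (size_t i = 0; i < nc; ++i) {
    double h = mean_alleles(cells[i]);
    sum_h += h;
    if (keep_h) hvec[i] = h;
  }
  List out = List::create(
    _["mean_h"] = sum_h / (double)nc,
    _["n_cells"] = (double)nc);
  if (keep_h) out["h"] = hvec;
  return out;
}
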