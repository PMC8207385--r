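#include <Rcpp.h>
using namespace Rcpp;

// Single-population Kingman coalescent with piecewise-constant effective size
// and strict stepwise (SMM) microsatellite mutation.
//
// Time is measured in generations, backwards from the present.  With diploid
// effective size N the pairwise coalescence rate is 1/(2N) per generation, so
// k lineages coalesce at rate k(k-1)/(4N); this yields E[pairwise TMRCA] = 2N
// and, with theta = 4*N*mu, the Ohta-Kimura equilibrium heterozygosity
// 1 - 1/sqrt(1 + 2*theta) used as the simulator's oracle.
//
// Mutation: the number of mutations on a branch of length L is
// Poisson(mu * L); each mutation moves the allele +-1 motif unit with equal
// probability, so the net displacement is 2*Binomial(m, 1/2) - m.  Sampling
// the net displacement directly is exact under the strict SMM and keeps large
// reference tables affordable.

namespace {

struct Genealogy {
  std::vector<int> parent;     // 2n-1 nodes, root has parent -1
  std::vector<double> time;    // node times (leaves at 0)
  std::vector<int> order;      // node indices sorted by decreasing time
};

Genealogy simulate_genealogy(int n, const NumericVector& epoch_start,
                             const NumericVector& epoch_ne) {
  int n_nodes = 2 * n - 1;
  Genealogy g;
  g.parent.assign(n_nodes, -1);
  g.time.assign(n_nodes, 0.0);

  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;

  int k = n;
  int next_node = n;
  int e = 0;
  int n_epochs = epoch_start.size();
  double t = 0.0;

  while (k > 1) {
    double N = epoch_ne[e];
    double rate = (double)k * (k - 1) / (4.0 * N);
    double w = R::rexp(1.0 / rate);
    double t_next = (e + 1 < n_epochs) ? epoch_start[e + 1] : R_PosInf;
    if (t + w >= t_next) {  // cross into older epoch, redraw under its size
      t = t_next;
      ++e;
      continue;
    }
    t += w;
    int i = (int)std::floor(R::unif_rand() * k);
    if (i >= k) i = k - 1;
    int j = (int)std::floor(R::unif_rand() * (k - 1));
    if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    int p = next_node++;
    g.parent[a] = p;
    g.parent[b] = p;
    g.time[p] = t;
    // replace slot min(i,j) with parent, drop the other
    int lo = std::min(i, j), hi = std::max(i, j);
    active[lo] = p;
    active[hi] = active[k - 1];
    --k;
  }

  // nodes were created in increasing time order; process root -> leaves
  g.order.resize(n_nodes);
  for (int v = 0; v < n_nodes; ++v) g.order[v] = n_nodes - 1 - v;
  return g;
}

void drop_mutations(const Genealogy& g, int n, double mu, int ancestral,
                    IntegerMatrix& out, int locus) {
  int n_nodes = 2 * n - 1;
  std::vector<int> allele(n_nodes, ancestral);
  for (int idx = 0; idx < n_nodes; ++idx) {
    int v = g.order[idx];
    int p = g.parent[v];
    if (p < 0) continue;  // root keeps the ancestral state
    double len = g.time[p] - g.time[v];
    double m = R::rpois(mu * len);
    int net = 0;
    if (m > 0) net = 2 * (int)R::rbinom(m, 0.5) - (int)m;
    allele[v] = allele[p] + net;
  }
  for (int i = 0; i < n; ++i) out(i, locus) = allele[i];
}

}  // namespace

// [[Rcpp::export(name = ".sim_msat_cpp")]]
IntegerMatrix sim_msat_cpp(int n_copies, NumericVector epoch_start,
                           NumericVector epoch_ne, NumericVector mu,
                           int n_loci, bool linked, int ancestral) {
  if (n_copies < 2) stop("n_copies must be >= 2");
  if (epoch_start.size() != epoch_ne.size())
    stop("epoch_start and epoch_ne lengths differ");
  for (int e = 0; e < epoch_start.size(); ++e) {
    if (epoch_ne[e] <= 0) stop("effective sizes must be positive");
    if (e > 0 && epoch_start[e] <= epoch_start[e - 1])
      stop("epoch start times must be strictly increasing (zero-length epoch)");
  }
  if (epoch_start[0] != 0) stop("first epoch must start at time 0");
  if (mu.size() != n_loci) stop("mu must have one rate per locus");

  IntegerMatrix out(n_copies, n_loci);
  if (linked) {
    Genealogy g = simulate_genealogy(n_copies, epoch_start, epoch_ne);
    for (int l = 0; l < n_loci; ++l)
      drop_mutations(g, n_copies, mu[l], ancestral, out, l);
  } else {
    for (int l = 0; l < n_loci; ++l) {
      Genealogy g = simulate_genealogy(n_copies, epoch_start, epoch_ne);
      drop_mutations(g, n_copies, mu[l], ancestral, out, l);
    }
  }
  return out;
}

// Per-locus summary statistics for a copies x loci allele-size matrix:
// allele count A, unbiased expected heterozygosity He, allele-size variance
// (population variance, denominator n) and Garza-Williamson M = A/(range+1).
// Returns an 8-vector: mean and variance across loci of (A, He, V, M).
// [[Rcpp::export(name = ".msat_stats_cpp")]]
NumericVector msat_stats_cpp(IntegerMatrix x) {
  int n = x.nrow(), L = x.ncol();
  if (n < 2 || L < 1) stop("need >= 2 copies and >= 1 locus");
  NumericMatrix per(L, 4);
  for (int l = 0; l < L; ++l) {
    std::map<int, int> counts;
    double s = 0, s2 = 0;
    int mn = x(0, l), mx = x(0, l);
    for (int i = 0; i < n; ++i) {
      int a = x(i, l);
      counts[a] += 1;
      s += a;
      s2 += (double)a * a;
      if (a < mn) mn = a;
      if (a > mx) mx = a;
    }
    int A = counts.size();
    double sum_p2 = 0;
    for (std::map<int, int>::iterator it = counts.begin(); it != counts.end();
         ++it) {
      double p = (double)it->second / n;
      sum_p2 += p * p;
    }
    double he = (double)n / (n - 1) * (1.0 - sum_p2);
    double v = s2 / n - (s / n) * (s / n);
    if (v < 0) v = 0;
    double m = (double)A / (mx - mn + 1);
    per(l, 0) = A;
    per(l, 1) = he;
    per(l, 2) = v;
    per(l, 3) = m;
  }
  NumericVector out(8);
  for (int s_i = 0; s_i < 4; ++s_i) {
    double mean = 0;
    for (int l = 0; l < L; ++l) mean += per(l, s_i);
    mean /= L;
    double var = 0;
    if (L > 1) {
      for (int l = 0; l < L; ++l)
        var += (per(l, s_i) - mean) * (per(l, s_i) - mean);
      var /= (L - 1);
    }
    out[2 * s_i] = mean;
    out[2 * s_i + 1] = var;
  }
  out.names() = CharacterVector::create("mean_A", "var_A", "mean_He", "var_He",
                                        "mean_V", "var_V", "mean_M", "var_M");
  return out;
}
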