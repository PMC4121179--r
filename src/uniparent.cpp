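// Compiled kernels: neutral-coalescent spectrum simulation and the
// stepwise-mutation-model pruning likelihood used by the genealogy MCMC.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Simulate `reps` neutral constant-size coalescent samples of size n and
// return per-replicate spectrum ingredients. Mutations are placed either
// Poisson(theta/2 * branch length) ("theta" mode, theta >= 0) or exactly
// S_fixed mutations multinomially by branch length. Columns: total
// mutations, mean pairwise differences, derived singletons (xi_1),
// distinct haplotypes k, mutations at derived count n-1 (xi_{n-1}).
// [[Rcpp::export]]
NumericMatrix coalsim_stats_cpp(int n, int reps, double theta, int S_fixed) {
  if (n < 2) stop("n must be >= 2");
  const int nnode = 2 * n - 1;
  NumericMatrix out(reps, 5);
  std::vector<int> parent(nnode), ndesc(nnode), mut(nnode);
  std::vector<double> time(nnode), blen(nnode);
  std::vector<int> active(n);
  std::vector<uint64_t> hash(nnode), bh(nnode);
  std::vector<uint64_t> leafh(n);

  RNGScope scope;
  for (int r = 0; r < reps; ++r) {
    // genealogy
    for (int i = 0; i < n; ++i) { active[i] = i; time[i] = 0.0; }
    int nact = n, next = n;
    double t = 0.0;
    while (nact > 1) {
      double rate = nact * (nact - 1) / 2.0;
      t += R::exp_rand() / rate;
      int i = (int)(R::unif_rand() * nact); if (i == nact) i = nact - 1;
      int j = (int)(R::unif_rand() * (nact - 1)); if (j == nact - 1) j = nact - 2;
      if (j >= i) j++;
      int a = active[i], b = active[j];
      parent[a] = next; parent[b] = next; time[next] = t;
      active[std::min(i, j)] = next;
      active[std::max(i, j)] = active[nact - 1];
      nact--; next++;
    }
    int root = nnode - 1;
    parent[root] = -1;
    double tot = 0.0;
    for (int v = 0; v < root; ++v) {
      blen[v] = time[parent[v]] - time[v];
      tot += blen[v];
    }
    // descendant counts: children always precede their parent
    for (int v = 0; v < nnode; ++v) ndesc[v] = (v < n) ? 1 : 0;
    for (int v = 0; v < root; ++v) ndesc[parent[v]] += ndesc[v];

    // mutations per branch
    std::fill(mut.begin(), mut.end(), 0);
    int S = 0;
    if (theta >= 0) {
      for (int v = 0; v < root; ++v) {
        mut[v] = (int)R::rpois(0.5 * theta * blen[v]);
        S += mut[v];
      }
    } else {
      S = S_fixed;
      for (int s = 0; s < S; ++s) {
        double u = R::unif_rand() * tot, acc = 0.0;
        int v = 0;
        for (; v < root; ++v) { acc += blen[v]; if (u <= acc) break; }
        if (v == root) v = root - 1;
        mut[v]++;
      }
    }

    double pi = 0.0; int xi1 = 0, xin1 = 0;
    double pairs = n * (n - 1) / 2.0;
    for (int v = 0; v < root; ++v) {
      if (!mut[v]) continue;
      pi += (double)mut[v] * ndesc[v] * (n - ndesc[v]) / pairs;
      if (ndesc[v] == 1) xi1 += mut[v];
      if (ndesc[v] == n - 1) xin1 += mut[v];
    }

    // distinct haplotypes via set-hash of mutated branches along root paths
    for (int v = 0; v < root; ++v) {
      if (mut[v]) {
        uint64_t h1 = (uint64_t)(R::unif_rand() * 4294967296.0);
        uint64_t h2 = (uint64_t)(R::unif_rand() * 4294967296.0);
        bh[v] = (h1 << 32) ^ h2 ^ 0x9e3779b97f4a7c15ULL;
      } else bh[v] = 0;
    }
    hash[root] = 0;
    for (int v = root - 1; v >= 0; --v) hash[v] = hash[parent[v]] ^ bh[v];
    for (int i = 0; i < n; ++i) leafh[i] = hash[i];
    std::sort(leafh.begin(), leafh.end());
    int k = 1;
    for (int i = 1; i < n; ++i) if (leafh[i] != leafh[i - 1]) k++;

    out(r, 0) = S; out(r, 1) = pi; out(r, 2) = xi1; out(r, 3) = k;
    out(r, 4) = xin1;
  }
  return out;
}

// Felsenstein pruning log-likelihood of STR allele data under a symmetric
// single-step mutation model on a bounded integer lattice. The generator is
// Q = mu * Q0 with Q0 the unit-rate reflecting random walk; its (fixed)
// spectral decomposition Q0 = V diag(lam) V^T is supplied from R, so
// exp(Q l) v = V diag(exp(mu l lam)) V^T v.
//
// parent: 0-based parent index per node (-1 for root); children always have
// smaller indices than their parent. times: node ages (generations).
// alleles: n x L matrix of 0-based lattice states at the leaves.
// Root prior: uniform over the lattice.
// [[Rcpp::export]]
double smm_loglik_cpp(IntegerVector parent, NumericVector times,
                      IntegerMatrix alleles, NumericMatrix V,
                      NumericVector lam, double mu) {
  const int nnode = parent.size();
  const int n = alleles.nrow(), L = alleles.ncol();
  const int S = V.nrow();
  if (nnode != 2 * n - 1) stop("node/leaf count mismatch");
  std::vector<double> part((size_t)nnode * S), w(S), q(S);
  double ll = 0.0;
  for (int loc = 0; loc < L; ++loc) {
    double logscale = 0.0;
    for (int v = 0; v < nnode; ++v)
      for (int s = 0; s < S; ++s)
        part[(size_t)v * S + s] = (v < n) ? 0.0 : 1.0;
    for (int i = 0; i < n; ++i) {
      int a = alleles(i, loc);
      if (a < 0 || a >= S) stop("allele state outside lattice");
      part[(size_t)i * S + a] = 1.0;
    }
    for (int v = 0; v < nnode - 1; ++v) {
      int p = parent[v];
      double len = times[p] - times[v];
      if (len < 0) stop("negative branch length");
      double *pv = &part[(size_t)v * S];
      // w = V^T pv
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int t2 = 0; t2 < S; ++t2) acc += V(t2, s) * pv[t2];
        w[s] = acc * std::exp(lam[s] * mu * len);
      }
      // q = V w
      double qs = 0.0;
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int t2 = 0; t2 < S; ++t2) acc += V(s, t2) * w[t2];
        q[s] = (acc > 0.0) ? acc : 0.0;
        qs += q[s];
      }
      if (qs <= 0.0) return -1e300;
      double *pp = &part[(size_t)p * S];
      for (int s = 0; s < S; ++s) pp[s] *= q[s] / qs;
      logscale += std::log(qs);
      // rescale parent partials to keep them in range
      double mx = 0.0;
      for (int s = 0; s < S; ++s) if (pp[s] > mx) mx = pp[s];
      if (mx > 0.0 && mx < 1e-150) {
        for (int s = 0; s < S; ++s) pp[s] /= mx;
        logscale += std::log(mx);
      }
    }
    double *pr = &part[(size_t)(nnode - 1) * S];
    double tot = 0.0;
    for (int s = 0; s < S; ++s) tot += pr[s];
    if (tot <= 0.0) return -1e300;
    ll += std::log(tot / S) + logscale;
  }
  return ll;
}
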