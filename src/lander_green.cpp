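#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multipoint all-affected IBD sharing over inheritance vectors.
//
// Hidden state: inheritance vector v in {0,1}^m, one bit per meiosis.
// Transition between adjacent markers flips each bit independently with
// the Haldane recombination fraction theta for that marker gap.
// Emission at a marker is the probability of the observed unphased
// genotypes given v, summing over founder-allele assignments weighted by
// the marker's panel allele frequency. The assignment sum factorizes over
// connected components of the founder-allele graph induced by v and the
// constrained (non-missing) individuals, so each component is enumerated
// separately (2^k patterns for k slots) instead of the full 2^(2f) space.

static inline double penet(int obs, int cnt, double err) {
  if (obs == cnt) return 1.0 - err;
  return err * 0.5;
}

// In-place transition step: each of the m bits flips independently w.p. theta.
static void butterfly(std::vector<double>& f, int m, double theta) {
  const int V = (int)f.size();
  const double s = 1.0 - theta;
  for (int j = 0; j < m; ++j) {
    const int bit = 1 << j;
    for (int v = 0; v < V; ++v) {
      if (v & bit) continue;
      const double a = f[v], b = f[v | bit];
      f[v] = s * a + theta * b;
      f[v | bit] = theta * a + s * b;
    }
  }
}

// Emission for one marker on orbit representatives only.
// Founder-symmetry: swapping a founder's two haplotype labels toggles a
// fixed set of meiosis bits (one per transmitting meiosis of that founder)
// and leaves the emission invariant, because both haplotypes carry the same
// allele-frequency prior. Emissions are therefore computed once per orbit
// of the XOR subgroup generated by the founder masks and copied to the
// other orbit members.
static void marker_emission_orbits(const IntegerMatrix& A1,
                                   const IntegerMatrix& A2,
                                   const std::vector<int>& g, double p,
                                   double err, int n_slots,
                                   const std::vector<int>& subgroup,
                                   const std::vector<int>& rep,
                                   std::vector<double>& e) {
  const int V = A1.nrow();
  const int n = A1.ncol();

  std::vector<int> obs_idx;
  obs_idx.reserve(n);
  for (int i = 0; i < n; ++i)
    if (g[i] >= 0) obs_idx.push_back(i);
  if (obs_idx.empty()) {
    std::fill(e.begin(), e.end(), 1.0);
    return;
  }

  std::vector<int> parent(n_slots), local(n_slots);
  std::vector<int> comp_slots, comp_inds;
  const double q = 1.0 - p;

  for (int v = 0; v < V; ++v) {
    if (rep[v] != v) continue;

    for (int s = 0; s < n_slots; ++s) parent[s] = s;
    for (size_t k = 0; k < obs_idx.size(); ++k) {
      int i = obs_idx[k];
      int a = A1(v, i) - 1, b = A2(v, i) - 1;
      while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
      while (parent[b] != b) { parent[b] = parent[parent[b]]; b = parent[b]; }
      if (a != b) parent[b] = a;
    }
    for (int s = 0; s < n_slots; ++s) {
      int r = s;
      while (parent[r] != r) r = parent[r];
      parent[s] = r;
    }

    double ev = 1.0;
    std::vector<bool> done(n_slots, false);
    for (size_t k0 = 0; k0 < obs_idx.size() && ev > 0.0; ++k0) {
      int root = parent[A1(v, obs_idx[k0]) - 1];
      if (done[root]) continue;
      done[root] = true;

      comp_slots.clear();
      for (int s = 0; s < n_slots; ++s)
        if (parent[s] == root) { local[s] = (int)comp_slots.size(); comp_slots.push_back(s); }
      comp_inds.clear();
      for (size_t k = 0; k < obs_idx.size(); ++k) {
        int i = obs_idx[k];
        if (parent[A1(v, i) - 1] == root) comp_inds.push_back(i);
      }

      const int K = (int)comp_slots.size();
      double fac = 0.0;
      const unsigned long nmask = 1UL << K;
      for (unsigned long mask = 0; mask < nmask; ++mask) {
        double w = 1.0;
        for (int s = 0; s < K; ++s) w *= (mask >> s & 1UL) ? p : q;
        if (w == 0.0) continue;
        for (size_t k = 0; k < comp_inds.size(); ++k) {
          int i = comp_inds[k];
          int cnt = (int)(mask >> local[A1(v, i) - 1] & 1UL) +
                    (int)(mask >> local[A2(v, i) - 1] & 1UL);
          w *= penet(g[i], cnt, err);
          if (w == 0.0) break;
        }
        fac += w;
      }
      ev *= fac;
    }
    e[v] = ev;
  }
  // propagate to the rest of each orbit
  for (int v = 0; v < V; ++v)
    if (rep[v] != v) e[v] = e[rep[v]];
}

//' @noRd
// [[Rcpp::export(name = ".lander_green_fb")]]
NumericVector lander_green_fb(IntegerMatrix A1, IntegerMatrix A2,
                              IntegerMatrix geno, NumericVector freq,
                              NumericVector theta, LogicalVector share,
                              int n_slots, double err,
                              IntegerVector founder_masks) {
  const int V = A1.nrow();
  const int n = A1.ncol();
  const int M = freq.size();
  if (geno.nrow() != n || geno.ncol() != M)
    stop("genotype matrix dimensions do not match descent arrays");
  if (theta.size() != M - 1 && M > 1)
    stop("theta must have length n_markers - 1");

  int m = 0;
  while ((1 << m) < V) ++m;
  if ((1 << m) != V) stop("state count is not a power of two");

  // XOR subgroup generated by the founder masks, and orbit representatives
  std::vector<int> subgroup(1, 0);
  for (int j = 0; j < founder_masks.size(); ++j) {
    const int mk = founder_masks[j];
    if (mk == 0) continue;
    const size_t sz = subgroup.size();
    for (size_t s = 0; s < sz; ++s) {
      int cand = subgroup[s] ^ mk;
      if (std::find(subgroup.begin(), subgroup.end(), cand) == subgroup.end())
        subgroup.push_back(cand);
    }
  }
  std::vector<int> rep(V);
  for (int v = 0; v < V; ++v) {
    int best = v;
    for (size_t s = 1; s < subgroup.size(); ++s) {
      const int w = v ^ subgroup[s];
      if (w < best) best = w;
    }
    rep[v] = best;
  }

  // emissions, stored per marker
  std::vector< std::vector<double> > E(M, std::vector<double>(V));
  std::vector<int> g(n);
  for (int t = 0; t < M; ++t) {
    for (int i = 0; i < n; ++i) g[i] = geno(i, t);
    marker_emission_orbits(A1, A2, g, freq[t], err, n_slots, subgroup, rep,
                           E[t]);
    // a marker whose genotypes are inconsistent with every inheritance
    // vector (e.g. a genotyping error) carries no linkage information;
    // treat it as missing rather than zeroing the chain likelihood
    double mx = 0.0;
    for (int v = 0; v < V; ++v) if (E[t][v] > mx) mx = E[t][v];
    if (mx == 0.0) std::fill(E[t].begin(), E[t].end(), 1.0);
  }

  // forward (scaled)
  std::vector< std::vector<double> > alpha(M, std::vector<double>(V));
  const double pv = 1.0 / V;
  {
    double c = 0.0;
    for (int v = 0; v < V; ++v) { alpha[0][v] = pv * E[0][v]; c += alpha[0][v]; }
    if (c <= 0.0) stop("zero likelihood at marker 1 (genotypes incompatible with pedigree)");
    for (int v = 0; v < V; ++v) alpha[0][v] /= c;
  }
  std::vector<double> work(V);
  for (int t = 1; t < M; ++t) {
    work = alpha[t - 1];
    butterfly(work, m, theta[t - 1]);
    double c = 0.0;
    for (int v = 0; v < V; ++v) { alpha[t][v] = work[v] * E[t][v]; c += alpha[t][v]; }
    if (c <= 0.0) stop("zero likelihood during forward pass (genotypes incompatible with pedigree)");
    for (int v = 0; v < V; ++v) alpha[t][v] /= c;
  }

  // backward + per-marker posterior of the all-affected sharing event
  NumericVector out(M);
  std::vector<double> beta(V, 1.0);
  for (int t = M - 1; t >= 0; --t) {
    double num = 0.0, den = 0.0;
    for (int v = 0; v < V; ++v) {
      const double post = alpha[t][v] * beta[v];
      den += post;
      if (share[v]) num += post;
    }
    out[t] = num / den;
    if (t > 0) {
      for (int v = 0; v < V; ++v) work[v] = beta[v] * E[t][v];
      butterfly(work, m, theta[t - 1]);
      double c = 0.0;
      for (int v = 0; v < V; ++v) c += work[v];
      for (int v = 0; v < V; ++v) beta[v] = work[v] / c;
    }
  }
  return out;
}
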