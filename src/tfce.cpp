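// Threshold-free cluster enhancement and sign-flip permutation machinery.
// These inner loops run once per permutation (hundreds to tens of
// thousands of times per test), hence compiled.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

// Union-find with size tracking.
struct DSU {
  std::vector<int> parent;
  std::vector<int> size;
  explicit DSU(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  void reset() {
    for (size_t i = 0; i < parent.size(); ++i) { parent[i] = (int)i; size[i] = 1; }
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

typedef std::vector< std::vector<int> > AdjList;

AdjList build_adjlist(const IntegerMatrix& edges, int n) {
  AdjList adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (a == b) continue;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  return adj;
}

const double T_CAP = 100.0;  // cap |t| so degenerate cells cannot stall the h sweep

// TFCE score for one statistic vector.  Descending threshold sweep with an
// incremental union-find: cells enter as h drops below their value, and at
// each step every active cell accrues extent^E * h^H * dh.
void tfce_core(const std::vector<double>& t, const AdjList& adj,
               double E, double H, double dh, DSU& dsu,
               std::vector<double>& score,
               std::vector<int>& order, std::vector<char>& active,
               std::vector<double>& pow_cache) {
  const int n = (int)t.size();
  std::fill(score.begin(), score.end(), 0.0);
  double hmax = 0.0;
  for (int i = 0; i < n; ++i) if (t[i] > hmax) hmax = t[i];
  if (hmax > T_CAP) hmax = T_CAP;
  if (hmax <= 0.0 || dh <= 0.0) return;

  order.resize(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&t](int a, int b) { return t[a] > t[b]; });

  dsu.reset();
  std::fill(active.begin(), active.end(), 0);
  std::fill(pow_cache.begin(), pow_cache.end(), -1.0);

  std::vector<int> active_list;
  active_list.reserve(n);

  int nth = (int)std::floor(hmax / dh);
  int ptr = 0;
  for (int k = nth; k >= 1; --k) {
    const double h = k * dh;
    while (ptr < n && std::min(t[order[ptr]], T_CAP) >= h) {
      const int c = order[ptr++];
      active[c] = 1;
      active_list.push_back(c);
      for (int w : adj[c]) if (active[w]) dsu.unite(c, w);
    }
    const double hterm = std::pow(h, H) * dh;
    for (int c : active_list) {
      const int sz = dsu.size[dsu.find(c)];
      double pe = pow_cache[sz];
      if (pe < 0.0) { pe = std::pow((double)sz, E); pow_cache[sz] = pe; }
      score[c] += pe * hterm;
    }
  }
}

// One-sample t against 0 for sign-flipped deviations.  Sum of squares is
// flip-invariant, so only the mean is recomputed per permutation.
void signflip_t(const NumericMatrix& dev, const double* flip,
                const std::vector<double>& ss, std::vector<double>& t_out) {
  const int ns = dev.nrow(), m = dev.ncol();
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < ns; ++i) s += flip[i] * dev(i, j);
    const double mean = s / ns;
    const double var = (ss[j] - ns * mean * mean) / (ns - 1);
    double t;
    if (var < 1e-24) t = (std::fabs(mean) < 1e-12) ? 0.0
                       : (mean > 0 ? T_CAP : -T_CAP);
    else t = mean / std::sqrt(var / ns);
    t_out[j] = t;
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector tval, IntegerMatrix edges, int n_nodes,
                       double E, double H, double dh) {
  const int n = tval.size();
  if (n != n_nodes) stop("statistic length does not match node count");
  AdjList adj = build_adjlist(edges, n);
  DSU dsu(n);
  std::vector<double> t(tval.begin(), tval.end());
  std::vector<double> score(n), pow_cache(n + 1, -1.0);
  std::vector<int> order;
  std::vector<char> active(n, 0);
  tfce_core(t, adj, E, H, dh, dsu, score, order, active, pow_cache);
  return NumericVector(score.begin(), score.end());
}

// [[Rcpp::export]]
List cpp_tfce_signflip(NumericMatrix dev, NumericMatrix flips,
                       IntegerMatrix edges, double E, double H, double dh) {
  const int ns = dev.nrow(), m = dev.ncol(), np = flips.nrow();
  if (flips.ncol() != ns) stop("flip matrix columns must equal subject count");
  AdjList adj = build_adjlist(edges, m);
  DSU dsu(m);

  std::vector<double> ss(m, 0.0);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < ns; ++i) ss[j] += dev(i, j) * dev(i, j);

  std::vector<double> tvec(m), score(m), pow_cache(m + 1, -1.0);
  std::vector<int> order;
  std::vector<char> active(m, 0);

  std::vector<double> ones(ns, 1.0);
  signflip_t(dev, ones.data(), ss, tvec);
  NumericVector obs_t(tvec.begin(), tvec.end());
  tfce_core(tvec, adj, E, H, dh, dsu, score, order, active, pow_cache);
  NumericVector obs_tfce(score.begin(), score.end());

  NumericVector null_max(np);
  std::vector<double> flip(ns);
  for (int p = 0; p < np; ++p) {
    for (int i = 0; i < ns; ++i) flip[i] = flips(p, i);
    signflip_t(dev, flip.data(), ss, tvec);
    tfce_core(tvec, adj, E, H, dh, dsu, score, order, active, pow_cache);
    double mx = 0.0;
    for (int j = 0; j < m; ++j) if (score[j] > mx) mx = score[j];
    null_max[p] = mx;
  }
  return List::create(_["obs_t"] = obs_t, _["obs_tfce"] = obs_tfce,
                      _["null_max"] = null_max);
}

// [[Rcpp::export]]
IntegerVector cpp_components(int n_nodes, IntegerMatrix edges,
                             LogicalVector active) {
  if (active.size() != n_nodes) stop("active flag length mismatch");
  DSU dsu(n_nodes);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (active[a] && active[b]) dsu.unite(a, b);
  }
  IntegerVector labels(n_nodes, 0);
  std::vector<int> lab_of_root(n_nodes, 0);
  int next = 0;
  for (int i = 0; i < n_nodes; ++i) {
    if (!active[i]) continue;
    int r = dsu.find(i);
    if (lab_of_root[r] == 0) lab_of_root[r] = ++next;  // by smallest member
    labels[i] = lab_of_root[r];
  }
  return labels;
}

// [[Rcpp::export]]
List cpp_cluster_mass_signflip(NumericMatrix dev, NumericMatrix flips,
                               IntegerMatrix edges, double thresh) {
  const int ns = dev.nrow(), m = dev.ncol(), np = flips.nrow();
  if (flips.ncol() != ns) stop("flip matrix columns must equal subject count");
  AdjList adj = build_adjlist(edges, m);

  std::vector<double> ss(m, 0.0);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < ns; ++i) ss[j] += dev(i, j) * dev(i, j);

  std::vector<double> tvec(m);
  std::vector<double> ones(ns, 1.0);
  signflip_t(dev, ones.data(), ss, tvec);
  NumericVector obs_t(tvec.begin(), tvec.end());

  DSU dsu(m);
  std::vector<double> flip(ns);
  NumericVector null_max(np);
  std::vector<double> mass(m);
  std::vector<char> active(m);
  for (int p = 0; p < np; ++p) {
    for (int i = 0; i < ns; ++i) flip[i] = flips(p, i);
    signflip_t(dev, flip.data(), ss, tvec);
    dsu.reset();
    for (int j = 0; j < m; ++j) active[j] = tvec[j] >= thresh;
    for (int j = 0; j < m; ++j) {
      if (!active[j]) continue;
      for (int w : adj[j]) if (w > j && active[w]) dsu.unite(j, w);
    }
    std::fill(mass.begin(), mass.end(), 0.0);
    double mx = 0.0;
    for (int j = 0; j < m; ++j) {
      if (!active[j]) continue;
      int r = dsu.find(j);
      mass[r] += tvec[j];
      if (mass[r] > mx) mx = mass[r];
    }
    null_max[p] = mx;
  }
  return List::create(_["obs_t"] = obs_t, _["null_max"] = null_max);
}
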