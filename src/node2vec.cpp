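// Second-order biased random walks (node2vec) and skip-gram with negative
// sampling, self-contained so that a given seed always yields the same
// embedding regardless of R's RNG state.
#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

// Deterministic RNG: raw mt19937_64 output only (the engine's sequence is
// fixed by the C++ standard; std::uniform_* distributions are not).
struct Rng {
  std::mt19937_64 eng;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() {  // in [0, 1)
    return (eng() >> 11) * (1.0 / 9007199254740992.0);
  }
  uint64_t below(uint64_t n) { return eng() % n; }  // modulo bias negligible
};

struct Graph {
  int n;
  std::vector<int> off;      // CSR offsets, size n+1
  std::vector<int> nb;       // neighbors, sorted within each node
  std::vector<double> wt;    // matching weights
  bool has_edge(int u, int v) const {
    const int *b = nb.data() + off[u], *e = nb.data() + off[u + 1];
    return std::binary_search(b, e, v);
  }
};

Graph build_graph(int n, const IntegerVector &ei, const IntegerVector &ej,
                  const NumericVector &ew) {
  Graph g;
  g.n = n;
  std::vector<std::vector<std::pair<int, double>>> adj(n);
  for (int k = 0; k < ei.size(); ++k) {
    adj[ei[k]].push_back({ej[k], ew[k]});
    adj[ej[k]].push_back({ei[k], ew[k]});
  }
  g.off.assign(n + 1, 0);
  for (int v = 0; v < n; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    g.off[v + 1] = g.off[v] + (int)adj[v].size();
  }
  g.nb.reserve(g.off[n]);
  g.wt.reserve(g.off[n]);
  for (int v = 0; v < n; ++v)
    for (auto &pr : adj[v]) {
      g.nb.push_back(pr.first);
      g.wt.push_back(pr.second);
    }
  return g;
}

// sample an index in [0, probs.size()) proportional to probs (linear scan;
// neighbor lists at this scale do not warrant alias tables)
int sample_prop(const std::vector<double> &probs, double total, Rng &rng) {
  double r = rng.unif() * total, acc = 0.0;
  for (size_t i = 0; i < probs.size(); ++i) {
    acc += probs[i];
    if (r < acc) return (int)i;
  }
  return (int)probs.size() - 1;
}

void one_walk(const Graph &g, int start, int walk_length, double p, double q,
              Rng &rng, std::vector<int> &out) {
  out.clear();
  out.push_back(start);
  if (g.off[start + 1] == g.off[start]) return;  // isolated: length-1 walk
  std::vector<double> probs;
  while ((int)out.size() < walk_length) {
    int cur = out.back();
    int lo = g.off[cur], hi = g.off[cur + 1];
    if (hi == lo) break;
    int nxt;
    if (out.size() == 1) {  // first step: plain weighted neighbor draw
      probs.assign(g.wt.begin() + lo, g.wt.begin() + hi);
      double tot = 0.0;
      for (double w : probs) tot += w;
      nxt = g.nb[lo + sample_prop(probs, tot, rng)];
    } else {                // biased by return parameter p, in-out parameter q
      int prev = out[out.size() - 2];
      probs.resize(hi - lo);
      double tot = 0.0;
      for (int k = lo; k < hi; ++k) {
        int x = g.nb[k];
        double w = g.wt[k];
        if (x == prev) w /= p;
        else if (!g.has_edge(prev, x)) w /= q;
        probs[k - lo] = w;
        tot += w;
      }
      nxt = g.nb[lo + sample_prop(probs, tot, rng)];
    }
    out.push_back(nxt);
  }
}

}  // namespace

// [[Rcpp::export(name = ".n2v_walks")]]
IntegerMatrix n2v_walks_cpp(int n_nodes, IntegerVector edge_i,
                            IntegerVector edge_j, NumericVector edge_w,
                            int walk_length, int walks_per_node, double p,
                            double q, int seed) {
  Graph g = build_graph(n_nodes, edge_i, edge_j, edge_w);
  Rng rng((uint64_t)seed);
  IntegerMatrix walks(n_nodes * walks_per_node, walk_length);
  std::fill(walks.begin(), walks.end(), NA_INTEGER);
  std::vector<int> order(n_nodes), walk;
  int row = 0;
  for (int r = 0; r < walks_per_node; ++r) {
    for (int v = 0; v < n_nodes; ++v) order[v] = v;
    for (int v = n_nodes - 1; v > 0; --v)  // Fisher-Yates shuffle
      std::swap(order[v], order[rng.below(v + 1)]);
    for (int v : order) {
      one_walk(g, v, walk_length, p, q, rng, walk);
      for (size_t t = 0; t < walk.size(); ++t) walks(row, t) = walk[t] + 1;
      ++row;
    }
  }
  return walks;
}

// [[Rcpp::export(name = ".n2v_embed")]]
NumericMatrix n2v_embed_cpp(IntegerMatrix walks, int n_nodes, int dim,
                            int window, int epochs, int negative,
                            double start_lr, int seed) {
  Rng rng((uint64_t)seed);
  // corpus as ragged vectors (walks may stop early at dead ends)
  std::vector<std::vector<int>> corpus;
  corpus.reserve(walks.nrow());
  long long total_tokens = 0;
  std::vector<double> counts(n_nodes, 0.0);
  for (int i = 0; i < walks.nrow(); ++i) {
    std::vector<int> w;
    for (int j = 0; j < walks.ncol(); ++j) {
      if (walks(i, j) == NA_INTEGER) break;
      w.push_back(walks(i, j) - 1);
      counts[w.back()] += 1.0;
    }
    total_tokens += (long long)w.size();
    corpus.push_back(std::move(w));
  }
  // unigram^0.75 negative-sampling table (cumulative, binary-searched)
  std::vector<double> cum(n_nodes, 0.0);
  double z = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    z += std::pow(counts[v], 0.75);
    cum[v] = z;
  }
  std::vector<double> in((size_t)n_nodes * dim), out((size_t)n_nodes * dim, 0.0);
  for (size_t k = 0; k < in.size(); ++k) in[k] = (rng.unif() - 0.5) / dim;

  const double T = (double)total_tokens * epochs;
  long long processed = 0;
  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (auto &walk : corpus) {
      for (size_t i = 0; i < walk.size(); ++i, ++processed) {
        double lr = start_lr * std::max(1.0 - processed / T, 1e-4);
        int b = (int)rng.below((uint64_t)window);  // reduced window
        int center = walk[i];
        double *vin = &in[(size_t)center * dim];
        for (int j = (int)i - window + b; j <= (int)i + window - b; ++j) {
          if (j < 0 || j >= (int)walk.size() || j == (int)i) continue;
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = walk[j];
              label = 1.0;
            } else {
              double r = rng.unif() * z;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), r) -
                             cum.begin());
              if (target >= n_nodes) target = n_nodes - 1;
              if (target == walk[j]) continue;
              label = 0.0;
            }
            double *vout = &out[(size_t)target * dim];
            double x = 0.0;
            for (int d = 0; d < dim; ++d) x += vin[d] * vout[d];
            double f = x > 6.0 ? 1.0 : (x < -6.0 ? 0.0 : 1.0 / (1.0 + std::exp(-x)));
            double gcoef = (label - f) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += gcoef * vout[d];
              vout[d] += gcoef * vin[d];
            }
          }
          for (int d = 0; d < dim; ++d) vin[d] += grad[d];
        }
      }
    }
  }
  NumericMatrix emb(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int d = 0; d < dim; ++d) emb(v, d) = in[(size_t)v * dim + d];
  return emb;
}
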