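// Training kernels for the embedding module: biased second-order random
// walks, skip-gram with negative sampling over walk corpora, and LINE
// first/second-order edge-sampling optimisation. Graphs arrive as CSR
// adjacency with 0-based, per-node-sorted neighbour lists; all randomness
// flows from the single seed argument through one mt19937_64 stream.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline bool is_neighbor(const IntegerVector &off, const IntegerVector &adj,
                               int u, int v) {
  const int *b = adj.begin() + off[u];
  const int *e = adj.begin() + off[u + 1];
  return std::binary_search(b, e, v);
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0 - 1e-8;
  if (x < -8.0) return 1e-8;
  return 1.0 / (1.0 + std::exp(-x));
}

// Vose alias table: O(1) draws from a fixed discrete distribution.
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;
  int n = 0;

  void build(const std::vector<double> &w) {
    n = (int)w.size();
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double tot = 0.0;
    for (double x : w) tot += x;
    std::vector<double> p(n);
    for (int i = 0; i < n; ++i) p[i] = w[i] * n / tot;
    std::vector<int> small, large;
    small.reserve(n);
    large.reserve(n);
    for (int i = 0; i < n; ++i) (p[i] < 1.0 ? small : large).push_back(i);
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = p[s];
      alias[s] = l;
      p[l] = (p[l] + p[s]) - 1.0;
      (p[l] < 1.0 ? small : large).push_back(l);
    }
    for (int i : large) prob[i] = 1.0;
    for (int i : small) prob[i] = 1.0;
  }

  inline int draw(std::mt19937_64 &rng) const {
    const double u = (double)(rng() >> 11) * (1.0 / 9007199254740992.0) * n;
    const int k = std::min((int)u, n - 1);
    return (u - k) < prob[k] ? k : alias[k];
  }
};

// [[Rcpp::export]]
IntegerMatrix generate_walks_cpp(IntegerVector offsets, IntegerVector neighbors,
                                 IntegerVector starts, int walks_per_node,
                                 int walk_length, double return_weight,
                                 double explore_weight, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const int ns = starts.size();
  const int nwalks = ns * walks_per_node;
  IntegerMatrix walks(nwalks, walk_length);
  std::vector<double> w;

  int row = 0;
  for (int r = 0; r < walks_per_node; ++r) {
    for (int s = 0; s < ns; ++s, ++row) {
      int curr = starts[s];
      int prev = -1;
      walks(row, 0) = curr;
      for (int step = 1; step < walk_length; ++step) {
        int b = offsets[curr], e = offsets[curr + 1];
        int deg = e - b;
        int nxt;
        if (prev < 0) {
          nxt = neighbors[b + (int)(unif(rng) * deg) % deg];
        } else {
          w.resize(deg);
          double tot = 0.0;
          for (int i = 0; i < deg; ++i) {
            int cand = neighbors[b + i];
            double wi;
            if (cand == prev) wi = return_weight;
            else if (is_neighbor(offsets, neighbors, prev, cand)) wi = 1.0;
            else wi = explore_weight;
            w[i] = wi;
            tot += wi;
          }
          double u = unif(rng) * tot;
          int i = 0;
          double acc = w[0];
          while (acc < u && i + 1 < deg) acc += w[++i];
          nxt = neighbors[b + i];
        }
        walks(row, step) = nxt;
        prev = curr;
        curr = nxt;
      }
    }
  }
  return walks;
}

// Skip-gram with negative sampling on a walk corpus. Noise distribution is
// unigram frequency^(3/4), drawn via an alias table. The effective window
// per center token is sampled uniformly in 1..window (standard word2vec
// schedule). The learning rate decays linearly to 1e-4 of its start value.
// The returned loss trace is the mean per-pair objective (positive plus
// negative terms), measured on a deterministic 1-in-8 subsample of pairs.
// [[Rcpp::export]]
List train_skipgram_cpp(IntegerMatrix walks, int n_nodes, int dim, int window,
                        int negatives, int epochs, double lr0, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const int nwalks = walks.nrow(), wl = walks.ncol();
  std::vector<double> freq(n_nodes, 0.0);
  for (int j = 0; j < wl; ++j)
    for (int i = 0; i < nwalks; ++i) freq[walks(i, j)] += 1.0;
  for (int v = 0; v < n_nodes; ++v) freq[v] = std::pow(freq[v], 0.75);
  AliasTable noise;
  noise.build(freq);

  // column-major copy of the corpus for cache-friendly row traversal
  std::vector<int> corpus((size_t)nwalks * wl);
  for (int i = 0; i < nwalks; ++i)
    for (int j = 0; j < wl; ++j) corpus[(size_t)i * wl + j] = walks(i, j);

  std::vector<double> vin(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> vout(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (auto &x : vin) x = (unif(rng) - 0.5) / dim;

  std::vector<int> order(nwalks);
  for (int i = 0; i < nwalks; ++i) order[i] = i;
  std::vector<double> grad(dim);
  NumericVector loss(epochs);

  const double total_tokens = (double)nwalks * wl * epochs;
  double processed = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    double ep_terms = 0.0;
    uint64_t pair_counter = 0;
    for (int oi = 0; oi < nwalks; ++oi) {
      const int *walk = &corpus[(size_t)order[oi] * wl];
      for (int c = 0; c < wl; ++c) {
        double lr = lr0 * std::max(1e-4, 1.0 - processed / total_tokens);
        processed += 1.0;
        int center = walk[c];
        double *vc = &vin[(size_t)center * dim];
        int b = 1 + (int)(rng() % (uint64_t)window); // dynamic window
        int lo = std::max(0, c - b), hi = std::min(wl - 1, c + b);
        for (int t = lo; t <= hi; ++t) {
          if (t == c) continue;
          int ctx = walk[t];
          const bool track = (++pair_counter & 7) == 0;
          std::fill(grad.begin(), grad.end(), 0.0);
          {
            double *vo = &vout[(size_t)ctx * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += vc[d] * vo[d];
            double p = sigmoid(dot);
            double gsc = lr * (1.0 - p);
            for (int d = 0; d < dim; ++d) {
              grad[d] += gsc * vo[d];
              vo[d] += gsc * vc[d];
            }
            if (track) {
              ep_loss += -std::log(p);
              ep_terms += 1.0;
            }
          }
          for (int k = 0; k < negatives; ++k) {
            int neg = noise.draw(rng);
            if (neg == ctx) continue;
            double *vo = &vout[(size_t)neg * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += vc[d] * vo[d];
            double p = sigmoid(dot);
            double gsc = lr * (0.0 - p);
            for (int d = 0; d < dim; ++d) {
              grad[d] += gsc * vo[d];
              vo[d] += gsc * vc[d];
            }
            if (track) ep_loss += -std::log(1.0 - p);
          }
          for (int d = 0; d < dim; ++d) vc[d] += grad[d];
        }
      }
    }
    loss[ep] = ep_loss / std::max(1.0, ep_terms);
  }

  NumericMatrix emb(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int d = 0; d < dim; ++d) emb(v, d) = vin[(size_t)v * dim + d];
  return List::create(_["embedding"] = emb, _["loss"] = loss);
}

// LINE: per-sample stochastic updates on uniformly sampled edges (the graph
// is unweighted). order 1: symmetric vertex-vertex objective; order 2:
// vertex-context objective. Noise distribution is degree^(3/4). Loss trace:
// mean positive-sample negative log-likelihood over 10 equal chunks.
// [[Rcpp::export]]
List train_line_cpp(IntegerVector edge_from, IntegerVector edge_to, int n_nodes,
                    int dim, int order, double total_samples, int negatives,
                    double lr0, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const int m = edge_from.size();

  std::vector<double> degw(n_nodes, 0.0);
  for (int i = 0; i < m; ++i) {
    degw[edge_from[i]] += 1.0;
    degw[edge_to[i]] += 1.0;
  }
  for (int v = 0; v < n_nodes; ++v) degw[v] = std::pow(degw[v], 0.75);
  AliasTable noise;
  noise.build(degw);

  std::vector<double> vert(static_cast<size_t>(n_nodes) * dim);
  for (auto &x : vert) x = (unif(rng) - 0.5) / dim;
  std::vector<double> ctx;
  if (order == 2) ctx.assign(static_cast<size_t>(n_nodes) * dim, 0.0);

  const long long S = (long long)total_samples;
  const int nchunk = 10;
  NumericVector loss(nchunk);
  std::vector<double> terms(nchunk, 0.0);
  std::vector<double> grad(dim);

  for (long long s = 0; s < S; ++s) {
    double lr = lr0 * std::max(1e-4, 1.0 - (double)s / (double)S);
    int e = (int)(rng() % (uint64_t)m);
    int u = edge_from[e], v = edge_to[e];
    if (rng() & 1u) std::swap(u, v); // undirected: random orientation
    int chunk = (int)((s * nchunk) / S);
    double *vu = &vert[(size_t)u * dim];
    std::fill(grad.begin(), grad.end(), 0.0);
    for (int k = 0; k <= negatives; ++k) {
      int target;
      double label;
      if (k == 0) {
        target = v;
        label = 1.0;
      } else {
        target = noise.draw(rng);
        if (target == v || target == u) continue;
        label = 0.0;
      }
      double *vt = (order == 2) ? &ctx[(size_t)target * dim]
                                : &vert[(size_t)target * dim];
      double dot = 0.0;
      for (int d = 0; d < dim; ++d) dot += vu[d] * vt[d];
      double p = sigmoid(dot);
      double gsc = lr * (label - p);
      for (int d = 0; d < dim; ++d) {
        grad[d] += gsc * vt[d];
        vt[d] += gsc * vu[d];
      }
      if (k == 0) {
        loss[chunk] += -std::log(p);
        terms[chunk] += 1.0;
      }
    }
    for (int d = 0; d < dim; ++d) vu[d] += grad[d];
  }
  for (int c = 0; c < nchunk; ++c) loss[c] /= std::max(1.0, terms[c]);

  NumericMatrix emb(n_nodes, dim);
  for (int v2 = 0; v2 < n_nodes; ++v2)
    for (int d = 0; d < dim; ++d) emb(v2, d) = vert[(size_t)v2 * dim + d];
  return List::create(_["embedding"] = emb, _["loss"] = loss);
}
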