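// Binary graph diagnostics on adjacency matrices, plus a density-sweep
// driver. Kernels are compiled because the analysis evaluates diagnostics on
// ensembles of ~10^5-10^7 small graphs (trials x network kinds x densities);
// a shared workspace keeps the hot path allocation-free.
#include <RcppArmadillo.h>
#include <cmath>
#include <vector>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef std::vector<std::vector<int> > AdjList;

// Small deterministic PRNG (xorshift64*), independent of R's RNG so that
// seeded kernels are reproducible regardless of calling context.
struct XRng {
  uint64_t s;
  explicit XRng(int seed) : s((uint64_t)seed * 2685821657736338717ULL + 1ULL) {
    next(); next();
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n) % n; }
};

// Reusable buffers sized to the node count.
struct GraphWS {
  int n;
  std::vector<int> dist, sigma, q, porder, predflat, predcnt, sub_nb,
      sub_dist, sub_q, order, map;
  std::vector<double> delta, cl, Lmat, dsum;
  std::vector<char> alive, seen, subadj, active;
  void init(int n_) {
    n = n_;
    dist.assign(n, 0); sigma.assign(n, 0); q.assign(n, 0);
    porder.assign(n, 0); predflat.assign((size_t)n * n, 0);
    predcnt.assign(n, 0); sub_nb.assign(n, 0); sub_dist.assign(n, 0);
    sub_q.assign(n, 0); order.assign(n, 0); map.assign(n, -1);
    delta.assign(n, 0.0); cl.assign(n, 0.0);
    Lmat.assign((size_t)n * n, 0.0); dsum.assign(n, 0.0);
    alive.assign(n, 1); seen.assign(n, 0);
    subadj.assign((size_t)n * n, 0); active.assign(n, 1);
  }
};

static void bfs(const AdjList &adj, int s, std::vector<int> &dist,
                std::vector<int> &q) {
  int n = adj.size();
  std::fill(dist.begin(), dist.begin() + n, -1);
  int head = 0, tail = 0;
  dist[s] = 0;
  q[tail++] = s;
  while (head < tail) {
    int v = q[head++];
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int w = adj[v][k];
      if (dist[w] < 0) { dist[w] = dist[v] + 1; q[tail++] = w; }
    }
  }
}

// Size of the largest connected component among alive nodes.
static int largest_component(const AdjList &adj, const std::vector<char> &alive,
                             GraphWS &ws) {
  int n = adj.size(), best = 0;
  std::fill(ws.seen.begin(), ws.seen.begin() + n, 0);
  for (int s = 0; s < n; ++s) {
    if (!alive[s] || ws.seen[s]) continue;
    int head = 0, tail = 0, sz = 0;
    ws.q[tail++] = s;
    ws.seen[s] = 1;
    while (head < tail) {
      int v = ws.q[head++];
      ++sz;
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (alive[w] && !ws.seen[w]) { ws.seen[w] = 1; ws.q[tail++] = w; }
      }
    }
    if (sz > best) best = sz;
  }
  return best;
}

static void local_clustering(const AdjList &adj, GraphWS &ws) {
  int n = adj.size();
  // adjacency indicator for O(1) edge tests
  std::fill(ws.subadj.begin(), ws.subadj.begin() + (size_t)n * n, 0);
  for (int v = 0; v < n; ++v)
    for (size_t k = 0; k < adj[v].size(); ++k)
      ws.subadj[(size_t)v * n + adj[v][k]] = 1;
  for (int v = 0; v < n; ++v) {
    int k = adj[v].size();
    if (k < 2) { ws.cl[v] = 0.0; continue; }
    int tri = 0;
    for (int a = 0; a < k; ++a) {
      const size_t row = (size_t)adj[v][a] * n;
      for (int b = a + 1; b < k; ++b) tri += ws.subadj[row + adj[v][b]];
    }
    ws.cl[v] = 2.0 * tri / (k * (double)(k - 1));
  }
}

// Brandes betweenness (unweighted), each unordered pair counted once,
// normalized by (n-1)(n-2)/2. Result left in ws.delta? No: returned in out.
static void betweenness_norm(const AdjList &adj, GraphWS &ws,
                             std::vector<double> &out) {
  int n = adj.size();
  out.assign(n, 0.0);
  for (int s = 0; s < n; ++s) {
    std::fill(ws.dist.begin(), ws.dist.begin() + n, -1);
    std::fill(ws.sigma.begin(), ws.sigma.begin() + n, 0);
    std::fill(ws.delta.begin(), ws.delta.begin() + n, 0.0);
    std::fill(ws.predcnt.begin(), ws.predcnt.begin() + n, 0);
    int head = 0, tail = 0;
    ws.dist[s] = 0; ws.sigma[s] = 1; ws.q[tail++] = s;
    while (head < tail) {
      int v = ws.q[head++];
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (ws.dist[w] < 0) { ws.dist[w] = ws.dist[v] + 1; ws.q[tail++] = w; }
        if (ws.dist[w] == ws.dist[v] + 1) {
          ws.sigma[w] += ws.sigma[v];
          ws.predflat[(size_t)w * n + ws.predcnt[w]++] = v;
        }
      }
    }
    for (int idx = tail - 1; idx >= 0; --idx) {
      int w = ws.q[idx];
      for (int k = 0; k < ws.predcnt[w]; ++k) {
        int v = ws.predflat[(size_t)w * n + k];
        ws.delta[v] += ((double)ws.sigma[v] / ws.sigma[w]) * (1.0 + ws.delta[w]);
      }
      if (w != s) out[w] += ws.delta[w];
    }
  }
  double norm = (n - 1.0) * (n - 2.0) / 2.0;
  for (int v = 0; v < n; ++v) out[v] = (norm > 0) ? out[v] / 2.0 / norm : 0.0;
}

struct BasicMetrics {
  double L, C, Eglob, Eloc, B, assort;
  bool connected;
};

static BasicMetrics basic_metrics_core(const AdjList &adj, GraphWS &ws) {
  int n = adj.size();
  BasicMetrics m;
  double sumd = 0.0, suminv = 0.0;
  long npairs_conn = 0, npairs_all = (long)n * (n - 1);
  for (int s = 0; s < n; ++s) {
    bfs(adj, s, ws.dist, ws.q);
    for (int t = 0; t < n; ++t) {
      if (t == s) continue;
      if (ws.dist[t] > 0) {
        sumd += ws.dist[t];
        suminv += 1.0 / ws.dist[t];
        ++npairs_conn;
      }
    }
  }
  m.connected = (npairs_conn == npairs_all);
  m.L = npairs_conn > 0 ? sumd / npairs_conn : NA_REAL;
  m.Eglob = npairs_all > 0 ? suminv / npairs_all : NA_REAL;

  local_clustering(adj, ws);  // also fills ws.subadj indicator
  double csum = 0.0;
  for (int v = 0; v < n; ++v) csum += ws.cl[v];
  m.C = csum / n;

  // Local efficiency: global efficiency of each node's neighborhood
  // subgraph (nodes of degree < 2 contribute 0).
  double elsum = 0.0;
  for (int v = 0; v < n; ++v) {
    int k = adj[v].size();
    if (k < 2) continue;
    for (int a = 0; a < k; ++a) ws.map[adj[v][a]] = a;
    double sinv = 0.0;
    for (int a = 0; a < k; ++a) {
      // BFS within the neighborhood subgraph from neighbor a
      std::fill(ws.sub_dist.begin(), ws.sub_dist.begin() + k, -1);
      int head = 0, tail = 0;
      ws.sub_dist[a] = 0;
      ws.sub_q[tail++] = a;
      while (head < tail) {
        int u = ws.sub_q[head++];
        int gu = adj[v][u];
        const size_t row = (size_t)gu * n;
        for (int b = 0; b < k; ++b) {
          if (ws.sub_dist[b] < 0 && ws.subadj[row + adj[v][b]]) {
            ws.sub_dist[b] = ws.sub_dist[u] + 1;
            ws.sub_q[tail++] = b;
          }
        }
      }
      for (int b = 0; b < k; ++b)
        if (b != a && ws.sub_dist[b] > 0) sinv += 1.0 / ws.sub_dist[b];
    }
    for (int a = 0; a < k; ++a) ws.map[adj[v][a]] = -1;
    elsum += sinv / ((double)k * (k - 1));
  }
  m.Eloc = elsum / n;

  static thread_local std::vector<double> bt;
  betweenness_norm(adj, ws, bt);
  double bsum = 0.0;
  for (int v = 0; v < n; ++v) bsum += bt[v];
  m.B = bsum / n;

  // Degree assortativity: Pearson correlation over ordered edge endpoints.
  double sx = 0, sxx = 0, sxy = 0;
  long e2 = 0;
  for (int v = 0; v < n; ++v) {
    double kv = adj[v].size();
    for (size_t k = 0; k < adj[v].size(); ++k) {
      double kw = adj[adj[v][k]].size();
      sx += kv; sxx += kv * kv; sxy += kv * kw; ++e2;
    }
  }
  if (e2 == 0) {
    m.assort = NA_REAL;
  } else {
    double mx = sx / e2, varx = sxx / e2 - mx * mx, cov = sxy / e2 - mx * mx;
    m.assort = (varx > 1e-12) ? cov / varx : NA_REAL;
  }
  return m;
}

// Greedy agglomerative modularity with seeded random tie-breaking restarts
// (restart 0 is deterministic), followed by single-node move refinement of
// the best partition found along each merge path.
static double modularity_of(const AdjList &adj, const std::vector<int> &mem,
                            double m) {
  int n = adj.size();
  int ncomm = 0;
  for (int v = 0; v < n; ++v) ncomm = std::max(ncomm, mem[v] + 1);
  std::vector<double> lc(ncomm, 0.0), dc(ncomm, 0.0);
  for (int v = 0; v < n; ++v) {
    dc[mem[v]] += adj[v].size();
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int w = adj[v][k];
      if (v < w && mem[v] == mem[w]) lc[mem[v]] += 1.0;
    }
  }
  double Q = 0.0;
  for (int c = 0; c < ncomm; ++c)
    Q += lc[c] / m - (dc[c] / (2 * m)) * (dc[c] / (2 * m));
  return Q;
}

// Kernighan-Lin style refinement: greedily move single nodes between
// communities (or to a fresh singleton) while modularity improves.
static void refine_partition(const AdjList &adj, std::vector<int> &mem,
                             double m) {
  int n = adj.size();
  bool improved = true;
  int guard = 0;
  while (improved && guard++ < 4 * n) {
    improved = false;
    for (int v = 0; v < n; ++v) {
      int cv = mem[v];
      double kv = adj[v].size();
      // links from v to each community; total degree per community
      std::vector<double> lv(n + 1, 0.0), dcom(n + 1, 0.0);
      for (int u = 0; u < n; ++u)
        if (u != v) dcom[mem[u]] += adj[u].size();
      for (size_t k = 0; k < adj[v].size(); ++k) lv[mem[adj[v][k]]] += 1.0;
      // candidate targets: neighboring communities and a fresh singleton
      int fresh = -1;
      for (int c = 0; c < n + 1; ++c)
        if (dcom[c] == 0.0 && lv[c] == 0.0 && c != cv) { fresh = c; break; }
      double base = -lv[cv] / m + kv * dcom[cv] / (2.0 * m * m);
      int best_c = cv;
      double best_gain = 0.0;
      for (size_t k = 0; k <= adj[v].size(); ++k) {
        int c;
        if (k < adj[v].size()) c = mem[adj[v][k]];
        else if (fresh >= 0) c = fresh;
        else break;
        if (c == cv) continue;
        double gain = base + lv[c] / m - kv * (dcom[c] + kv) / (2.0 * m * m) +
                      kv * kv / (2.0 * m * m);
        if (gain > best_gain + 1e-12) { best_gain = gain; best_c = c; }
      }
      if (best_c != cv) { mem[v] = best_c; improved = true; }
    }
  }
}

static double modularity_core(const AdjList &adj, int restarts, int seed,
                              GraphWS &ws) {
  int n = adj.size();
  long m2 = 0;
  for (int v = 0; v < n; ++v) m2 += adj[v].size();
  double m = m2 / 2.0;
  if (m <= 0) return NA_REAL;
  double bestQ = -1.0;
  std::vector<std::pair<int, int> > ties;
  std::vector<int> mem(n), best_mem(n);
  for (int r = 0; r < std::max(1, restarts); ++r) {
    XRng rng(seed + 7919 * r);
    std::fill(ws.Lmat.begin(), ws.Lmat.begin() + (size_t)n * n, 0.0);
    std::fill(ws.active.begin(), ws.active.begin() + n, 1);
    for (int v = 0; v < n; ++v) {
      mem[v] = v;
      ws.dsum[v] = adj[v].size();
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (v < w) {
          ws.Lmat[(size_t)v * n + w] += 1.0;
          ws.Lmat[(size_t)w * n + v] += 1.0;
        }
      }
    }
    double Q = 0.0;
    for (int v = 0; v < n; ++v)
      Q -= (ws.dsum[v] / (2 * m)) * (ws.dsum[v] / (2 * m));
    double best = Q;
    best_mem = mem;
    int ncomm = n;
    std::vector<std::pair<double, std::pair<int, int> > > cand;
    while (ncomm > 1) {
      cand.clear();
      for (int a = 0; a < n; ++a) {
        if (!ws.active[a]) continue;
        for (int b = a + 1; b < n; ++b) {
          if (!ws.active[b] || ws.Lmat[(size_t)a * n + b] <= 0) continue;
          double dq = ws.Lmat[(size_t)a * n + b] / m -
                      ws.dsum[a] * ws.dsum[b] / (2.0 * m * m);
          cand.push_back(std::make_pair(dq, std::make_pair(a, b)));
        }
      }
      if (cand.empty()) break;  // remaining communities disconnected
      std::sort(cand.begin(), cand.end(),
                [](const std::pair<double, std::pair<int, int> > &x,
                   const std::pair<double, std::pair<int, int> > &y) {
                  if (x.first != y.first) return x.first > y.first;
                  return x.second < y.second;
                });
      size_t pick_i = 0;
      if (r > 0) {
        // explore: choose uniformly among merges within the top 3
        // distinct gains (ties included)
        double thr = cand.front().first;
        int distinct = 1;
        size_t lim = 1;
        while (lim < cand.size()) {
          if (cand[lim].first < thr - 1e-12) {
            if (++distinct > 3) break;
            thr = cand[lim].first;
          }
          ++lim;
        }
        pick_i = rng.below((int)lim);
      }
      int a = cand[pick_i].second.first, b = cand[pick_i].second.second;
      Q += cand[pick_i].first;
      for (int c = 0; c < n; ++c) {
        if (!ws.active[c] || c == a || c == b) continue;
        ws.Lmat[(size_t)a * n + c] += ws.Lmat[(size_t)b * n + c];
        ws.Lmat[(size_t)c * n + a] = ws.Lmat[(size_t)a * n + c];
      }
      ws.Lmat[(size_t)a * n + a] +=
          ws.Lmat[(size_t)b * n + b] + ws.Lmat[(size_t)a * n + b];
      ws.dsum[a] += ws.dsum[b];
      ws.active[b] = 0;
      for (int v = 0; v < n; ++v)
        if (mem[v] == b) mem[v] = a;
      --ncomm;
      if (Q > best + 1e-15) { best = Q; best_mem = mem; }
    }
    refine_partition(adj, best_mem, m);
    double refined = modularity_of(adj, best_mem, m);
    if (refined > bestQ) bestQ = refined;
    if (best > bestQ) bestQ = best;
  }
  return bestQ;
}

// Laplacian eigenratio lambda_2 / lambda_max of the largest component.
static double synchronizability_core(const AdjList &adj, GraphWS &ws) {
  int n = adj.size();
  std::fill(ws.seen.begin(), ws.seen.begin() + n, 0);
  std::vector<int> bestcomp;
  for (int s = 0; s < n; ++s) {
    if (ws.seen[s]) continue;
    int head = 0, tail = 0;
    ws.q[tail++] = s;
    ws.seen[s] = 1;
    std::vector<int> comp;
    while (head < tail) {
      int v = ws.q[head++];
      comp.push_back(v);
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (!ws.seen[w]) { ws.seen[w] = 1; ws.q[tail++] = w; }
      }
    }
    if (comp.size() > bestcomp.size()) bestcomp.swap(comp);
  }
  int c = bestcomp.size();
  if (c < 3) return NA_REAL;
  std::fill(ws.map.begin(), ws.map.begin() + n, -1);
  for (int i = 0; i < c; ++i) ws.map[bestcomp[i]] = i;
  arma::mat Lap(c, c, arma::fill::zeros);
  for (int i = 0; i < c; ++i) {
    int v = bestcomp[i];
    Lap(i, i) = adj[v].size();
    for (size_t k = 0; k < adj[v].size(); ++k)
      Lap(i, ws.map[adj[v][k]]) = -1.0;
  }
  for (int i = 0; i < c; ++i) ws.map[bestcomp[i]] = -1;
  arma::vec ev;
  if (!arma::eig_sym(ev, Lap)) return NA_REAL;
  double l2 = ev(1), lmax = ev(c - 1);
  if (lmax <= 1e-12) return NA_REAL;
  return l2 / lmax;
}

// Attack robustness: mean largest-component fraction over the N removal
// steps (fraction of the ORIGINAL node count, recorded before each removal).
static double robustness_core(const AdjList &adj, bool targeted, int n_orders,
                              int seed, GraphWS &ws) {
  int n = adj.size();
  if (n < 2) return NA_REAL;
  int reps = targeted ? 1 : std::max(1, n_orders);
  double auc_total = 0.0;
  for (int r = 0; r < reps; ++r) {
    std::fill(ws.alive.begin(), ws.alive.begin() + n, 1);
    if (!targeted) {
      XRng rng(seed + 104729 * r);
      for (int i = 0; i < n; ++i) ws.order[i] = i;
      for (int i = n - 1; i > 0; --i)
        std::swap(ws.order[i], ws.order[rng.below(i + 1)]);
    }
    double frac_sum = 0.0;
    for (int step = 0; step < n; ++step) {
      frac_sum += (double)largest_component(adj, ws.alive, ws) / n;
      int victim;
      if (targeted) {
        int kmax = -1;
        victim = -1;
        for (int v = 0; v < n; ++v) {
          if (!ws.alive[v]) continue;
          int k = 0;
          for (size_t a = 0; a < adj[v].size(); ++a) k += ws.alive[adj[v][a]];
          if (k > kmax) { kmax = k; victim = v; }
        }
      } else {
        victim = ws.order[step];
      }
      ws.alive[victim] = 0;
    }
    auc_total += frac_sum / n;
  }
  return auc_total / reps;
}

static double mcd_core(const AdjList &adj, const double *co, int n, int D) {
  double s = 0.0;
  long e = 0;
  for (int i = 0; i < n; ++i)
    for (size_t k = 0; k < adj[i].size(); ++k) {
      int j = adj[i][k];
      if (j <= i) continue;
      double d2 = 0.0;
      for (int d = 0; d < D; ++d) {
        double dd = co[i + (size_t)d * n] - co[j + (size_t)d * n];
        d2 += dd * dd;
      }
      s += std::sqrt(d2);
      ++e;
    }
  return e > 0 ? s / e : NA_REAL;
}

// Node membership of sampled axis-aligned boxes, reusable across densities
// (membership depends only on the layout).
struct RentBoxes {
  std::vector<std::vector<char> > inside;  // usable boxes only
  std::vector<int> count;
  void sample(const double *co, int n, int D, int n_boxes, int seed) {
    inside.clear();
    count.clear();
    std::vector<double> lo(D, R_PosInf), hi(D, R_NegInf);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < D; ++d) {
        lo[d] = std::min(lo[d], co[i + (size_t)d * n]);
        hi[d] = std::max(hi[d], co[i + (size_t)d * n]);
      }
    XRng rng(seed);
    std::vector<double> blo(D), bhi(D);
    std::vector<char> in(n);
    for (int b = 0; b < n_boxes; ++b) {
      for (int d = 0; d < D; ++d) {
        double u1 = lo[d] + rng.unif() * (hi[d] - lo[d]);
        double u2 = lo[d] + rng.unif() * (hi[d] - lo[d]);
        blo[d] = std::min(u1, u2);
        bhi[d] = std::max(u1, u2);
      }
      int cnt = 0;
      for (int i = 0; i < n; ++i) {
        char ok = 1;
        for (int d = 0; d < D; ++d) {
          double x = co[i + (size_t)d * n];
          if (x < blo[d] || x > bhi[d]) { ok = 0; break; }
        }
        in[i] = ok;
        cnt += ok;
      }
      if (cnt < 2 || cnt > n / 2) continue;
      inside.push_back(in);
      count.push_back(cnt);
    }
  }
};

// log(crossing edges) ~ log(enclosed nodes) slope over usable boxes.
static double rent_from_boxes(const RentBoxes &boxes,
                              const std::vector<std::pair<int, int> > &edges,
                              long n_edges, int n) {
  if (n < 8 || n_edges < 8) return NA_REAL;
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  int used = 0;
  for (size_t b = 0; b < boxes.inside.size(); ++b) {
    const std::vector<char> &in = boxes.inside[b];
    int cross = 0;
    for (long e = 0; e < n_edges; ++e)
      if (in[edges[e].first] != in[edges[e].second]) ++cross;
    if (cross < 1) continue;
    double x = std::log((double)boxes.count[b]);
    double y = std::log((double)cross);
    sx += x; sy += y; sxx += x * x; sxy += x * y;
    ++used;
  }
  if (used < 30) return NA_REAL;
  double mx = sx / used, varx = sxx / used - mx * mx;
  if (varx < 1e-12) return NA_REAL;
  return (sxy / used - mx * sy / used) / varx;
}

static double hierarchy_core(const AdjList &adj, GraphWS &ws,
                             bool cl_valid = false) {
  int n = adj.size();
  if (!cl_valid) local_clustering(adj, ws);
  std::vector<double> csum(n + 1, 0.0);
  std::vector<int> cnt(n + 1, 0);
  for (int v = 0; v < n; ++v) {
    int k = adj[v].size();
    if (k >= 2) { csum[k] += ws.cl[v]; cnt[k]++; }
  }
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  int used = 0;
  for (int k = 2; k <= n; ++k) {
    if (cnt[k] == 0) continue;
    double cbar = csum[k] / cnt[k];
    if (cbar <= 0) continue;
    double x = std::log((double)k), y = std::log(cbar);
    sx += x; sy += y; sxx += x * x; sxy += x * y;
    ++used;
  }
  if (used < 2) return NA_REAL;
  double mx = sx / used, varx = sxx / used - mx * mx;
  if (varx < 1e-12) return NA_REAL;
  return -(sxy / used - mx * sy / used) / varx;
}

static AdjList adj_from_matrix(const IntegerMatrix &A) {
  int n = A.nrow();
  AdjList adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && A(i, j) != 0) adj[i].push_back(j);
  return adj;
}

// ---- exported single-graph wrappers -------------------------------------

// [[Rcpp::export]]
List cpp_basic_metrics(IntegerMatrix A) {
  AdjList adj = adj_from_matrix(A);
  GraphWS ws;
  ws.init(adj.size());
  BasicMetrics m = basic_metrics_core(adj, ws);
  std::vector<double> bt;
  betweenness_norm(adj, ws, bt);
  local_clustering(adj, ws);
  return List::create(
      _["path_length"] = m.L, _["clustering"] = m.C,
      _["global_efficiency"] = m.Eglob, _["local_efficiency"] = m.Eloc,
      _["betweenness"] = m.B, _["assortativity"] = m.assort,
      _["connected"] = m.connected,
      _["betweenness_nodes"] = NumericVector(bt.begin(), bt.end()),
      _["clustering_nodes"] = NumericVector(ws.cl.begin(),
                                            ws.cl.begin() + adj.size()));
}

// [[Rcpp::export]]
double cpp_modularity(IntegerMatrix A, int restarts, int seed) {
  AdjList adj = adj_from_matrix(A);
  GraphWS ws;
  ws.init(adj.size());
  return modularity_core(adj, restarts, seed, ws);
}

// [[Rcpp::export]]
double cpp_synchronizability(IntegerMatrix A) {
  AdjList adj = adj_from_matrix(A);
  GraphWS ws;
  ws.init(adj.size());
  return synchronizability_core(adj, ws);
}

// [[Rcpp::export]]
double cpp_robustness(IntegerMatrix A, bool targeted, int n_orders, int seed) {
  AdjList adj = adj_from_matrix(A);
  GraphWS ws;
  ws.init(adj.size());
  return robustness_core(adj, targeted, n_orders, seed, ws);
}

// [[Rcpp::export]]
double cpp_mean_connection_distance(IntegerMatrix A, NumericMatrix coords) {
  AdjList adj = adj_from_matrix(A);
  return mcd_core(adj, REAL(coords), adj.size(), coords.ncol());
}

// [[Rcpp::export]]
double cpp_rent(IntegerMatrix A, NumericMatrix coords, int n_boxes, int seed) {
  AdjList adj = adj_from_matrix(A);
  int n = adj.size();
  RentBoxes boxes;
  boxes.sample(REAL(coords), n, coords.ncol(), n_boxes, seed);
  std::vector<std::pair<int, int> > edges;
  for (int v = 0; v < n; ++v)
    for (size_t k = 0; k < adj[v].size(); ++k)
      if (v < adj[v][k]) edges.push_back(std::make_pair(v, adj[v][k]));
  return rent_from_boxes(boxes, edges, edges.size(), n);
}

// [[Rcpp::export]]
double cpp_hierarchy(IntegerMatrix A) {
  AdjList adj = adj_from_matrix(A);
  GraphWS ws;
  ws.init(adj.size());
  return hierarchy_core(adj, ws);
}

// Pre-sample Rent boxes for a layout once; membership depends only on the
// coordinates, so the same boxes serve every trial, kind and density.
// [[Rcpp::export]]
SEXP cpp_make_rent_boxes(NumericMatrix coords, int n_boxes, int seed) {
  RentBoxes *boxes = new RentBoxes();
  boxes->sample(REAL(coords), coords.nrow(), coords.ncol(), n_boxes, seed);
  return XPtr<RentBoxes>(boxes, true);
}

// ---- density sweep --------------------------------------------------------

// Cumulatively threshold W over the kappa grid and evaluate all 13
// diagnostics at every density. Ties in W broken by lexicographic (i, j).
// Columns: L, C, Eglob, Eloc, B, Q, hierarchy, sync, assort, Rt, Rr, MCD,
// rent. Rent boxes are sampled once per call and shared across densities.
// [[Rcpp::export]]
NumericMatrix cpp_diag_sweep(NumericMatrix W, NumericMatrix coords,
                             NumericVector kappas, int mod_restarts,
                             int rand_orders, int rent_boxes, int seed,
                             bool do_physical,
                             SEXP box_cache = R_NilValue) {
  int n = W.nrow();
  long M = (long)n * (n - 1) / 2;
  std::vector<std::pair<double, std::pair<int, int> > > ed;
  ed.reserve(M);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      ed.push_back(std::make_pair(W(i, j), std::make_pair(i, j)));
  std::stable_sort(ed.begin(), ed.end(),
                   [](const std::pair<double, std::pair<int, int> > &a,
                      const std::pair<double, std::pair<int, int> > &b) {
                     if (a.first != b.first) return a.first > b.first;
                     return a.second < b.second;
                   });
  GraphWS ws;
  ws.init(n);
  RentBoxes local_boxes;
  const RentBoxes *boxes = &local_boxes;
  if (do_physical) {
    if (box_cache != R_NilValue) {
      XPtr<RentBoxes> xp(box_cache);
      boxes = xp.get();
    } else {
      local_boxes.sample(REAL(coords), n, coords.ncol(), rent_boxes, seed);
    }
  }
  int nk = kappas.size();
  NumericMatrix out(nk, 13);
  AdjList adj(n);
  std::vector<std::pair<int, int> > edges;
  long cur = 0;
  for (int q = 0; q < nk; ++q) {
    long target = (long)std::floor(kappas[q] * M + 1e-9);
    if (target > M) target = M;
    for (; cur < target; ++cur) {
      int i = ed[cur].second.first, j = ed[cur].second.second;
      adj[i].push_back(j);
      adj[j].push_back(i);
      edges.push_back(std::make_pair(i, j));
    }
    if (cur == 0) {
      for (int c = 0; c < 13; ++c) out(q, c) = NA_REAL;
      continue;
    }
    BasicMetrics m = basic_metrics_core(adj, ws);
    out(q, 0) = m.L;
    out(q, 1) = m.C;
    out(q, 2) = m.Eglob;
    out(q, 3) = m.Eloc;
    out(q, 4) = m.B;
    out(q, 6) = hierarchy_core(adj, ws, true);  // ws.cl from basic metrics
    out(q, 5) = modularity_core(adj, mod_restarts, seed + 11 * q, ws);
    out(q, 7) = synchronizability_core(adj, ws);
    out(q, 8) = m.assort;
    out(q, 9) = robustness_core(adj, true, 1, seed, ws);
    out(q, 10) = robustness_core(adj, false, rand_orders, seed + 31 * q, ws);
    if (do_physical) {
      out(q, 11) = mcd_core(adj, REAL(coords), n, coords.ncol());
      out(q, 12) = rent_from_boxes(*boxes, edges, edges.size(), n);
    } else {
      out(q, 11) = NA_REAL;
      out(q, 12) = NA_REAL;
    }
  }
  return out;
}
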