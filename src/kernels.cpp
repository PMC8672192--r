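#include <Rcpp.h>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Compressed adjacency for the simulation engines.  `edges` is a two-column
// matrix of 1-based endpoints; the graph is simple and undirected.
static void build_csr(int n, const IntegerMatrix& edges,
                      std::vector<int>& ptr, std::vector<int>& adj) {
  const int m = edges.nrow();
  std::vector<int> deg(n + 1, 0);
  for (int e = 0; e < m; ++e) {
    ++deg[edges(e, 0)];
    ++deg[edges(e, 1)];
  }
  ptr.assign(n + 2, 0);
  for (int v = 1; v <= n; ++v) ptr[v + 1] = ptr[v] + deg[v];
  adj.assign(2L * m, 0);
  std::vector<int> fill(n + 1, 0);
  for (int e = 0; e < m; ++e) {
    const int a = edges(e, 0), b = edges(e, 1);
    adj[ptr[a] + fill[a]++] = b;
    adj[ptr[b] + fill[b]++] = a;
  }
}

// Discrete-time SIR (snapshot semantics).  Nodes infected at the start of an
// iteration attack each still-susceptible neighbour with an independent
// Bernoulli(beta) trial, then recover with probability gamma.  Nodes infected
// within the iteration neither transmit nor recover until the next one.
// Uses R's RNG (seed with set.seed() before calling).
// [[Rcpp::export]]
List cpp_run_sir(int n, IntegerMatrix edges, IntegerVector init,
                 double beta, double gamma, int max_iters,
                 bool record_states) {
  std::vector<int> ptr, adj;
  build_csr(n, edges, ptr, adj);

  std::vector<char> state(n + 1, 0);  // 0 = S, 1 = I, 2 = R
  std::vector<int> infected(init.begin(), init.end());
  for (int j : infected) state[j] = 1;
  int nI = (int)infected.size(), nR = 0;

  std::vector<int> S_t, I_t, R_t;
  S_t.push_back(n - nI); I_t.push_back(nI); R_t.push_back(0);

  std::vector<IntegerVector> traj;
  if (record_states) {
    IntegerVector s0(n);
    for (int v = 1; v <= n; ++v) s0[v - 1] = state[v];
    traj.push_back(s0);
  }

  int stabilized = NA_INTEGER;
  if (nI == 0) stabilized = 0;

  for (int it = 1; it <= max_iters && nI > 0; ++it) {
    std::vector<int> next, newly;
    next.reserve(infected.size());
    for (size_t a = 0; a < infected.size(); ++a) {
      const int j = infected[a];
      for (int t = ptr[j]; t < ptr[j + 1]; ++t) {
        const int k = adj[t];
        if (state[k] == 0 && unif_rand() < beta) {
          state[k] = 1;
          newly.push_back(k);
        }
      }
      if (unif_rand() < gamma) {
        state[j] = 2; ++nR; --nI;
      } else {
        next.push_back(j);
      }
    }
    nI += (int)newly.size();
    for (int k : newly) next.push_back(k);
    infected.swap(next);

    S_t.push_back(n - nI - nR); I_t.push_back(nI); R_t.push_back(nR);
    if (record_states) {
      IntegerVector st(n);
      for (int v = 1; v <= n; ++v) st[v - 1] = state[v];
      traj.push_back(st);
    }
    if (nI == 0) { stabilized = it; break; }
  }

  List out = List::create(_["S"] = S_t, _["I"] = I_t, _["R"] = R_t,
                          _["stabilized_at"] = stabilized);
  if (record_states) {
    List tr(traj.size());
    for (size_t i = 0; i < traj.size(); ++i) tr[i] = traj[i];
    out["states"] = tr;
  }
  return out;
}

// Synchronous Threshold cascade: a susceptible node with degree > 0 activates
// when strictly more than `threshold` of its neighbours were infected at the
// start of the iteration.  Deterministic given the seed set.
// [[Rcpp::export]]
List cpp_run_threshold(int n, IntegerMatrix edges, IntegerVector init,
                       double threshold, int max_iters, bool record_states) {
  std::vector<int> ptr, adj;
  build_csr(n, edges, ptr, adj);

  std::vector<char> inf(n + 1, 0);
  std::vector<int> cnt(n + 1, 0);
  for (int j : init) inf[j] = 1;
  for (int j : init)
    for (int t = ptr[j]; t < ptr[j + 1]; ++t) ++cnt[adj[t]];
  int nI = init.size();

  std::vector<int> S_t, I_t;
  S_t.push_back(n - nI); I_t.push_back(nI);

  std::vector<IntegerVector> traj;
  if (record_states) {
    IntegerVector s0(n);
    for (int v = 1; v <= n; ++v) s0[v - 1] = inf[v];
    traj.push_back(s0);
  }

  int stabilized = NA_INTEGER;
  for (int it = 1; it <= max_iters; ++it) {
    std::vector<int> newly;
    for (int v = 1; v <= n; ++v) {
      if (inf[v]) continue;
      const int deg = ptr[v + 1] - ptr[v];
      if (deg > 0 && (double)cnt[v] > threshold * (double)deg)
        newly.push_back(v);
    }
    if (newly.empty()) { stabilized = it - 1; break; }
    for (int v : newly) inf[v] = 1;
    for (int v : newly)
      for (int t = ptr[v]; t < ptr[v + 1]; ++t) ++cnt[adj[t]];
    nI += (int)newly.size();
    S_t.push_back(n - nI); I_t.push_back(nI);
    if (record_states) {
      IntegerVector st(n);
      for (int v = 1; v <= n; ++v) st[v - 1] = inf[v];
      traj.push_back(st);
    }
  }

  List out = List::create(_["S"] = S_t, _["I"] = I_t,
                          _["stabilized_at"] = stabilized);
  if (record_states) {
    List tr(traj.size());
    for (size_t i = 0; i < traj.size(); ++i) tr[i] = traj[i];
    out["states"] = tr;
  }
  return out;
}

// Shared-neighbour proportion of i and j on a live adjacency, ignoring any
// direct i-j edge: with A = N(i)\{j}, B = N(j)\{i}, S = A n B, returns
// max(|S|/|A|, |S|/|B|); zero-denominator ratios count as 0.
static double shared_prop(const std::vector<std::unordered_set<int> >& adj,
                          int i, int j) {
  const std::unordered_set<int>& A = adj[i];
  const std::unordered_set<int>& B = adj[j];
  const int sA = (int)A.size() - (A.count(j) ? 1 : 0);
  const int sB = (int)B.size() - (B.count(i) ? 1 : 0);
  if (sA == 0 && sB == 0) return 0.0;
  const std::unordered_set<int>& small = (A.size() <= B.size()) ? A : B;
  const std::unordered_set<int>& big = (A.size() <= B.size()) ? B : A;
  int sh = 0;
  for (std::unordered_set<int>::const_iterator it = small.begin();
       it != small.end(); ++it) {
    const int x = *it;
    if (x == i || x == j) continue;
    if (big.count(x)) ++sh;
  }
  const double r1 = sA ? (double)sh / sA : 0.0;
  const double r2 = sB ? (double)sh / sB : 0.0;
  return r1 > r2 ? r1 : r2;
}

// Merge node j into node i: every edge of j is reattached to i; self-loops
// and parallel edges are dropped; j is deleted.
static void merge_into(std::vector<std::unordered_set<int> >& adj,
                       int i, int j) {
  for (std::unordered_set<int>::const_iterator it = adj[j].begin();
       it != adj[j].end(); ++it) {
    const int nb = *it;
    adj[nb].erase(j);
    if (nb != i) {
      adj[i].insert(nb);
      adj[nb].insert(i);
    }
  }
  adj[j].clear();
}

static void build_sets(int n, const IntegerMatrix& edges,
                       std::vector<std::unordered_set<int> >& adj) {
  adj.assign(n + 1, std::unordered_set<int>());
  const int m = edges.nrow();
  for (int e = 0; e < m; ++e) {
    adj[edges(e, 0)].insert(edges(e, 1));
    adj[edges(e, 1)].insert(edges(e, 0));
  }
}

static IntegerMatrix collect_edges(int n,
    const std::vector<std::unordered_set<int> >& adj) {
  long m = 0;
  for (int v = 1; v <= n; ++v)
    for (std::unordered_set<int>::const_iterator it = adj[v].begin();
         it != adj[v].end(); ++it)
      if (*it > v) ++m;
  IntegerMatrix out(m, 2);
  long e = 0;
  for (int v = 1; v <= n; ++v)
    for (std::unordered_set<int>::const_iterator it = adj[v].begin();
         it != adj[v].end(); ++it)
      if (*it > v) { out(e, 0) = v; out(e, 1) = *it; ++e; }
  return out;
}

// Sequential shared-neighbour aggregation: bins are scanned in ascending
// index, node pairs (i, j), i < j, in ascending label order within each bin;
// whenever the live shared-neighbour proportion strictly exceeds p, j is
// merged into i immediately and the scan continues on the updated graph.
// No transitive-closure reconciliation.
// [[Rcpp::export]]
List cpp_systematic_aggregation(int n, IntegerMatrix edges,
                                IntegerVector bins, double p) {
  std::vector<std::unordered_set<int> > adj;
  build_sets(n, edges, adj);

  int K = 0;
  for (int v = 0; v < n; ++v) if (bins[v] > K) K = bins[v];
  std::vector<std::vector<int> > members(K + 1);
  for (int v = 1; v <= n; ++v) members[bins[v - 1]].push_back(v);

  std::vector<char> alive(n + 1, 1);
  std::vector<int> mbin, msurv, mmerg;
  std::vector<double> mprop;

  for (int k = 1; k <= K; ++k) {
    const std::vector<int>& mem = members[k];
    const int sz = (int)mem.size();
    for (int a = 0; a < sz; ++a) {
      const int i = mem[a];
      if (!alive[i]) continue;
      for (int b = a + 1; b < sz; ++b) {
        const int j = mem[b];
        if (!alive[j]) continue;
        const double pr = shared_prop(adj, i, j);
        if (pr > p) {
          merge_into(adj, i, j);
          alive[j] = 0;
          mbin.push_back(k); msurv.push_back(i); mmerg.push_back(j);
          mprop.push_back(pr);
        }
      }
    }
  }

  IntegerVector alive_out(n);
  for (int v = 1; v <= n; ++v) alive_out[v - 1] = alive[v];
  return List::create(_["edges"] = collect_edges(n, adj),
                      _["alive"] = alive_out,
                      _["bin"] = mbin, _["survivor"] = msurv,
                      _["merged"] = mmerg, _["proportion"] = mprop);
}

// Matched baseline: n_merges successive merges of a uniformly chosen ordered
// pair of distinct survivors (second merged into first).  Uses R's RNG.
// [[Rcpp::export]]
List cpp_random_aggregation(int n, IntegerMatrix edges, int n_merges) {
  std::vector<std::unordered_set<int> > adj;
  build_sets(n, edges, adj);

  std::vector<int> pool(n);
  for (int v = 0; v < n; ++v) pool[v] = v + 1;
  std::vector<int> msurv, mmerg;

  for (int m = 0; m < n_merges; ++m) {
    const int sz = (int)pool.size();
    int ai = (int)(unif_rand() * sz);
    if (ai >= sz) ai = sz - 1;
    int bi = (int)(unif_rand() * (sz - 1));
    if (bi >= sz - 1) bi = sz - 2;
    if (bi >= ai) ++bi;
    const int i = pool[ai], j = pool[bi];
    merge_into(adj, i, j);
    msurv.push_back(i); mmerg.push_back(j);
    pool[bi] = pool.back();
    pool.pop_back();
  }

  std::vector<char> alive(n + 1, 0);
  for (size_t v = 0; v < pool.size(); ++v) alive[pool[v]] = 1;
  IntegerVector alive_out(n);
  for (int v = 1; v <= n; ++v) alive_out[v - 1] = alive[v];
  return List::create(_["edges"] = collect_edges(n, adj),
                      _["alive"] = alive_out,
                      _["survivor"] = msurv, _["merged"] = mmerg);
}
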