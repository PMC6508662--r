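#include <Rcpp.h>
#include <vector>
#include <set>
#include <map>
using namespace Rcpp;

// Generalized Louvain: locally greedy maximization of
//   Q_raw = sum_{p,q} B[p,q] * delta(g_p, g_q)   (ordered pairs, zero diagonal
// at the finest level; aggregated self-loops carry intra-community weight).
// B is any symmetric modularity-coefficient matrix in CSC form; entries may
// be negative, so moves into an empty community are considered alongside
// moves into neighboring communities. Node visiting order is a fresh
// uniform shuffle (R RNG) on every pass; ties between equally improving
// target communities break toward the lowest community id. A move is
// accepted only when it improves Q_raw by more than `tol` (absolute).

struct Graph {
  int n;
  std::vector<int> ptr;     // size n + 1
  std::vector<int> idx;     // neighbor indices
  std::vector<double> w;    // weights
  std::vector<double> self; // self-loop weight per node
};

static double graph_quality(const Graph &g, const std::vector<int> &comm) {
  double q = 0.0;
  for (int v = 0; v < g.n; ++v) {
    q += g.self[v];
    for (int e = g.ptr[v]; e < g.ptr[v + 1]; ++e) {
      if (comm[g.idx[e]] == comm[v]) q += g.w[e];
    }
  }
  return q;
}

// one level of greedy node moves; returns true if any node moved
static bool local_moves(const Graph &g, std::vector<int> &comm, double tol) {
  const int n = g.n;
  std::vector<int> comm_size(n, 0);
  for (int v = 0; v < n; ++v) comm_size[comm[v]]++;
  std::set<int> empty_comms;
  for (int c = 0; c < n; ++c) if (comm_size[c] == 0) empty_comms.insert(c);

  std::vector<double> link(n, 0.0); // weight from v to each community
  std::vector<int> touched;
  touched.reserve(64);

  bool any_move = false;
  bool improved = true;
  int pass = 0;
  while (improved && pass < 1000) {
    improved = false;
    ++pass;
    IntegerVector ord = sample(n, n, false); // R RNG, 1-based
    for (int t = 0; t < n; ++t) {
      int v = ord[t] - 1;
      int a = comm[v];
      touched.clear();
      for (int e = g.ptr[v]; e < g.ptr[v + 1]; ++e) {
        int u = g.idx[e];
        if (u == v) continue;
        int c = comm[u];
        if (link[c] == 0.0) touched.push_back(c);
        link[c] += g.w[e];
      }
      double d_own = 0.0;
      for (size_t k = 0; k < touched.size(); ++k) {
        if (touched[k] == a) { d_own = link[a]; break; }
      }
      // candidate communities: touched ones, plus one empty community
      int best_c = a;
      double best_gain = 0.0;
      for (size_t k = 0; k < touched.size(); ++k) {
        int c = touched[k];
        if (c == a) continue;
        double gain = link[c] - d_own;
        if (gain > best_gain || (gain == best_gain && c < best_c)) {
          best_gain = gain;
          best_c = c;
        }
      }
      if (comm_size[a] > 1 && !empty_comms.empty()) {
        // moving v to a fresh (empty) community gains -d_own
        double gain = -d_own;
        int c = *empty_comms.begin();
        if (gain > best_gain || (gain == best_gain && best_c != a && c < best_c)) {
          best_gain = gain;
          best_c = c;
        }
      }
      if (best_c != a && best_gain > tol) {
        comm[v] = best_c;
        comm_size[a]--;
        comm_size[best_c]++;
        if (comm_size[a] == 0) empty_comms.insert(a);
        if (comm_size[best_c] == 1) empty_comms.erase(best_c);
        improved = true;
        any_move = true;
      }
      for (size_t k = 0; k < touched.size(); ++k) link[touched[k]] = 0.0;
    }
  }
  return any_move;
}

// relabel communities to 0..C-1 (order of first appearance); return C
static int renumber(std::vector<int> &comm) {
  std::map<int, int> remap;
  int next = 0;
  for (size_t v = 0; v < comm.size(); ++v) {
    std::map<int, int>::iterator it = remap.find(comm[v]);
    if (it == remap.end()) {
      remap[comm[v]] = next;
      comm[v] = next++;
    } else {
      comm[v] = it->second;
    }
  }
  return next;
}

static Graph aggregate(const Graph &g, const std::vector<int> &comm, int nc) {
  std::vector< std::map<int, double> > rows(nc);
  std::vector<double> self(nc, 0.0);
  for (int v = 0; v < g.n; ++v) self[comm[v]] += g.self[v];
  for (int v = 0; v < g.n; ++v) {
    int cv = comm[v];
    for (int e = g.ptr[v]; e < g.ptr[v + 1]; ++e) {
      int cu = comm[g.idx[e]];
      if (cu == cv) self[cv] += g.w[e]; // ordered pairs: both directions land here
      else rows[cv][cu] += g.w[e];
    }
  }
  Graph out;
  out.n = nc;
  out.self = self;
  out.ptr.assign(nc + 1, 0);
  for (int c = 0; c < nc; ++c) out.ptr[c + 1] = out.ptr[c] + (int)rows[c].size();
  out.idx.resize(out.ptr[nc]);
  out.w.resize(out.ptr[nc]);
  for (int c = 0; c < nc; ++c) {
    int at = out.ptr[c];
    for (std::map<int, double>::iterator it = rows[c].begin(); it != rows[c].end(); ++it) {
      out.idx[at] = it->first;
      out.w[at] = it->second;
      ++at;
    }
  }
  return out;
}

// [[Rcpp::export]]
List genlouvain_cpp(IntegerVector bp, IntegerVector bi, NumericVector bx,
                    int n, double tol) {
  Graph g;
  g.n = n;
  g.ptr.assign(bp.begin(), bp.end());
  g.idx.assign(bi.begin(), bi.end());
  g.w.assign(bx.begin(), bx.end());
  g.self.assign(n, 0.0);
  // strip any diagonal entries into self-loops
  for (int v = 0; v < n; ++v) {
    for (int e = g.ptr[v]; e < g.ptr[v + 1]; ++e) {
      if (g.idx[e] == v) { g.self[v] += g.w[e]; g.w[e] = 0.0; }
    }
  }

  std::vector<int> fine(n);
  for (int v = 0; v < n; ++v) fine[v] = v;

  std::vector<double> phase_q;
  std::vector<int> comm(n);
  for (int v = 0; v < n; ++v) comm[v] = v;
  phase_q.push_back(graph_quality(g, comm));

  while (true) {
    bool moved = local_moves(g, comm, tol);
    double q_now = graph_quality(g, comm);
    if (q_now + 1e-9 < phase_q.back())
      stop("internal error: quality decreased during a Louvain phase");
    phase_q.push_back(q_now);
    if (!moved) break;
    int nc = renumber(comm);
    for (int v = 0; v < (int)fine.size(); ++v) fine[v] = comm[fine[v]];
    if (nc == g.n) break;
    g = aggregate(g, comm, nc);
    comm.assign(nc, 0);
    for (int c = 0; c < nc; ++c) comm[c] = c;
    double q_agg = graph_quality(g, comm);
    if (std::abs(q_agg - phase_q.back()) > 1e-6 * (1.0 + std::abs(q_agg)))
      stop("internal error: aggregation changed the quality");
    if (nc == 1) break;
  }

  std::vector<int> out = fine;
  renumber(out);
  IntegerVector labels(n);
  for (int v = 0; v < n; ++v) labels[v] = out[v] + 1; // 1-based for R
  return List::create(_["labels"] = labels,
                      _["q_raw"] = phase_q.back(),
                      _["phase_q"] = NumericVector(phase_q.begin(), phase_q.end()));
}
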