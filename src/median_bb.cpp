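// Exact DCJ median of three circular genomes by branch and bound on the
// multiple breakpoint graph (MBG).
//
// The MBG holds one perfect matching per genome on the 2n extremity
// vertices. A median is a perfect matching M (the candidate genome's
// adjacencies) maximizing the total number of alternating cycles against
// the three genome matchings; the median score is then 3n - cycles.
//
// Search state: choosing median edge (u,v) "shrinks" it out of every
// genome matching -- a matching containing (u,v) closes a cycle, any other
// has its edges (u,a),(v,b) rewired to (a,b). The bound credits at most
// one future cycle per genome per remaining median edge, which never
// underestimates the attainable total (admissible), so no optimum is
// pruned.
//
// The median must be a single circular chromosome. A union-find-free path
// structure (oend[x] = opposite end of the partial genome path containing
// extremity x, initialized to the gene co-extremity) rejects any edge that
// would close a chromosome before all genes are linked; the final edge is
// exempt.
//
// Adequate subgraphs of size 2 -- vertex pairs joined by >= 2 parallel
// genome edges -- are committed eagerly without branching (as_mode 2; mode
// 1 restricts this to 3-parallel pairs, mode 0 disables it). Fixed
// adjacencies are first forced into every matching by edge surgery (which
// makes them adequate) and committed.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Undo {
  int a[3], b[3];
  int e1, e2;
  int u, v;
};

struct Solver {
  int n2;                      // number of extremity vertices (2n)
  int n_edges;                 // median edges to choose (n)
  std::vector<int> m[3];       // 1-based matchings; meaningful for free vertices
  std::vector<int> oend;       // opposite end of genome path, original ids
  std::vector<char> used;      // vertex committed to a median edge
  std::vector<int> med;        // median partner per vertex
  std::vector<int> best;       // best complete median matching
  int cycles = 0;
  int best_cycles = -1;
  int chosen = 0;
  double nodes = 0.0, budget = 0.0;
  bool aborted = false;

  int mult(int u, int v) const {
    return (m[0][u] == v) + (m[1][u] == v) + (m[2][u] == v);
  }

  // branching key: multiplicity first, ties by the first genome whose
  // matching contains the edge (input order), then vertex id -- makes the
  // search order, and hence any budget-truncated result, deterministic
  long cand_key(int u, int v) const {
    int idx = m[0][u] == v ? 0 : m[1][u] == v ? 1 : m[2][u] == v ? 2 : 3;
    return (3L - mult(u, v)) * 4L * (n2 + 1) + idx * (n2 + 1) + v;
  }

  bool closes_early(int u, int v) const {
    return oend[u] == v && chosen < n_edges - 1;
  }

  Undo apply(int u, int v) {
    Undo un;
    un.u = u; un.v = v;
    un.e1 = oend[u]; un.e2 = oend[v];
    oend[un.e1] = un.e2;
    oend[un.e2] = un.e1;
    used[u] = used[v] = 1;
    med[u] = v; med[v] = u;
    ++chosen;
    for (int g = 0; g < 3; ++g) {
      if (m[g][u] == v) {
        ++cycles;
        un.a[g] = 0; un.b[g] = 0;
      } else {
        int a = m[g][u], b = m[g][v];
        un.a[g] = a; un.b[g] = b;
        m[g][a] = b; m[g][b] = a;
      }
    }
    return un;
  }

  void unapply(const Undo& un) {
    int u = un.u, v = un.v;
    for (int g = 0; g < 3; ++g) {
      if (un.a[g] == 0) {
        --cycles;
      } else {
        int a = un.a[g], b = un.b[g];
        m[g][a] = u; m[g][u] = a;
        m[g][b] = v; m[g][v] = b;
      }
    }
    --chosen;
    used[u] = used[v] = 0;
    oend[un.e1] = u; oend[un.e2] = v;
    oend[u] = un.e1; oend[v] = un.e2;
  }

  // canonical reading of a complete median matching: start at the tail of
  // gene 1, so the genome begins +1
  std::vector<int> canon_of(const std::vector<int>& mm) const {
    std::vector<int> genes;
    genes.reserve(n_edges);
    int v = 1;
    do {
      int gi = (v + 1) / 2;
      int ex;
      if (v % 2 == 1) { genes.push_back(gi); ex = v + 1; }
      else { genes.push_back(-gi); ex = v - 1; }
      v = mm[ex];
    } while (v != 1);
    return genes;
  }

  static bool genes_less(const std::vector<int>& a, const std::vector<int>& b) {
    for (size_t i = 0; i < a.size() && i < b.size(); ++i) {
      int ka = 2 * std::abs(a[i]) + (a[i] < 0);
      int kb = 2 * std::abs(b[i]) + (b[i] < 0);
      if (ka != kb) return ka < kb;
    }
    return false;
  }

  void record_if_better() {
    if (cycles > best_cycles) {
      best_cycles = cycles;
      best = med;
    } else if (cycles == best_cycles &&
               genes_less(canon_of(med), canon_of(best))) {
      best = med;  // among visited ties keep the canonically smallest
    }
  }

  // Commit every pair joined by >= minmult parallel edges, greedily by
  // descending multiplicity then lowest vertex ids. Cascades: rewiring can
  // create new parallel pairs.
  void eager_shrink(int minmult) {
    for (;;) {
      int bu = 0, bv = 0, bm = 0;
      for (int u = 1; u <= n2; ++u) {
        if (used[u]) continue;
        for (int g = 0; g < 3; ++g) {
          int v = m[g][u];
          if (v <= u) continue;  // visit each pair once, from its low end
          int mu = mult(u, v);
          if (mu < minmult || closes_early(u, v)) continue;
          if (mu > bm || (mu == bm && (u < bu || (u == bu && v < bv)))) {
            bm = mu; bu = u; bv = v;
          }
        }
      }
      if (bm == 0) break;
      apply(bu, bv);
    }
  }

  // One greedy descent to seed the incumbent before branch and bound.
  void greedy_seed() {
    std::vector<Undo> trail;
    for (;;) {
      int u = 0;
      for (int x = 1; x <= n2; ++x) if (!used[x]) { u = x; break; }
      if (!u) break;
      int bv = 0;
      long bk = 0;
      for (int v = 1; v <= n2; ++v) {
        if (v == u || used[v] || closes_early(u, v)) continue;
        long k = cand_key(u, v);
        if (bv == 0 || k < bk) { bk = k; bv = v; }
      }
      trail.push_back(apply(u, bv));
    }
    record_if_better();
    for (auto it = trail.rbegin(); it != trail.rend(); ++it) unapply(*it);
  }

  void dfs() {
    if (aborted) return;
    nodes += 1.0;
    if (budget > 0 && nodes > budget) { aborted = true; return; }
    if ((static_cast<long long>(nodes) & 0x3FFF) == 0) checkUserInterrupt();
    int u = 0;
    for (int x = 1; x <= n2; ++x) if (!used[x]) { u = x; break; }
    if (!u) { record_if_better(); return; }
    int rem = n_edges - chosen;
    if (cycles + 3 * rem <= best_cycles) return;  // admissible bound
    std::vector<std::pair<long, int>> cand;  // (branching key, v)
    cand.reserve(n2);
    for (int v = 1; v <= n2; ++v) {
      if (v == u || used[v] || closes_early(u, v)) continue;
      cand.emplace_back(cand_key(u, v), v);
    }
    std::sort(cand.begin(), cand.end());
    for (auto& c : cand) {
      Undo un = apply(u, c.second);
      dfs();
      unapply(un);
      if (aborted) return;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".median_bb")]]
List median_bb(IntegerVector m1, IntegerVector m2, IntegerVector m3,
               IntegerMatrix fixed, double budget, int as_mode) {
  Solver s;
  s.n2 = m1.size();
  s.n_edges = s.n2 / 2;
  if (m2.size() != s.n2 || m3.size() != s.n2 || s.n2 < 2 || s.n2 % 2) {
    stop("matchings must share one even-sized vertex set");
  }
  for (int g = 0; g < 3; ++g) s.m[g].assign(s.n2 + 1, 0);
  for (int u = 1; u <= s.n2; ++u) {
    s.m[0][u] = m1[u - 1];
    s.m[1][u] = m2[u - 1];
    s.m[2][u] = m3[u - 1];
  }
  for (int g = 0; g < 3; ++g) {
    for (int u = 1; u <= s.n2; ++u) {
      int v = s.m[g][u];
      if (v < 1 || v > s.n2 || v == u || s.m[g][v] != u) {
        stop("input is not a valid perfect matching");
      }
    }
  }
  s.oend.assign(s.n2 + 1, 0);
  for (int i = 1; i <= s.n_edges; ++i) {
    s.oend[2 * i - 1] = 2 * i;
    s.oend[2 * i] = 2 * i - 1;
  }
  s.used.assign(s.n2 + 1, 0);
  s.med.assign(s.n2 + 1, 0);
  s.budget = std::max(budget, 8.0 * s.n_edges + 8.0);

  // Force fixed adjacencies into every matching (edge surgery), then
  // commit them.
  for (int r = 0; r < fixed.nrow(); ++r) {
    int u = fixed(r, 0), v = fixed(r, 1);
    if (u < 1 || u > s.n2 || v < 1 || v > s.n2 || u == v) {
      stop("fixed adjacency out of range");
    }
    if ((u + 1) / 2 == (v + 1) / 2) {
      stop("cannot fix the two extremities of one gene");
    }
    if (s.used[u] || s.used[v]) stop("fixed adjacencies reuse a vertex");
    for (int g = 0; g < 3; ++g) {
      if (s.m[g][u] == v) continue;
      int a = s.m[g][u], b = s.m[g][v];
      s.m[g][u] = v; s.m[g][v] = u;
      s.m[g][a] = b; s.m[g][b] = a;
    }
    if (s.closes_early(u, v)) {
      stop("fixed adjacencies close a circular chromosome prematurely");
    }
    s.apply(u, v);
  }

  if (as_mode >= 1) s.eager_shrink(as_mode == 1 ? 3 : 2);
  s.greedy_seed();
  s.dfs();

  IntegerVector match(s.n2);
  for (int u = 1; u <= s.n2; ++u) match[u - 1] = s.best[u];
  return List::create(_["match"] = match,
                      _["cycles"] = s.best_cycles,
                      _["optimal"] = !s.aborted,
                      _["nodes"] = s.nodes);
}

// Score every candidate median matching (rows of `cands`) against three
// genome matchings: total alternating cycles per candidate. Used by the
// exhaustive test oracle.
// [[Rcpp::export(name = ".score_matchings")]]
IntegerVector score_matchings(IntegerMatrix cands, IntegerVector m1,
                              IntegerVector m2, IntegerVector m3) {
  int n2 = m1.size();
  const int* gm[3];
  gm[0] = INTEGER(m1); gm[1] = INTEGER(m2); gm[2] = INTEGER(m3);
  int K = cands.nrow();
  IntegerVector out(K);
  std::vector<char> visited(n2 + 1);
  for (int k = 0; k < K; ++k) {
    int total = 0;
    for (int g = 0; g < 3; ++g) {
      std::fill(visited.begin(), visited.end(), 0);
      for (int sstart = 1; sstart <= n2; ++sstart) {
        if (visited[sstart]) continue;
        ++total;
        int v = sstart;
        do {
          visited[v] = 1;
          int w = cands(k, v - 1);
          visited[w] = 1;
          v = gm[g][w - 1];
        } while (v != sstart);
      }
    }
    out[k] = total;
  }
  return out;
}
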