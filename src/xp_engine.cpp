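#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// ---- simple-path enumeration ----------------------------------------------
// Recursive DFS over a CSR adjacency in lexicographic neighbour order
// (the order is prepared on the R side). Throws once max_paths is exceeded:
// a truncated path set would silently corrupt the count distribution.

struct PathAcc {
  std::vector<std::vector<int>> edges; // edge ids per path (0-based)
  long max_paths;
};

static void dfs_paths(const std::vector<int>& head, const std::vector<int>& nbr,
                      const std::vector<int>& eid, int t, int max_len,
                      std::vector<char>& visited, std::vector<int>& estack,
                      int u, PathAcc& acc) {
  if (u == t) {
    if ((long)acc.edges.size() >= acc.max_paths)
      throw std::range_error("max_paths");
    acc.edges.push_back(estack);
    return;
  }
  if ((int)estack.size() >= max_len) return;
  visited[u] = 1;
  for (int k = head[u]; k < head[u + 1]; ++k) {
    int w = nbr[k];
    if (!visited[w]) {
      estack.push_back(eid[k]);
      dfs_paths(head, nbr, eid, t, max_len, visited, estack, w, acc);
      estack.pop_back();
    }
  }
  visited[u] = 0;
}

// [[Rcpp::export]]
List cpp_simple_paths(int n, IntegerVector head, IntegerVector nbr,
                      IntegerVector eid, int s, int t,
                      int max_len, double max_paths) {
  PathAcc acc;
  acc.max_paths = (long)max_paths;
  std::vector<int> h(head.begin(), head.end());
  std::vector<int> nb(nbr.begin(), nbr.end());
  std::vector<int> ei(eid.begin(), eid.end());
  std::vector<char> visited(n, 0);
  std::vector<int> estack;
  bool overflow = false;
  try {
    dfs_paths(h, nb, ei, t, max_len, visited, estack, s, acc);
  } catch (const std::range_error&) {
    overflow = true;
  }
  List out(acc.edges.size());
  for (size_t i = 0; i < acc.edges.size(); ++i) {
    IntegerVector v(acc.edges[i].begin(), acc.edges[i].end());
    out[i] = v + 1; // back to 1-based edge rows
  }
  return List::create(_["paths"] = out, _["overflow"] = overflow);
}

// ---- the x-polynomial engine ----------------------------------------------
// Terms are (coefficient, alive-path bitset, marker path list); see the R
// documentation of count_shortest_paths() for the algebra. Identical
// signatures are merged via a hash map after every edge-polynomial
// multiplication.

struct Term {
  std::vector<uint64_t> alive;
  std::vector<int> marks; // collapsed path ids, sorted
  double coef;
};

static inline void clear_bit(std::vector<uint64_t>& b, int i) {
  b[i >> 6] &= ~(uint64_t(1) << (i & 63));
}
static inline bool get_bit(const std::vector<uint64_t>& b, int i) {
  return (b[i >> 6] >> (i & 63)) & 1;
}

static std::string term_key(const Term& tm) {
  std::string k;
  k.reserve(tm.alive.size() * 8 + tm.marks.size() * 4 + 1);
  k.append(reinterpret_cast<const char*>(tm.alive.data()), tm.alive.size() * 8);
  k.push_back('|');
  k.append(reinterpret_cast<const char*>(tm.marks.data()), tm.marks.size() * 4);
  return k;
}

static void merge_push(std::vector<Term>& pool,
                       std::unordered_map<std::string, size_t>& index,
                       Term&& tm) {
  std::string key = term_key(tm);
  auto it = index.find(key);
  if (it == index.end()) {
    index.emplace(std::move(key), pool.size());
    pool.push_back(std::move(tm));
  } else {
    pool[it->second].coef += tm.coef;
  }
}

// path_edges: per path, 1-based rows into the full edge table
// lens: per path, its length; p: presence probability per edge row
// interior: per path, 1-based node indices of its interior nodes
// [[Rcpp::export]]
List cpp_xp_engine(List path_edges, IntegerVector lens, NumericVector p,
                   List interior, int n_nodes, bool track, double max_terms) {
  int K = path_edges.size();
  int words = (K + 63) / 64;

  std::vector<std::vector<int>> pedges(K);
  for (int i = 0; i < K; ++i) {
    IntegerVector e = path_edges[i];
    pedges[i].assign(e.begin(), e.end());
    for (int& x : pedges[i]) --x;
  }

  // distinct lengths ascending = the group order
  std::vector<int> ulen(lens.begin(), lens.end());
  std::sort(ulen.begin(), ulen.end());
  ulen.erase(std::unique(ulen.begin(), ulen.end()), ulen.end());
  int G = ulen.size();

  // schedule: per group, first-appearance order of not yet scheduled edges
  std::unordered_map<int, int> sched_pos; // edge row -> position
  std::vector<int> schedule;              // edge rows
  std::vector<int> group_end(G, 0);       // schedule length after each group
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < K; ++i) {
      if (lens[i] != ulen[g]) continue;
      for (int e : pedges[i]) {
        if (!sched_pos.count(e)) {
          sched_pos[e] = schedule.size();
          schedule.push_back(e);
        }
      }
    }
    group_end[g] = schedule.size();
  }

  // paths through each scheduled edge, and collapse list per position
  int S = schedule.size();
  std::vector<std::vector<int>> paths_of(S), collapse_at(S);
  for (int i = 0; i < K; ++i) {
    int fin = -1;
    for (int e : pedges[i]) {
      int pos = sched_pos[e];
      paths_of[pos].push_back(i);
      if (pos > fin) fin = pos;
    }
    collapse_at[fin].push_back(i);
  }

  // distribution support: max per-length multiplicity
  int kmax = 0;
  for (int g = 0; g < G; ++g) {
    int c = 0;
    for (int i = 0; i < K; ++i) if (lens[i] == ulen[g]) ++c;
    if (c > kmax) kmax = c;
  }
  std::vector<double> p_y(kmax + 1, 0.0);
  int m_edges = p.size();
  std::vector<double> edge_contrib(m_edges, 0.0);
  std::vector<double> node_contrib(n_nodes, 0.0);

  std::vector<Term> pool(1);
  pool[0].alive.assign(words, 0);
  for (int i = 0; i < K; ++i) pool[0].alive[i >> 6] |= uint64_t(1) << (i & 63);
  pool[0].coef = 1.0;

  int pos = 0;
  for (int g = 0; g < G; ++g) {
    for (; pos < group_end[g]; ++pos) {
      int e = schedule[pos];
      double pe = p[e], qe = 1.0 - pe;
      const std::vector<int>& P_j = paths_of[pos];
      const std::vector<int>& F_j = collapse_at[pos];

      std::vector<Term> next;
      next.reserve(pool.size() * 2);
      std::unordered_map<std::string, size_t> index;
      index.reserve(pool.size() * 2);

      for (Term& tm : pool) {
        if (pe > 0.0) { // present branch: collapse the finished paths
          Term t1;
          t1.alive = tm.alive;
          t1.marks = tm.marks;
          t1.coef = tm.coef * pe;
          for (int r : F_j) {
            if (get_bit(t1.alive, r)) {
              clear_bit(t1.alive, r);
              t1.marks.insert(
                std::lower_bound(t1.marks.begin(), t1.marks.end(), r), r);
            }
          }
          merge_push(next, index, std::move(t1));
        }
        if (qe > 0.0) { // absent branch: every path through e breaks
          Term t2;
          t2.alive = tm.alive;
          t2.marks = std::move(tm.marks);
          t2.coef = tm.coef * qe;
          for (int r : P_j) clear_bit(t2.alive, r);
          merge_push(next, index, std::move(t2));
        }
      }
      pool.swap(next);
      if ((double)pool.size() > max_terms)
        stop("polynomial term pool exceeded max_terms = %.0f", max_terms);
    }

    // select: retire terms with markers at the current group length
    int r_len = ulen[g];
    std::vector<Term> keep;
    keep.reserve(pool.size());
    for (Term& tm : pool) {
      int j = 0;
      for (int h : tm.marks) if (lens[h] == r_len) ++j;
      if (j > 0) {
        p_y[j] += tm.coef;
        if (track) {
          double w = tm.coef / j;
          for (int h : tm.marks) {
            if (lens[h] != r_len) continue;
            for (int e : pedges[h]) edge_contrib[e] += w;
            IntegerVector iv = interior[h];
            for (int v : iv) node_contrib[v - 1] += w;
          }
        }
      } else {
        bool empty_alive = true;
        for (uint64_t wd : tm.alive) if (wd) { empty_alive = false; break; }
        if (empty_alive && tm.marks.empty()) {
          p_y[0] += tm.coef;
        } else {
          keep.push_back(std::move(tm));
        }
      }
    }
    pool.swap(keep);
  }
  for (const Term& tm : pool) p_y[0] += tm.coef;

  return List::create(
    _["prob"] = NumericVector(p_y.begin(), p_y.end()),
    _["edge_contrib"] = NumericVector(edge_contrib.begin(), edge_contrib.end()),
    _["node_contrib"] = NumericVector(node_contrib.begin(), node_contrib.end())
  );
}
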