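#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Fixed-radius neighbor search via cell lists.
//
// Cells have side length equal to the search radius, so all pairs closer
// than the radius live in adjacent (27-neighborhood) cells.  Membership is
// decided on squared distance; `strict` selects d < r (graph building) vs
// d <= r (smoothing neighborhoods).
// ---------------------------------------------------------------------------

static inline long long cellKey(int ix, int iy, int iz) {
  // coordinates are offset to be nonnegative before calling
  return (static_cast<long long>(ix) << 42) |
         (static_cast<long long>(iy) << 21) |
         static_cast<long long>(iz);
}

static void buildCells(const NumericMatrix& xyz, double h,
                       std::unordered_map<long long, std::vector<int> >& cells,
                       std::vector<int>& cx, std::vector<int>& cy,
                       std::vector<int>& cz) {
  const int n = xyz.nrow();
  double minx = R_PosInf, miny = R_PosInf, minz = R_PosInf;
  for (int i = 0; i < n; ++i) {
    minx = std::min(minx, xyz(i, 0));
    miny = std::min(miny, xyz(i, 1));
    minz = std::min(minz, xyz(i, 2));
  }
  cx.resize(n); cy.resize(n); cz.resize(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = static_cast<int>(std::floor((xyz(i, 0) - minx) / h));
    cy[i] = static_cast<int>(std::floor((xyz(i, 1) - miny) / h));
    cz[i] = static_cast<int>(std::floor((xyz(i, 2) - minz) / h));
    cells[cellKey(cx[i], cy[i], cz[i])].push_back(i);
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_contact_edges(NumericMatrix xyz, double cutoff, bool strict) {
  const int n = xyz.nrow();
  std::unordered_map<long long, std::vector<int> > cells;
  std::vector<int> cx, cy, cz;
  buildCells(xyz, cutoff, cells, cx, cy, cz);

  const double c2 = cutoff * cutoff;
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(cellKey(cx[i] + dx, cy[i] + dy, cz[i] + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            const double ddx = xyz(i, 0) - xyz(j, 0);
            const double ddy = xyz(i, 1) - xyz(j, 1);
            const double ddz = xyz(i, 2) - xyz(j, 2);
            const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (strict ? (d2 < c2) : (d2 <= c2)) {
              ei.push_back(i + 1);
              ej.push_back(j + 1);
            }
          }
        }
  }
  const int m = ei.size();
  IntegerMatrix out(m, 2);
  for (int k = 0; k < m; ++k) {
    out(k, 0) = ei[k];
    out(k, 1) = ej[k];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_neighbor_lists(NumericMatrix xyz, double radius) {
  const int n = xyz.nrow();
  std::unordered_map<long long, std::vector<int> > cells;
  std::vector<int> cx, cy, cz;
  buildCells(xyz, radius, cells, cx, cy, cz);

  const double r2 = radius * radius;
  List out(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(cellKey(cx[i] + dx, cy[i] + dy, cz[i] + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            const double ddx = xyz(i, 0) - xyz(j, 0);
            const double ddy = xyz(i, 1) - xyz(j, 1);
            const double ddz = xyz(i, 2) - xyz(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) nb.push_back(j + 1);
          }
        }
    std::sort(nb.begin(), nb.end());
    out[i] = IntegerVector(nb.begin(), nb.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Graphlet orbit counting for connected induced subgraphs on 2-4 nodes.
//
// Enumeration follows Wernicke's ESU: every connected induced subgraph of
// size 3 and 4 is visited exactly once (the size-3 sets are the depth-3
// states of the size-4 recursion).  Each visited subgraph is classified by
// its (edge count, within-subgraph degree) signature, which identifies the
// graphlet type and each member's orbit uniquely:
//   size 3: 2 edges -> path   (deg1 = orbit 1, deg2 = orbit 2)
//           3 edges -> triangle (orbit 3)
//   size 4: 3 edges, maxdeg 2 -> path    (deg1 -> 4, deg2 -> 5)
//           3 edges, maxdeg 3 -> star    (deg1 -> 6, deg3 -> 7)
//           4 edges, maxdeg 2 -> cycle   (orbit 8)
//           4 edges, maxdeg 3 -> paw     (deg1 -> 9, deg2 -> 10, deg3 -> 11)
//           5 edges            -> diamond (deg2 -> 12, deg3 -> 13)
//           6 edges            -> K4      (orbit 14)
// Orbit 0 is the plain degree.
// ---------------------------------------------------------------------------

class OrbitCounter {
public:
  OrbitCounter(int n_, const std::vector<std::vector<int> >& adj_,
               IntegerMatrix& orb_)
      : n(n_), adj(adj_), orb(orb_), marked(n_, 0) {}

  void run() {
    std::vector<int> sub;
    sub.reserve(4);
    for (int v = 0; v < n; ++v) {
      orb(v, 0) = adj[v].size();
      marked[v] = 1;
      for (int u : adj[v]) marked[u] = 1;
      sub.assign(1, v);
      std::vector<int> ext;
      for (int u : adj[v])
        if (u > v) ext.push_back(u);
      extend(sub, ext, v);
      marked[v] = 0;
      for (int u : adj[v]) marked[u] = 0;
    }
  }

private:
  int n;
  const std::vector<std::vector<int> >& adj;
  IntegerMatrix& orb;
  std::vector<char> marked;  // in subgraph or adjacent to it

  bool isAdj(int a, int b) const {
    const std::vector<int>& v = adj[a];
    return std::binary_search(v.begin(), v.end(), b);
  }

  void classify3(const std::vector<int>& s) {
    const bool ab = isAdj(s[0], s[1]), ac = isAdj(s[0], s[2]),
               bc = isAdj(s[1], s[2]);
    const int e = ab + ac + bc;
    if (e == 3) {
      for (int i = 0; i < 3; ++i) orb(s[i], 3)++;
    } else {  // path: ESU guarantees connectivity, so e == 2
      const int d0 = ab + ac, d1 = ab + bc, d2 = ac + bc;
      orb(s[0], d0 == 2 ? 2 : 1)++;
      orb(s[1], d1 == 2 ? 2 : 1)++;
      orb(s[2], d2 == 2 ? 2 : 1)++;
    }
  }

  void classify4(const std::vector<int>& s) {
    bool p01 = isAdj(s[0], s[1]), p02 = isAdj(s[0], s[2]),
         p03 = isAdj(s[0], s[3]), p12 = isAdj(s[1], s[2]),
         p13 = isAdj(s[1], s[3]), p23 = isAdj(s[2], s[3]);
    const int e = p01 + p02 + p03 + p12 + p13 + p23;
    int d[4];
    d[0] = p01 + p02 + p03;
    d[1] = p01 + p12 + p13;
    d[2] = p02 + p12 + p23;
    d[3] = p03 + p13 + p23;
    const int maxd = std::max(std::max(d[0], d[1]), std::max(d[2], d[3]));
    for (int i = 0; i < 4; ++i) {
      int o;
      switch (e) {
        case 3:
          o = (maxd == 3) ? (d[i] == 1 ? 6 : 7) : (d[i] == 1 ? 4 : 5);
          break;
        case 4:
          o = (maxd == 3) ? (d[i] == 1 ? 9 : (d[i] == 2 ? 10 : 11)) : 8;
          break;
        case 5:
          o = (d[i] == 2) ? 12 : 13;
          break;
        default:  // e == 6
          o = 14;
      }
      orb(s[i], o)++;
    }
  }

  void extend(std::vector<int>& sub, std::vector<int> ext, int v) {
    while (!ext.empty()) {
      const int w = ext.back();
      ext.pop_back();
      // exclusive neighborhood of w w.r.t. the current subgraph
      std::vector<int> ext2 = ext;
      for (int u : adj[w])
        if (u > v && !marked[u]) ext2.push_back(u);
      std::vector<int> newly;
      for (int u : adj[w])
        if (!marked[u]) {
          marked[u] = 1;
          newly.push_back(u);
        }
      sub.push_back(w);
      if (sub.size() == 3) {
        classify3(sub);
        extend(sub, ext2, v);
      } else if (sub.size() == 4) {
        classify4(sub);
      } else {
        extend(sub, ext2, v);
      }
      sub.pop_back();
      for (int u : newly) marked[u] = 0;
    }
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_count_orbits(int n, IntegerMatrix edges) {
  std::vector<std::vector<int> > adj(n);
  const int m = edges.nrow();
  for (int k = 0; k < m; ++k) {
    const int a = edges(k, 0) - 1, b = edges(k, 1) - 1;
    if (a < 0 || b < 0 || a >= n || b >= n)
      stop("edge index out of range");
    if (a == b) stop("self-loop in edge list");
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  for (int i = 0; i < n; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    if (std::adjacent_find(adj[i].begin(), adj[i].end()) != adj[i].end())
      stop("duplicate edge in edge list");
  }
  IntegerMatrix orb(n, 15);
  OrbitCounter counter(n, adj, orb);
  counter.run();
  return orb;
}
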