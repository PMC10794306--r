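// Vietoris-Rips persistent homology in dimensions 0 and 1.
//
// Dimension 0 is computed by Kruskal-style union-find over the sorted edge
// list.  Dimension 1 uses persistent cohomology with clearing: columns are
// the coboundaries of the non-merging ("positive") edges, processed in
// decreasing filtration order; the pivot of a column is its minimal cofacet
// triangle in filtration order.  Columns whose raw pivot is unclaimed are
// settled immediately and kept in implicit (regenerate-on-demand) form, so
// memory stays proportional to the small number of columns that actually
// collide -- the same observation that makes ripser fast.
//
// The filtration is truncated at the enclosing radius
// min_i max_j d(i, j); at that scale the complex is a cone, so no
// dimension-1 class survives and all finite intervals are unchanged.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Edge {
  double diam;
  int a, b;  // a < b
};

struct TriEntry {
  double diam;
  int64_t idx;  // encodes the sorted vertex triple, unique per triangle
};

// Min-order comparison for the filtration (diam, then combinatorial index).
inline bool tri_less(const TriEntry &x, const TriEntry &y) {
  if (x.diam != y.diam) return x.diam < y.diam;
  return x.idx < y.idx;
}

struct TriGreater {  // for a min-heap via std::priority_queue
  bool operator()(const TriEntry &x, const TriEntry &y) const {
    return tri_less(y, x);
  }
};

class UnionFind {
 public:
  explicit UnionFind(int n) : parent_(n) {
    for (int i = 0; i < n; ++i) parent_[i] = i;
  }
  int find(int x) {
    int root = x;
    while (parent_[root] != root) root = parent_[root];
    while (parent_[x] != root) {
      int next = parent_[x];
      parent_[x] = root;
      x = next;
    }
    return root;
  }
  void unite(int x, int y) { parent_[find(x)] = find(y); }

 private:
  std::vector<int> parent_;
};

struct ColumnStore {
  // One record per settled column (an edge whose pivot triangle is claimed).
  // `raw` columns are regenerated from the edge's cofacets on demand.
  std::vector<int> edge_id;
  std::vector<bool> raw;
  std::vector<std::vector<TriEntry>> entries;  // only filled when !raw
};

inline int64_t tri_index(int i, int j, int k, int n) {
  // requires i < j < k
  return (static_cast<int64_t>(i) * n + j) * n + k;
}

// Enumerate cofacet triangles of edge (a, b) within the threshold.
void edge_cofacets(int a, int b, int n, const std::vector<double> &dist,
                   double threshold, std::vector<TriEntry> &out) {
  out.clear();
  const double dab = dist[static_cast<size_t>(a) * n + b];
  for (int c = 0; c < n; ++c) {
    if (c == a || c == b) continue;
    double dac = dist[static_cast<size_t>(a) * n + c];
    double dbc = dist[static_cast<size_t>(b) * n + c];
    if (dac > threshold || dbc > threshold) continue;
    double diam = std::max(dab, std::max(dac, dbc));
    int i = a, j = b, k = c;
    if (k < i) std::swap(i, k);
    if (k < j) std::swap(j, k);
    if (j < i) std::swap(i, j);
    out.push_back({diam, tri_index(i, j, k, n)});
  }
}

}  // namespace

// [[Rcpp::export(name = ".rips_pairs")]]
NumericMatrix rips_pairs(NumericMatrix points) {
  const int n = points.nrow();
  const int d = points.ncol();
  if (n < 1) stop("point cloud must contain at least one point");

  // Dense Euclidean distance matrix.
  std::vector<double> dist(static_cast<size_t>(n) * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = points(i, k) - points(j, k);
        s += diff * diff;
      }
      double v = std::sqrt(s);
      dist[static_cast<size_t>(i) * n + j] = v;
      dist[static_cast<size_t>(j) * n + i] = v;
    }
  }

  // Enclosing radius.
  double threshold = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double mx = 0.0;
    for (int j = 0; j < n; ++j)
      mx = std::max(mx, dist[static_cast<size_t>(i) * n + j]);
    threshold = std::min(threshold, mx);
  }

  std::vector<Edge> edges;
  edges.reserve(static_cast<size_t>(n) * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = dist[static_cast<size_t>(i) * n + j];
      if (v <= threshold) edges.push_back({v, i, j});
    }
  std::sort(edges.begin(), edges.end(), [n](const Edge &x, const Edge &y) {
    if (x.diam != y.diam) return x.diam < y.diam;
    return static_cast<int64_t>(x.a) * n + x.b <
           static_cast<int64_t>(y.a) * n + y.b;
  });

  std::vector<double> births, deaths;
  std::vector<int> dims;

  // --- dimension 0: union-find ------------------------------------------
  UnionFind uf(n);
  std::vector<char> merging(edges.size(), 0);
  for (size_t e = 0; e < edges.size(); ++e) {
    int ra = uf.find(edges[e].a), rb = uf.find(edges[e].b);
    if (ra != rb) {
      uf.unite(ra, rb);
      merging[e] = 1;
      if (edges[e].diam > 0) {  // zero-persistence pairs are dropped
        dims.push_back(0);
        births.push_back(0.0);
        deaths.push_back(edges[e].diam);
      }
    }
  }
  dims.push_back(0);  // the essential connected component
  births.push_back(0.0);
  deaths.push_back(R_PosInf);

  // --- dimension 1: persistent cohomology over the positive edges -------
  ColumnStore cols;
  std::unordered_map<int64_t, int> pivot_of;  // triangle idx -> column id
  std::vector<TriEntry> scratch;

  for (size_t ei = edges.size(); ei-- > 0;) {  // decreasing filtration order
    if (merging[ei]) continue;                 // clearing: H0 death simplices
    const Edge &edge = edges[ei];

    // Find the minimal cofacet on the fly (no materialization).
    const int a = edge.a, b = edge.b;
    const double dab = dist[static_cast<size_t>(a) * n + b];
    const double *ra = &dist[static_cast<size_t>(a) * n];
    const double *rb = &dist[static_cast<size_t>(b) * n];
    // For fixed a < b the triangle index is strictly increasing in the third
    // vertex, so the minimal cofacet is the smallest c attaining the minimal
    // diameter; track (diam, c) only and encode the index once.
    double best_diam = R_PosInf;
    int best_c = -1;
    for (int c = 0; c < n; ++c) {
      if (c == a || c == b) continue;
      double dac = ra[c], dbc = rb[c];
      if (dac > threshold || dbc > threshold) continue;
      double diam = std::max(dab, std::max(dac, dbc));
      if (diam < best_diam) {
        best_diam = diam;
        best_c = c;
      }
    }
    if (best_c < 0) continue;  // cannot occur below the enclosing radius
    TriEntry best;
    {
      int i = a, j = b, k = best_c;
      if (k < i) std::swap(i, k);
      if (k < j) std::swap(j, k);
      if (j < i) std::swap(i, j);
      best = {best_diam, tri_index(i, j, k, n)};
    }

    // Apparent/unclaimed raw pivot: settle without materializing a heap.
    auto hit = pivot_of.find(best.idx);
    if (hit == pivot_of.end()) {
      int id = static_cast<int>(cols.edge_id.size());
      cols.edge_id.push_back(static_cast<int>(ei));
      cols.raw.push_back(true);
      cols.entries.emplace_back();
      pivot_of.emplace(best.idx, id);
      if (best.diam > edge.diam) {
        dims.push_back(1);
        births.push_back(edge.diam);
        deaths.push_back(best.diam);
      }
      continue;
    }

    // Collision: full reduction with a lazy Z/2 heap. Long cascades fill
    // the heap with cancelled duplicates, so compress it (drain, cancel
    // mod 2, rebuild) whenever it grows past a moving limit.
    edge_cofacets(edge.a, edge.b, n, dist, threshold, scratch);
    std::priority_queue<TriEntry, std::vector<TriEntry>, TriGreater> heap(
        TriGreater(), scratch);
    size_t compress_limit = std::max<size_t>(4096, 4 * scratch.size());
    std::vector<TriEntry> reduced;
    bool settled = false;
    while (!heap.empty()) {
      if (heap.size() > compress_limit) {
        std::vector<TriEntry> live;
        while (!heap.empty()) {
          TriEntry t = heap.top();
          heap.pop();
          bool cc = false;
          while (!heap.empty() && heap.top().idx == t.idx) {
            heap.pop();
            cc = !cc;
          }
          if (!cc) live.push_back(t);
        }
        heap = std::priority_queue<TriEntry, std::vector<TriEntry>,
                                   TriGreater>(TriGreater(), live);
        compress_limit = std::max<size_t>(4096, 4 * live.size());
        if (heap.empty()) break;
      }
      TriEntry pivot = heap.top();
      heap.pop();
      // cancel duplicate entries mod 2
      bool cancelled = false;
      while (!heap.empty() && heap.top().idx == pivot.idx) {
        heap.pop();
        cancelled = !cancelled;
      }
      if (cancelled) continue;
      auto claim = pivot_of.find(pivot.idx);
      if (claim == pivot_of.end()) {
        int id = static_cast<int>(cols.edge_id.size());
        // materialize the reduced column: pivot plus the drained heap
        // (the heap is dead after settling, so drain it destructively)
        reduced.clear();
        reduced.push_back(pivot);
        while (!heap.empty()) {
          TriEntry t = heap.top();
          heap.pop();
          bool cc = false;
          while (!heap.empty() && heap.top().idx == t.idx) {
            heap.pop();
            cc = !cc;
          }
          if (!cc) reduced.push_back(t);
        }
        cols.edge_id.push_back(static_cast<int>(ei));
        cols.raw.push_back(false);
        cols.entries.push_back(reduced);
        pivot_of.emplace(pivot.idx, id);
        if (pivot.diam > edge.diam) {
          dims.push_back(1);
          births.push_back(edge.diam);
          deaths.push_back(pivot.diam);
        }
        settled = true;
        break;
      }
      // add the claiming column (pivot re-enters and cancels against itself)
      int cid = claim->second;
      heap.push(pivot);
      if (cols.raw[cid]) {
        const Edge &oe = edges[cols.edge_id[cid]];
        std::vector<TriEntry> other;
        edge_cofacets(oe.a, oe.b, n, dist, threshold, other);
        for (const TriEntry &t : other) heap.push(t);
      } else {
        for (const TriEntry &t : cols.entries[cid]) heap.push(t);
      }
    }
    if (!settled) {
      // column reduced to zero: an essential 1-cycle (cannot occur at the
      // enclosing-radius threshold, kept as a safeguard)
      dims.push_back(1);
      births.push_back(edge.diam);
      deaths.push_back(R_PosInf);
    }
  }

  NumericMatrix out(static_cast<int>(dims.size()), 3);
  for (size_t i = 0; i < dims.size(); ++i) {
    out(i, 0) = dims[i];
    out(i, 1) = births[i];
    out(i, 2) = deaths[i];
  }
  colnames(out) = CharacterVector::create("dimension", "birth", "death");
  return out;
}
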