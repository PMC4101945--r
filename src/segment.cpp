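// Region-merging image segmentation and 4-connected component labelling.
//
// Segmentation follows the classic multiresolution (Baatz-Schaepe style)
// formulation: starting from single-pixel regions, repeatedly perform the
// globally cheapest merge of two adjacent regions, where the fusion cost is
//   f = w_color * dh_color + (1 - w_color) * dh_shape
// with per-region heterogeneity
//   h_color = sum over bands of the pixel-value sd,
//   h_shape = 0.5 * compactness + 0.5 * smoothness,
//   compactness = perimeter / (4 * sqrt(n)),
//   smoothness  = perimeter / bounding-box perimeter,
// each weighted by region pixel count, and dh = h(merged) - h(a) - h(b).
// Merging stops when the cheapest available merge would cost more than the
// scale parameter.  Ties are broken by the lowest region id (a region's id is
// the smallest initial linear pixel index it contains), so the procedure is
// fully deterministic.

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Region {
  double n = 0;
  std::vector<double> sum, sumsq;
  double perim = 0;
  int rmin = 0, rmax = 0, cmin = 0, cmax = 0;
  int rid = 0;                 // min initial pixel index over members
  uint32_t version = 0;
  bool alive = false;
  std::unordered_map<int, double> adj;  // neighbour slot -> shared edge length
};

struct Cand {
  double f;
  int a, b;
  uint32_t va, vb;
  int rid_lo, rid_hi;
};

struct CandCmp {
  bool operator()(const Cand& x, const Cand& y) const {
    if (x.f != y.f) return x.f > y.f;
    if (x.rid_lo != y.rid_lo) return x.rid_lo > y.rid_lo;
    return x.rid_hi > y.rid_hi;
  }
};

// weighted heterogeneity n * (w * h_color + (1-w) * h_shape)
double heter(const Region& r, int nb, double w_color) {
  double hc = 0.0;
  for (int b = 0; b < nb; ++b) {
    double mean = r.sum[b] / r.n;
    double var = r.sumsq[b] / r.n - mean * mean;
    hc += var > 0 ? std::sqrt(var) : 0.0;
  }
  double compact = r.perim / (4.0 * std::sqrt(r.n));
  double bb = 2.0 * ((r.rmax - r.rmin + 1) + (r.cmax - r.cmin + 1));
  double smooth = r.perim / bb;
  double hs = 0.5 * compact + 0.5 * smooth;
  return r.n * (w_color * hc + (1.0 - w_color) * hs);
}

double fusion_cost(const Region& a, const Region& b, double shared, int nb,
                   double w_color) {
  Region m;
  m.n = a.n + b.n;
  m.sum.resize(nb);
  m.sumsq.resize(nb);
  for (int k = 0; k < nb; ++k) {
    m.sum[k] = a.sum[k] + b.sum[k];
    m.sumsq[k] = a.sumsq[k] + b.sumsq[k];
  }
  m.perim = a.perim + b.perim - 2.0 * shared;
  m.rmin = std::min(a.rmin, b.rmin);
  m.rmax = std::max(a.rmax, b.rmax);
  m.cmin = std::min(a.cmin, b.cmin);
  m.cmax = std::max(a.cmax, b.cmax);
  return heter(m, nb, w_color) - heter(a, nb, w_color) - heter(b, nb, w_color);
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_segment(NumericVector bands, double scale, double w_color) {
  IntegerVector dim = bands.attr("dim");
  const int H = dim[0], W = dim[1];
  const int NB = dim.size() == 3 ? dim[2] : 1;
  const int N = H * W;

  std::vector<Region> reg(N);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int id = i + H * j;
      Region& r = reg[id];
      r.alive = true;
      r.n = 1;
      r.perim = 4;
      r.rmin = r.rmax = i;
      r.cmin = r.cmax = j;
      r.rid = id;
      r.sum.resize(NB);
      r.sumsq.resize(NB);
      for (int b = 0; b < NB; ++b) {
        double v = bands[id + N * b];
        r.sum[b] = v;
        r.sumsq[b] = v * v;
      }
    }
  }
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int id = i + H * j;
      if (i + 1 < H) { reg[id].adj[id + 1] = 1; reg[id + 1].adj[id] = 1; }
      if (j + 1 < W) { reg[id].adj[id + H] = 1; reg[id + H].adj[id] = 1; }
    }
  }

  std::priority_queue<Cand, std::vector<Cand>, CandCmp> heap;
  auto push_cand = [&](int a, int b) {
    const Region& ra = reg[a];
    const Region& rb = reg[b];
    double shared = ra.adj.at(b);
    double f = fusion_cost(ra, rb, shared, NB, w_color);
    heap.push(Cand{f, a, b, ra.version, rb.version,
                   std::min(ra.rid, rb.rid), std::max(ra.rid, rb.rid)});
  };
  for (int id = 0; id < N; ++id)
    for (auto& kv : reg[id].adj)
      if (kv.first > id) push_cand(id, kv.first);

  std::vector<int> parent(N);
  for (int id = 0; id < N; ++id) parent[id] = id;

  while (!heap.empty()) {
    Cand c = heap.top();
    heap.pop();
    int a = c.a, b = c.b;
    if (!reg[a].alive || !reg[b].alive) continue;
    if (reg[a].version != c.va || reg[b].version != c.vb) continue;
    if (c.f > scale) break;  // cheapest valid merge too expensive: done

    if (reg[b].adj.size() > reg[a].adj.size()) std::swap(a, b);
    Region& A = reg[a];
    Region& B = reg[b];
    double shared = A.adj[b];
    for (int k = 0; k < NB; ++k) {
      A.sum[k] += B.sum[k];
      A.sumsq[k] += B.sumsq[k];
    }
    A.n += B.n;
    A.perim += B.perim - 2.0 * shared;
    A.rmin = std::min(A.rmin, B.rmin);
    A.rmax = std::max(A.rmax, B.rmax);
    A.cmin = std::min(A.cmin, B.cmin);
    A.cmax = std::max(A.cmax, B.cmax);
    A.rid = std::min(A.rid, B.rid);
    A.adj.erase(b);
    for (auto& kv : B.adj) {
      if (kv.first == a) continue;
      reg[kv.first].adj.erase(b);
      reg[kv.first].adj[a] += kv.second;
      A.adj[kv.first] += kv.second;
    }
    B.alive = false;
    B.adj.clear();
    B.sum.clear();
    B.sumsq.clear();
    parent[b] = a;
    A.version++;
    for (auto& kv : A.adj) push_cand(a, kv.first);
  }

  // resolve roots and relabel 1..K in column-major first-encounter order
  IntegerMatrix lab(H, W);
  std::vector<int> newlab(N, 0);
  int next = 0;
  for (int id = 0; id < N; ++id) {
    int r = id;
    while (parent[r] != r) { parent[r] = parent[parent[r]]; r = parent[r]; }
    if (newlab[r] == 0) newlab[r] = ++next;
    lab[id] = newlab[r];
  }
  return lab;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label4(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + H * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int id = stack.back();
        stack.pop_back();
        int ci = id % H, cj = id / H;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + H * nj);
          }
        }
      }
    }
  }
  return lab;
}
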