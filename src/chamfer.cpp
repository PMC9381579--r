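// Low-level grid operations shared by the morphometry module:
// connected-component labeling, single-source chamfer-weighted geodesic
// distance (Dijkstra on the pixel adjacency graph), and multi-source
// nearest-label assignment (geometric influence zones).

#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <limits>

using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
// 4-connectivity subset: indices 1, 3, 4, 6 of the table above

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % H, cc = idx / H;
        for (int k = 0; k < 8; ++k) {
          if (connectivity == 4 && (DR8[k] != 0 && DC8[k] != 0)) continue;
          int nr = cr + DR8[k], nc = cc + DC8[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(nr + nc * H);
          }
        }
      }
    }
  }
  return lab;
}

// Shortest within-mask path cost from a single source pixel under chamfer
// weights (1 for axial steps, wdiag for diagonal steps). Pixels outside the
// mask get Inf. src is a 0-based linear (column-major) index into the mask.
// [[Rcpp::export]]
NumericMatrix cpp_chamfer_distance(const LogicalMatrix& mask, int src,
                                   double wdiag) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix dist(H, W);
  std::fill(dist.begin(), dist.end(), INF);
  if (src < 0 || src >= H * W || !mask[src])
    stop("source pixel is outside the mask");

  typedef std::pair<double, int> Node; // (distance, linear index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[src] = 0.0;
  pq.push(Node(0.0, src));
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = top.first;
    int idx = top.second;
    if (d > dist[idx]) continue;
    int r = idx % H, c = idx / H;
    for (int k = 0; k < 8; ++k) {
      int nr = r + DR8[k], nc = c + DC8[k];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      if (!mask(nr, nc)) continue;
      double w = (DR8[k] != 0 && DC8[k] != 0) ? wdiag : 1.0;
      int nidx = nr + nc * H;
      if (d + w < dist[nidx]) {
        dist[nidx] = d + w;
        pq.push(Node(d + w, nidx));
      }
    }
  }
  return dist;
}

// Assign every zero pixel to the label of its chamfer-nearest labeled pixel
// (multi-source Dijkstra). Exact distance ties resolve to the smaller label,
// independent of traversal order. Pixels farther than max_dist from every
// label keep 0.
// [[Rcpp::export]]
IntegerMatrix cpp_influence_zones(const IntegerMatrix& labels, double wdiag,
                                  double max_dist) {
  const int H = labels.nrow(), W = labels.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  IntegerMatrix out(H, W);
  std::vector<double> dist((size_t)H * W, INF);

  typedef std::tuple<double, int, int> Node; // (distance, label, index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int i = 0; i < H * W; ++i) {
    if (labels[i] > 0) {
      out[i] = labels[i];
      dist[i] = 0.0;
      pq.push(Node(0.0, labels[i], i));
    }
  }
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = std::get<0>(top);
    int lbl = std::get<1>(top), idx = std::get<2>(top);
    if (d > dist[idx]) continue;
    if (d == dist[idx] && out[idx] != 0 && out[idx] < lbl) continue;
    int r = idx % H, c = idx / H;
    for (int k = 0; k < 8; ++k) {
      int nr = r + DR8[k], nc = c + DC8[k];
      if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
      double w = (DR8[k] != 0 && DC8[k] != 0) ? wdiag : 1.0;
      double nd = d + w;
      if (nd > max_dist) continue;
      int nidx = nr + nc * H;
      if (nd < dist[nidx] || (nd == dist[nidx] && lbl < out[nidx])) {
        dist[nidx] = nd;
        out[nidx] = lbl;
        pq.push(Node(nd, lbl, nidx));
      }
    }
  }
  return out;
}

// Nearest and second-nearest seed for each query point (squared
// Euclidean); used for Lloyd relaxation and Voronoi rasterization.
// [[Rcpp::export]]
List cpp_nearest_two(const NumericVector& px, const NumericVector& py,
                     const NumericVector& sx, const NumericVector& sy) {
  const int n = px.size(), m = sx.size();
  NumericVector d1(n, R_PosInf), d2(n, R_PosInf);
  IntegerVector i1(n), i2(n);
  for (int i = 0; i < n; ++i) {
    double b1 = R_PosInf, b2 = R_PosInf;
    int k1 = 0, k2 = 0;
    for (int j = 0; j < m; ++j) {
      double dx = px[i] - sx[j], dy = py[i] - sy[j];
      double d = dx * dx + dy * dy;
      if (d < b1) { b2 = b1; k2 = k1; b1 = d; k1 = j + 1; }
      else if (d < b2) { b2 = d; k2 = j + 1; }
    }
    d1[i] = b1; d2[i] = b2; i1[i] = k1; i2[i] = k2;
  }
  return List::create(_["d1"] = d1, _["i1"] = i1,
                      _["d2"] = d2, _["i2"] = i2);
}

// Geodesic diameter of a connected mask: the largest within-mask
// shortest-path cost between two pixels. Runs Dijkstra from every
// boundary pixel (diameter endpoints sit on the region boundary) and
// keeps the largest finite distance, then refines once by propagating
// from the best endpoint found.
// [[Rcpp::export]]
double cpp_geodesic_diameter(const LogicalMatrix& mask, double wdiag) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> boundary;
  int npx = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      ++npx;
      bool edge = (r == 0 || r == H - 1 || c == 0 || c == W - 1) ||
        !mask(r - 1, c) || !mask(r + 1, c) ||
        !mask(r, c - 1) || !mask(r, c + 1);
      if (edge) boundary.push_back(r + c * H);
    }
  }
  if (npx <= 1) return 0.0;

  std::vector<double> dist((size_t)H * W);
  typedef std::pair<double, int> Node;
  int best_end = -1;
  double best = 0.0;
  auto propagate = [&](int src) {
    std::fill(dist.begin(), dist.end(), INF);
    std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
    dist[src] = 0.0;
    pq.push(Node(0.0, src));
    while (!pq.empty()) {
      Node top = pq.top(); pq.pop();
      double d = top.first;
      int idx = top.second;
      if (d > dist[idx]) continue;
      int r = idx % H, c = idx / H;
      for (int k = 0; k < 8; ++k) {
        int nr = r + DR8[k], nc = c + DC8[k];
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        if (!mask(nr, nc)) continue;
        double w = (DR8[k] != 0 && DC8[k] != 0) ? wdiag : 1.0;
        int nidx = nr + nc * H;
        if (d + w < dist[nidx]) {
          dist[nidx] = d + w;
          pq.push(Node(d + w, nidx));
        }
      }
    }
    for (int i = 0; i < H * W; ++i) {
      if (mask[i] && dist[i] < INF && dist[i] > best) {
        best = dist[i];
        best_end = i;
      }
    }
  };
  // eccentricity-bound pruning: after propagating from s, any other
  // source t has ecc(t) <= ecc(s) + d(s, t); skip sources whose upper
  // bound cannot beat the current best. Sources are visited in order of
  // decreasing upper bound.
  const size_t B = boundary.size();
  std::vector<double> ub(B, INF);
  std::vector<bool> done(B, false);
  for (;;) {
    int pick = -1;
    double pick_ub = -1.0;
    for (size_t b = 0; b < B; ++b) {
      if (!done[b] && ub[b] > pick_ub) { pick_ub = ub[b]; pick = (int)b; }
    }
    if (pick < 0 || pick_ub <= best) break;
    done[pick] = true;
    propagate(boundary[pick]);
    // eccentricity of this source = max distance reached just now
    double ecc_s = 0.0;
    for (int i = 0; i < H * W; ++i)
      if (mask[i] && dist[i] < INF && dist[i] > ecc_s) ecc_s = dist[i];
    for (size_t b = 0; b < B; ++b) {
      if (done[b]) continue;
      double u = ecc_s + dist[boundary[b]];
      if (u < ub[b]) ub[b] = u;
    }
  }
  if (best_end >= 0) propagate(best_end);
  return best;
}
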