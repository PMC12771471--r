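#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// Median filter over a disc (or square) neighbourhood with replicated borders.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int radius, bool square) {
  int H = img.nrow(), W = img.ncol();
  std::vector<int> dr, dc;
  for (int r = -radius; r <= radius; ++r)
    for (int c = -radius; c <= radius; ++c)
      if (square || r * r + c * c <= radius * radius) {
        dr.push_back(r);
        dc.push_back(c);
      }
  int k = (int)dr.size();
  std::vector<double> buf(k);
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) {
      for (int t = 0; t < k; ++t) {
        int r = i + dr[t], c = j + dc[t];
        r = r < 0 ? 0 : (r >= H ? H - 1 : r);
        c = c < 0 ? 0 : (c >= W ? W - 1 : c);
        buf[t] = img(r, c);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.end());
      double med = buf[k / 2];
      if (k % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + k / 2 - 1,
                         buf.begin() + k / 2);
        med = 0.5 * (med + buf[k / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

static inline void neighbours(int idx, int H, int W, int connectivity,
                              std::vector<int> &out) {
  out.clear();
  int i = idx % H, j = idx / H;  // column-major
  for (int dj = -1; dj <= 1; ++dj)
    for (int di = -1; di <= 1; ++di) {
      if (di == 0 && dj == 0) continue;
      if (connectivity == 4 && di != 0 && dj != 0) continue;
      int r = i + di, c = j + dj;
      if (r < 0 || r >= H || c < 0 || c >= W) continue;
      out.push_back(c * H + r);
    }
}

// Connected-component labelling; labels assigned in column-major scan order
// so ties (e.g. equal-area components) resolve to the lowest label.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol(), n = H * W;
  IntegerMatrix lab(H, W);
  std::vector<int> stack, nb;
  int next = 0;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    ++next;
    lab[idx] = next;
    stack.push_back(idx);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      neighbours(cur, H, W, connectivity, nb);
      for (int q : nb)
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
    }
  }
  return lab;
}

struct FloodNode {
  double priority;  // distance-transform value; flood high to low
  long order;       // insertion counter for deterministic ties
  int idx;
  int label;
};
struct FloodCmp {
  bool operator()(const FloodNode &a, const FloodNode &b) const {
    if (a.priority != b.priority) return a.priority < b.priority;
    return a.order > b.order;  // earlier insertion wins on ties
  }
};

// Marker-based watershed by priority flooding of the distance transform
// (equivalently, watershed of the negated distance map) restricted to mask.
// Marker pixels carry initial labels; every mask pixel connected to a marker
// receives the label of the marker basin that reaches it first.
// [[Rcpp::export]]
IntegerMatrix marker_watershed_cpp(NumericMatrix dist, IntegerMatrix markers,
                                   LogicalMatrix mask, int connectivity) {
  int H = dist.nrow(), W = dist.ncol(), n = H * W;
  IntegerMatrix lab(H, W);
  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodCmp> pq;
  long counter = 0;
  for (int idx = 0; idx < n; ++idx)
    if (mask[idx] && markers[idx] > 0) {
      lab[idx] = markers[idx];
      pq.push({dist[idx], counter++, idx, markers[idx]});
    }
  std::vector<int> nb;
  while (!pq.empty()) {
    FloodNode nd = pq.top();
    pq.pop();
    neighbours(nd.idx, H, W, connectivity, nb);
    for (int q : nb)
      if (mask[q] && lab[q] == 0) {
        lab[q] = lab[nd.idx];
        pq.push({dist[q], counter++, q, lab[q]});
      }
  }
  return lab;
}
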