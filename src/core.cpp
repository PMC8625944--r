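// Low-level raster kernels for the segmentation pipeline.
//
// Matrices are column-major (R layout); element (r, c), 0-based, lives at
// r + c * H.  "Raster order" throughout means row-major scanning (top row
// left-to-right first), which fixes label numbering and queue seeding so
// results are bit-reproducible across platforms.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

// Neighbor offsets in a fixed scan order (row-major around the pixel).
// The same order is mirrored by the plain-R oracle used in the tests.
void neighbor_offsets(int connectivity, std::vector<int>& dr,
                      std::vector<int>& dc) {
  dr.clear();
  dc.clear();
  for (int a = -1; a <= 1; ++a) {
    for (int b = -1; b <= 1; ++b) {
      if (a == 0 && b == 0) continue;
      if (connectivity == 4 && a != 0 && b != 0) continue;
      dr.push_back(a);
      dc.push_back(b);
    }
  }
}

inline int at(int r, int c, int H) { return r + c * H; }

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(const IntegerMatrix& img, int window) {
  const int H = img.nrow(), W = img.ncol(), half = window / 2;
  IntegerMatrix out(H, W);
  std::vector<int> buf(window * window);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int n = 0;
      for (int dc = -half; dc <= half; ++dc) {
        int cc = std::min(std::max(c + dc, 0), W - 1);  // replicate edges
        for (int dr = -half; dr <= half; ++dr) {
          int rr = std::min(std::max(r + dr, 0), H - 1);
          buf[n++] = img(rr, cc);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      out(r, c) = buf[n / 2];
    }
  }
  return out;
}

// Dilation per A (+) B = {z | reflected-B at z hits A}: out(z) is true when
// some b in B has z - b inside A.  Out-of-bounds pixels count as background.
// [[Rcpp::export]]
LogicalMatrix cpp_dilate(const LogicalMatrix& mask, const LogicalMatrix& se) {
  const int H = mask.nrow(), W = mask.ncol();
  const int sh = se.nrow(), sw = se.ncol();
  const int orr = sh / 2, orc = sw / 2;  // origin at the center
  std::vector<int> dr, dc;
  for (int j = 0; j < sw; ++j)
    for (int i = 0; i < sh; ++i)
      if (se(i, j)) {
        dr.push_back(i - orr);
        dc.push_back(j - orc);
      }
  LogicalMatrix out(H, W);
  const int K = (int)dr.size();
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      bool hit = false;
      for (int k = 0; k < K && !hit; ++k) {
        int rr = r - dr[k], cc = c - dc[k];
        if (rr >= 0 && rr < H && cc >= 0 && cc < W && mask(rr, cc)) hit = true;
      }
      out(r, c) = hit;
    }
  }
  return out;
}

// Erosion per A (-) B = {z | B at z fits inside A}; out-of-bounds is
// background, so the structuring element must fit entirely inside the raster.
// [[Rcpp::export]]
LogicalMatrix cpp_erode(const LogicalMatrix& mask, const LogicalMatrix& se) {
  const int H = mask.nrow(), W = mask.ncol();
  const int sh = se.nrow(), sw = se.ncol();
  const int orr = sh / 2, orc = sw / 2;
  std::vector<int> dr, dc;
  for (int j = 0; j < sw; ++j)
    for (int i = 0; i < sh; ++i)
      if (se(i, j)) {
        dr.push_back(i - orr);
        dc.push_back(j - orc);
      }
  LogicalMatrix out(H, W);
  const int K = (int)dr.size();
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      bool fit = true;
      for (int k = 0; k < K && fit; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W || !mask(rr, cc))
          fit = false;
      }
      out(r, c) = fit;
    }
  }
  return out;
}

// Connected-component labeling; labels are assigned in raster order of each
// component's first pixel, starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> dr, dc;
  neighbor_offsets(connectivity, dr, dc);
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> stack;
  int next = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(at(r, c, H));
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % H, pc = p / H;
        for (size_t k = 0; k < dr.size(); ++k) {
          int rr = pr + dr[k], cc = pc + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(at(rr, cc, H));
          }
        }
      }
    }
  }
  return lab;
}

// Exact Euclidean distance to the nearest false pixel (Felzenszwalb &
// Huttenlocher lower-envelope scan on squared distances).
// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  // Pass 1: per column, squared distance to nearest false in that column.
  std::vector<double> g(static_cast<size_t>(H) * W, INF);
  for (int c = 0; c < W; ++c) {
    double d = INF;
    for (int r = 0; r < H; ++r) {
      d = mask(r, c) ? (d + 1.0) : 0.0;
      g[at(r, c, H)] = d;
    }
    d = INF;
    for (int r = H - 1; r >= 0; --r) {
      d = mask(r, c) ? (d + 1.0) : 0.0;
      double& v = g[at(r, c, H)];
      if (d < v) v = d;
    }
  }
  // Columns with no background pixel keep a huge (but finite) sentinel so
  // the envelope arithmetic stays well defined; the caller guarantees the
  // mask has at least one false pixel, so every row resolves to finite
  // distances through some finite column.
  const double BIG = 1e15;
  for (size_t i = 0; i < g.size(); ++i)
    g[i] = std::isfinite(g[i]) ? g[i] * g[i] : BIG;
  // Pass 2: per row, lower envelope of parabolas rooted at (c', g(r,c')).
  NumericMatrix out(H, W);
  std::vector<int> v(W);
  std::vector<double> z(W + 1), f(W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) f[c] = g[at(r, c, H)];
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < W; ++q) {
      double s;
      while (true) {
        int p = v[k];
        s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) /
            (2.0 * q - 2.0 * p);
        if (s <= z[k]) {
          --k;
        } else {
          break;
        }
      }
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = INF;
    }
    int k2 = 0;
    for (int q = 0; q < W; ++q) {
      while (z[k2 + 1] < q) ++k2;
      int p = v[k2];
      out(r, q) = std::sqrt((q - p) * (double)(q - p) + f[p]);
    }
  }
  return out;
}

// Grayscale reconstruction by dilation (Vincent's hybrid raster/FIFO
// algorithm): marker <= mask everywhere, result is the largest image
// below mask reachable from marker by geodesic dilations.
static IntegerMatrix reconstruct_dilation(IntegerMatrix J,
                                          const IntegerMatrix& mask,
                                          int connectivity) {
  const int H = J.nrow(), W = J.ncol();
  std::vector<int> dr, dc;
  neighbor_offsets(connectivity, dr, dc);
  const size_t K = dr.size();
  // forward raster scan (uses "already visited" half of the neighborhood)
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int m = J(r, c);
      for (size_t k = 0; k < K / 2; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (J(rr, cc) > m) m = J(rr, cc);
      }
      J(r, c) = std::min(m, mask(r, c));
    }
  }
  // backward scan + queue seeding
  std::queue<int> fifo;
  for (int r = H - 1; r >= 0; --r) {
    for (int c = W - 1; c >= 0; --c) {
      int m = J(r, c);
      for (size_t k = K / 2; k < K; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (J(rr, cc) > m) m = J(rr, cc);
      }
      J(r, c) = std::min(m, mask(r, c));
      for (size_t k = K / 2; k < K; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          fifo.push(at(r, c, H));
          break;
        }
      }
    }
  }
  while (!fifo.empty()) {
    int p = fifo.front();
    fifo.pop();
    int pr = p % H, pc = p / H;
    for (size_t k = 0; k < K; ++k) {
      int rr = pr + dr[k], cc = pc + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (J(rr, cc) < J(pr, pc) && mask(rr, cc) != J(rr, cc)) {
        J(rr, cc) = std::min(J(pr, pc), mask(rr, cc));
        fifo.push(at(rr, cc, H));
      }
    }
  }
  return J;
}

// Reconstruction by erosion, the dual: marker >= mask everywhere.
// [[Rcpp::export]]
IntegerMatrix cpp_reconstruct_erosion(const IntegerMatrix& marker,
                                      const IntegerMatrix& mask,
                                      int connectivity) {
  const int H = marker.nrow(), W = marker.ncol();
  IntegerMatrix nm(H, W), nk(H, W);
  for (int i = 0; i < H * W; ++i) {
    nm[i] = -marker[i];
    nk[i] = -mask[i];
  }
  IntegerMatrix res = reconstruct_dilation(nm, nk, connectivity);
  for (int i = 0; i < H * W; ++i) res[i] = -res[i];
  return res;
}

// Regional minima: connected plateaus with no strictly lower neighbor.
// Pixels where inside == false are ignored (treated as +infinity walls).
// [[Rcpp::export]]
LogicalMatrix cpp_regional_minima(const IntegerMatrix& surf, int connectivity,
                                  const LogicalMatrix& inside) {
  const int H = surf.nrow(), W = surf.ncol();
  std::vector<int> dr, dc;
  neighbor_offsets(connectivity, dr, dc);
  LogicalMatrix out(H, W);
  std::vector<signed char> state(static_cast<size_t>(H) * W, 0);
  // state: 0 unvisited, 1 in current plateau, 2 resolved
  std::vector<int> plateau, stack;
  for (int r0 = 0; r0 < H; ++r0) {
    for (int c0 = 0; c0 < W; ++c0) {
      int p0 = at(r0, c0, H);
      if (state[p0] != 0 || !inside(r0, c0)) continue;
      const int v = surf(r0, c0);
      bool is_min = true;
      plateau.clear();
      stack.clear();
      stack.push_back(p0);
      state[p0] = 1;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        plateau.push_back(p);
        int pr = p % H, pc = p / H;
        for (size_t k = 0; k < dr.size(); ++k) {
          int rr = pr + dr[k], cc = pc + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (!inside(rr, cc)) continue;
          int q = at(rr, cc, H);
          int vq = surf(rr, cc);
          if (vq < v) is_min = false;
          if (vq == v && state[q] == 0) {
            state[q] = 1;
            stack.push_back(q);
          }
        }
      }
      for (size_t i = 0; i < plateau.size(); ++i) {
        state[plateau[i]] = 2;
        if (is_min) out[plateau[i]] = true;
      }
    }
  }
  return out;
}

// Meyer's marker-driven flooding.  seeds: 0 = unlabeled, k > 0 = basin seed.
// Pixels outside `inside` stay 0 and act as walls.  The priority queue orders
// by height then by a FIFO push counter, seeded in raster order, so flooding
// is fully deterministic.  Pixels whose labeled neighbors disagree at pop
// time become ridge pixels (label 0, final).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const IntegerMatrix& surf,
                            const IntegerMatrix& seeds,
                            const LogicalMatrix& inside, int connectivity) {
  const int H = surf.nrow(), W = surf.ncol();
  std::vector<int> dr, dc;
  neighbor_offsets(connectivity, dr, dc);
  const size_t K = dr.size();
  IntegerMatrix lab(H, W);
  std::vector<signed char> done(static_cast<size_t>(H) * W, 0);

  struct Node {
    int height;
    std::int64_t order;
    int idx;
  };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.height != b.height) return a.height > b.height;
      return a.order > b.order;  // FIFO within a height level
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  std::int64_t counter = 0;

  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!inside(r, c)) {
        done[at(r, c, H)] = 1;
        continue;
      }
      if (seeds(r, c) > 0) {
        lab(r, c) = seeds(r, c);
        done[at(r, c, H)] = 1;
      }
    }
  }
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (seeds(r, c) <= 0 || !inside(r, c)) continue;
      for (size_t k = 0; k < K; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (!done[at(rr, cc, H)])
          pq.push({surf(rr, cc), counter++, at(rr, cc, H)});
      }
    }
  }
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    if (done[nd.idx]) continue;
    int pr = nd.idx % H, pc = nd.idx / H;
    int found = 0;
    bool conflict = false;
    for (size_t k = 0; k < K; ++k) {
      int rr = pr + dr[k], cc = pc + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (!inside(rr, cc)) continue;
      int lq = lab(rr, cc);
      if (lq > 0 && done[at(rr, cc, H)]) {
        if (found == 0) {
          found = lq;
        } else if (found != lq) {
          conflict = true;
        }
      }
    }
    if (found == 0) continue;  // may be re-reached later from a labeled side
    done[nd.idx] = 1;
    if (conflict) {
      lab(pr, pc) = 0;  // watershed ridge
      continue;
    }
    lab(pr, pc) = found;
    for (size_t k = 0; k < K; ++k) {
      int rr = pr + dr[k], cc = pc + dc[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (!done[at(rr, cc, H)])
        pq.push({surf(rr, cc), counter++, at(rr, cc, H)});
    }
  }
  return lab;
}
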