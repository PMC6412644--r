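// Low-level morphological kernels used by the segmentation pipeline:
// grayscale reconstruction by dilation (Vincent's hybrid algorithm),
// connected-component labeling, regional-minima detection and a
// deterministic marker-driven priority-flood watershed.
//
// All matrices are column-major (R layout); "raster order" below means
// column-major order. Connectivity is 4 or 8.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline void neighbour_offsets(int conn, std::vector<int>& dr,
                                     std::vector<int>& dc) {
  // fixed scan order: column-major sweep of the 3x3 neighbourhood
  static const int dr8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dc8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dr4[4] = {0, -1, 1, 0};
  static const int dc4[4] = {-1, 0, 0, 1};
  dr.clear(); dc.clear();
  if (conn == 8) {
    dr.assign(dr8, dr8 + 8); dc.assign(dc8, dc8 + 8);
  } else {
    dr.assign(dr4, dr4 + 4); dc.assign(dc4, dc4 + 4);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask,
                                     int conn) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have the same dimensions");
  if (conn != 4 && conn != 8) stop("conn must be 4 or 8");

  NumericMatrix J(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      J(i, j) = std::min(marker(i, j), mask(i, j));

  std::vector<int> dr, dc;
  neighbour_offsets(conn, dr, dc);
  const int nn = (int) dr.size();

  // forward raster sweep (predecessors in raster order)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = J(i, j);
      for (int k = 0; k < nn; ++k) {
        int ii = i + dr[k], jj = j + dc[k];
        if (jj < j || (jj == j && ii < i)) {
          if (ii >= 0 && ii < nr && jj >= 0 && jj < nc)
            v = std::max(v, J(ii, jj));
        }
      }
      J(i, j) = std::min(v, mask(i, j));
    }
  }

  // backward sweep, enqueue pixels with a lower, unsaturated successor
  std::queue<int> fifo;
  std::vector<char> queued((size_t) nr * nc, 0);
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      double v = J(i, j);
      for (int k = 0; k < nn; ++k) {
        int ii = i + dr[k], jj = j + dc[k];
        if (jj > j || (jj == j && ii > i)) {
          if (ii >= 0 && ii < nr && jj >= 0 && jj < nc)
            v = std::max(v, J(ii, jj));
        }
      }
      J(i, j) = std::min(v, mask(i, j));
      bool push = false;
      for (int k = 0; k < nn && !push; ++k) {
        int ii = i + dr[k], jj = j + dc[k];
        if (jj > j || (jj == j && ii > i)) {
          if (ii >= 0 && ii < nr && jj >= 0 && jj < nc)
            if (J(ii, jj) < J(i, j) && J(ii, jj) < mask(ii, jj)) push = true;
        }
      }
      if (push && !queued[(size_t) j * nr + i]) {
        fifo.push(j * nr + i);
        queued[(size_t) j * nr + i] = 1;
      }
    }
  }

  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int i = p % nr, j = p / nr;
    queued[(size_t) p] = 0;
    for (int k = 0; k < nn; ++k) {
      int ii = i + dr[k], jj = j + dc[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (J(ii, jj) < J(i, j) && J(ii, jj) < mask(ii, jj)) {
        J(ii, jj) = std::min(J(i, j), mask(ii, jj));
        int q = jj * nr + ii;
        if (!queued[(size_t) q]) { fifo.push(q); queued[(size_t) q] = 1; }
      }
    }
  }
  return J;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix x, int conn) {
  const int nr = x.nrow(), nc = x.ncol();
  if (conn != 4 && conn != 8) stop("conn must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  std::vector<int> dr, dc;
  neighbour_offsets(conn, dr, dc);
  const int nn = (int) dr.size();
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!x(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(j * nr + i);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nn; ++k) {
          int ii = pi + dr[k], jj = pj + dc[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (x(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(jj * nr + ii);
          }
        }
      }
    }
  }
  return lab;
}

// [[Rcpp::export]]
LogicalMatrix cpp_regional_minima(NumericMatrix x, int conn) {
  const int nr = x.nrow(), nc = x.ncol();
  if (conn != 4 && conn != 8) stop("conn must be 4 or 8");
  LogicalMatrix out(nr, nc);
  std::vector<char> visited((size_t) nr * nc, 0);
  std::vector<int> dr, dc;
  neighbour_offsets(conn, dr, dc);
  const int nn = (int) dr.size();
  std::vector<int> plateau, stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (visited[(size_t) j * nr + i]) continue;
      const double v = x(i, j);
      bool is_min = true;
      plateau.clear();
      stack.clear();
      stack.push_back(j * nr + i);
      visited[(size_t) j * nr + i] = 1;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        plateau.push_back(p);
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nn; ++k) {
          int ii = pi + dr[k], jj = pj + dc[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          double w = x(ii, jj);
          if (w < v) is_min = false;
          else if (w == v && !visited[(size_t) jj * nr + ii]) {
            visited[(size_t) jj * nr + ii] = 1;
            stack.push_back(jj * nr + ii);
          }
        }
      }
      if (is_min)
        for (size_t k = 0; k < plateau.size(); ++k)
          out[plateau[k]] = true;
    }
  }
  return out;
}

struct WsEntry {
  double value;
  long long counter;
  int idx;
};

struct WsCompare {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.value != b.value) return a.value > b.value;   // lower value first
    return a.counter > b.counter;                       // then FIFO
  }
};

// Meyer's flooding from labeled markers. Ties on the flooding surface are
// broken by queue insertion order, which makes the transform deterministic.
// A popped pixel takes the label of its already-labeled neighbours when they
// agree; disagreeing neighbours make it a ridge pixel, assigned either to the
// lowest adjacent label (assign_ridge) or left 0.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix surface, IntegerMatrix markers,
                            int conn, bool assign_ridge) {
  const int nr = surface.nrow(), nc = surface.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("surface and markers must have the same dimensions");
  if (conn != 4 && conn != 8) stop("conn must be 4 or 8");

  IntegerMatrix lab(nr, nc);
  std::vector<char> state((size_t) nr * nc, 0); // 0 far, 1 queued, 2 done
  bool any_marker = false;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int m = markers(i, j);
      if (m < 0) stop("marker labels must be >= 0");
      lab(i, j) = m;
      if (m > 0) { state[(size_t) j * nr + i] = 2; any_marker = true; }
    }
  if (!any_marker) stop("at least one marker pixel is required");

  std::vector<int> dr, dc;
  neighbour_offsets(conn, dr, dc);
  const int nn = (int) dr.size();

  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCompare> pq;
  long long counter = 0;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) == 0) continue;
      for (int k = 0; k < nn; ++k) {
        int ii = i + dr[k], jj = j + dc[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        size_t q = (size_t) jj * nr + ii;
        if (state[q] == 0) {
          state[q] = 1;
          pq.push(WsEntry{surface(ii, jj), counter++, jj * nr + ii});
        }
      }
    }

  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    int i = e.idx % nr, j = e.idx / nr;
    size_t p = (size_t) e.idx;
    if (state[p] == 2) continue;
    state[p] = 2;

    int first = 0;
    bool conflict = false;
    int lowest = 0;
    for (int k = 0; k < nn; ++k) {
      int ii = i + dr[k], jj = j + dc[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (state[(size_t) jj * nr + ii] == 2) {
        int l = lab(ii, jj);
        if (l <= 0) continue; // ridge neighbours don't vote
        if (first == 0) { first = l; lowest = l; }
        else if (l != first) conflict = true;
        if (l < lowest) lowest = l;
      }
    }
    if (first == 0) continue; // isolated (cannot happen with conn >= 4 seeding)
    int assigned;
    if (!conflict) assigned = first;
    else assigned = assign_ridge ? lowest : 0;
    lab(i, j) = assigned;

    bool propagate = assigned > 0;
    if (propagate) {
      for (int k = 0; k < nn; ++k) {
        int ii = i + dr[k], jj = j + dc[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        size_t q = (size_t) jj * nr + ii;
        if (state[q] == 0) {
          state[q] = 1;
          pq.push(WsEntry{surface(ii, jj), counter++, jj * nr + ii});
        }
      }
    }
  }
  return lab;
}
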