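#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Marker-controlled watershed by priority flooding (Meyer's algorithm,
// 4-connected, FIFO tie-break). Every pixel ends up in the basin of some
// marker; no explicit watershed-line pixels are kept, so downstream masking
// is simply "label belongs to a foreground marker".

struct QEntry {
  double prio;
  long order;
  int idx;
  int label;
};

struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // min-heap on priority
    return a.order > b.order;                      // FIFO among equals
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix priority, IntegerMatrix markers) {
  const int nr = priority.nrow(), nc = priority.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc)
    stop("priority and marker images differ in size");
  IntegerMatrix labels = clone(markers);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  long counter = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (labels(r, c) <= 0) continue;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (labels(rr, cc) == 0)
          pq.push({priority(rr, cc), counter++, rr + cc * nr, labels(r, c)});
      }
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    int r = e.idx % nr, c = e.idx / nr;
    if (labels(r, c) != 0) continue;
    labels(r, c) = e.label;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (labels(rr, cc) == 0)
        pq.push({priority(rr, cc), counter++, rr + cc * nr, e.label});
    }
  }
  return labels;
}

// Connected-component labelling of a binary image (BFS), connectivity 4 or 8.
// Returns 0 for background, 1..K for components in scan order.

// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix labels(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nlab = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++nlab;
      stack.clear();
      stack.push_back(r + c * nr);
      labels(r, c) = nlab;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr0 = idx % nr, cc0 = idx / nr;
        for (int k = 0; k < connectivity; ++k) {
          int rr = rr0 + dr8[k], cc = cc0 + dc8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && labels(rr, cc) == 0) {
            labels(rr, cc) = nlab;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  }
  return labels;
}
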