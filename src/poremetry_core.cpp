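#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 8-neighbour offsets in clockwise ring order starting East.
static const int DR[8] = { 0, -1, -1, -1,  0,  1, 1, 1 };
static const int DC[8] = { 1,  1,  0, -1, -1, -1, 0, 1 };

// Connected-component labelling with 4- or 8-connectivity (BFS, row-major
// label order so labels are deterministic).
// [[Rcpp::export]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int r = q.front().first, c = q.front().second; q.pop();
        for (int k = 0; k < 8; ++k) {
          if (connectivity == 4 && (k % 2) == 1) continue;
          int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Ring of the 8 neighbours of (i,j); out-of-frame counts as background.
static inline void ring(const LogicalMatrix& fg, int i, int j, int* x) {
  const int nr = fg.nrow(), nc = fg.ncol();
  for (int k = 0; k < 8; ++k) {
    int r = i + DR[k], c = j + DC[k];
    x[k] = (r >= 0 && r < nr && c >= 0 && c < nc) ? (fg(r, c) ? 1 : 0) : 0;
  }
}

// Number of 8-connected foreground components in the neighbour ring.
static int fg_components8(const int* x) {
  int seen[8] = {0,0,0,0,0,0,0,0};
  int comp = 0;
  for (int s = 0; s < 8; ++s) {
    if (!x[s] || seen[s]) continue;
    ++comp;
    // walk the ring both ways; ring positions k and k+1 are 8-adjacent
    // pixels, so contiguous runs of 1s form one component.
    int k = s;
    while (x[k] && !seen[k]) { seen[k] = 1; k = (k + 1) % 8; }
    k = (s + 7) % 8;
    while (x[k] && !seen[k]) { seen[k] = 1; k = (k + 7) % 8; }
  }
  return comp;
}

// Number of 4-connected background components in the ring that are
// 4-adjacent to the centre (Yokoi connectivity for the complement).
static int bg_components4(const int* x) {
  // count transitions using the standard crossing-number form:
  // sum over k in {0,2,4,6} of b_k - b_k*b_{k+1}*b_{k+2}, b = 1-x
  int b[8];
  for (int k = 0; k < 8; ++k) b[k] = 1 - x[k];
  int n = 0;
  for (int k = 0; k < 8; k += 2)
    n += b[k] - b[k] * b[(k + 1) % 8] * b[(k + 2) % 8];
  return n;
}

static inline bool is_simple(const LogicalMatrix& fg, int i, int j) {
  int x[8];
  ring(fg, i, j, x);
  int nfg = 0;
  for (int k = 0; k < 8; ++k) nfg += x[k];
  if (nfg == 0) return false;              // isolated pixel: keep
  return fg_components8(x) == 1 && bg_components4(x) == 1;
}

static inline bool is_endpoint(const LogicalMatrix& fg, int i, int j) {
  int x[8];
  ring(fg, i, j, x);
  int nfg = 0;
  for (int k = 0; k < 8; ++k) nfg += x[k];
  return nfg == 1;
}

struct PixOrd {
  double d; int idx;
  bool operator<(const PixOrd& o) const {
    if (d != o.d) return d < o.d;
    return idx < o.idx;                    // column-major: deterministic
  }
};

// Medial-axis skeleton by anchored directional thinning.
//
// Anchors are the distance-map ridge pixels: a phase pixel is an anchor if
// it is a plateau local maximum (distance >= all 8 neighbours) and exceeds
// both neighbours along at least one direction pair (N/S, E/W or a
// diagonal) by at least half a pixel -- the quantization step of exact
// pixel-centre distances, which separates genuine ridges from the shallow
// lattice-aligned undulations of a discrete distance map.  Anchors are
// never deleted, so the skeleton passes through the medial-axis ridge.
//
// Thinning then peels boundary layers in four directional subpasses per
// round (south-, east-, north-, then west-border), the candidate set of
// each subpass frozen at its start so that a two-pixel-wide ridge plateau
// collapses onto a single centre line instead of eroding from its ends;
// within a subpass candidates are processed in order of increasing
// distance value (ties column-major) and deleted only if the deletion
// preserves local topology (simple point: one 8-connected foreground and
// one 4-connected background component in the neighbourhood) and the
// pixel is not a curve endpoint.  The subpass order makes the plateau
// tie-break deterministic: of two tied centre rows the one with the
// smaller row index survives.
// [[Rcpp::export]]
LogicalMatrix thin_skeleton(const LogicalMatrix& phase, const NumericMatrix& dist) {
  const int nr = phase.nrow(), nc = phase.ncol();
  if (dist.nrow() != nr || dist.ncol() != nc)
    stop("phase and dist dimensions differ");
  LogicalMatrix fg = clone(phase);

  // ridge anchors: strict maximum along >= 1 direction pair
  // direction pairs as ring indices: (E,W)=(0,4), (NE,SW)=(1,5),
  // (N,S)=(2,6), (NW,SE)=(3,7); out-of-frame neighbours count as d = 0.
  LogicalMatrix anchor(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!fg(i, j)) continue;
      // out-of-frame neighbours count as ties: the frame is not a wall
      // and must not support a ridge
      double dv[8];
      for (int k = 0; k < 8; ++k) {
        int r = i + DR[k], c = j + DC[k];
        dv[k] = (r >= 0 && r < nr && c >= 0 && c < nc) ? dist(r, c)
                                                       : dist(i, j);
      }
      bool plateau = true;
      for (int k = 0; k < 8 && plateau; ++k)
        if (dv[k] > dist(i, j)) plateau = false;
      bool a = false;
      for (int k = 0; k < 4 && !a; ++k)
        if (dist(i, j) >= dv[k] + 0.5 && dist(i, j) >= dv[k + 4] + 0.5) a = true;
      anchor(i, j) = plateau && a;
    }
  }

  // border directions, subpass order: south, east, north, west
  static const int BDR[4] = { 1, 0, -1,  0 };
  static const int BDC[4] = { 0, 1,  0, -1 };

  bool changed = true;
  std::vector<PixOrd> cand;
  while (changed) {
    changed = false;
    for (int s = 0; s < 4; ++s) {
      cand.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!fg(i, j) || anchor(i, j)) continue;
          int r = i + BDR[s], c = j + BDC[s];
          bool border = (r < 0 || r >= nr || c < 0 || c >= nc) ? false : !fg(r, c);
          if (!border) continue;
          PixOrd p; p.d = dist(i, j); p.idx = j * nr + i;
          cand.push_back(p);
        }
      }
      std::sort(cand.begin(), cand.end());
      for (size_t m = 0; m < cand.size(); ++m) {
        int i = cand[m].idx % nr, j = cand[m].idx / nr;
        if (!fg(i, j)) continue;
        if (is_endpoint(fg, i, j)) continue;
        if (!is_simple(fg, i, j)) continue;
        fg(i, j) = false;
        changed = true;
      }
    }
  }
  return fg;
}
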