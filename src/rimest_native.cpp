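#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// kd-tree over the rows of an N x 3 point matrix.
//
// The reference cloud is indexed once and queried for every frame of a
// sequence, so the tree lives behind an external pointer on the R side.
// ---------------------------------------------------------------------------

struct KdTree {
  std::vector<double> pts;        // row-major N x 3
  std::vector<int> idx;           // permutation of 0..N-1, tree order
  int n;

  double coord(int i, int d) const { return pts[3 * i + d]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    int d = depth % 3;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, d) < coord(b, d); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(const double *q, int lo, int hi, int depth,
             double &best, int &besti) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int p = idx[mid];
    double dx = q[0] - coord(p, 0);
    double dy = q[1] - coord(p, 1);
    double dz = q[2] - coord(p, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best || (d2 == best && (besti < 0 || p < besti))) {
      // ties broken toward the smallest original row index (deterministic)
      if (d2 < best || p < besti) { best = d2; besti = p; }
    }
    int d = depth % 3;
    double diff = q[d] - coord(p, d);
    int nearLo, nearHi, farLo, farHi;
    if (diff < 0) { nearLo = lo; nearHi = mid; farLo = mid + 1; farHi = hi; }
    else          { nearLo = mid + 1; nearHi = hi; farLo = lo; farHi = mid; }
    query(q, nearLo, nearHi, depth + 1, best, besti);
    if (diff * diff <= best)
      query(q, farLo, farHi, depth + 1, best, besti);
  }
};

// [[Rcpp::export(name = ".cpp_kdtree_build")]]
SEXP cpp_kdtree_build(NumericMatrix ref) {
  if (ref.ncol() != 3) stop("reference points must be an N x 3 matrix");
  KdTree *t = new KdTree();
  t->n = ref.nrow();
  t->pts.resize(3 * t->n);
  for (int i = 0; i < t->n; ++i)
    for (int d = 0; d < 3; ++d) t->pts[3 * i + d] = ref(i, d);
  t->idx.resize(t->n);
  for (int i = 0; i < t->n; ++i) t->idx[i] = i;
  t->build(0, t->n, 0);
  XPtr<KdTree> p(t, true);
  return p;
}

// Nearest reference neighbor for each query row: Euclidean distance and
// 1-based index into the reference matrix.
// [[Rcpp::export(name = ".cpp_kdtree_nn")]]
List cpp_kdtree_nn(SEXP treeptr, NumericMatrix query) {
  XPtr<KdTree> t(treeptr);
  if (query.ncol() != 3) stop("query points must be an N x 3 matrix");
  int n = query.nrow();
  NumericVector dist(n);
  IntegerVector index(n);
  double q[3];
  for (int i = 0; i < n; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    double best = R_PosInf;
    int besti = -1;
    t->query(q, 0, t->n, 0, best, besti);
    dist[i] = std::sqrt(best);
    index[i] = besti + 1;
  }
  return List::create(_["dist"] = dist, _["index"] = index);
}

// ---------------------------------------------------------------------------
// Connected-component labeling of a binary image, 8-connectivity (BFS).
// Labels are assigned in row-major scan order of the first pixel met, so
// component 1 contains the first foreground pixel in row-major order.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > bfs;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      bfs.push(std::make_pair(r, c));
      while (!bfs.empty()) {
        std::pair<int, int> p = bfs.front(); bfs.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = p.first + dr, cc = p.second + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              bfs.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}
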