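// Pixel-grid geometry primitives shared by the annotation rasterizer, the
// object extractor and the evaluation code.
//
// Conventions (package-wide): coordinates are 0-based, x right / y down, in
// pixel units; pixel (row r, col c) of an H x W matrix occupies the unit
// square [c, c+1] x [r, r+1] and has its center at (c + 0.5, r + 0.5).
// A pixel belongs to a polygon iff its center is inside under the even-odd
// rule. Region outlines are traced along pixel edges, so the shoelace area
// of a traced outline equals the pixel count of the region.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <functional>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Linear 1-based indices (into an H x W R matrix) of pixels whose center
// lies inside the polygon (even-odd rule, scanline over pixel centers).
// [[Rcpp::export]]
IntegerVector fill_polygon_cpp(NumericVector xs, NumericVector ys,
                               int H, int W) {
  const int n = xs.size();
  std::vector<int> out;
  if (n < 3) return IntegerVector(0);
  double ymin = *std::min_element(ys.begin(), ys.end());
  double ymax = *std::max_element(ys.begin(), ys.end());
  int r0 = std::max(0, (int)std::floor(ymin - 0.5));
  int r1 = std::min(H - 1, (int)std::ceil(ymax));
  std::vector<double> xcross;
  for (int r = r0; r <= r1; ++r) {
    double y = r + 0.5;
    xcross.clear();
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double y0 = ys[i], y1 = ys[j];
      if ((y0 <= y && y < y1) || (y1 <= y && y < y0)) {
        double t = (y - y0) / (y1 - y0);
        xcross.push_back(xs[i] + t * (xs[j] - xs[i]));
      }
    }
    std::sort(xcross.begin(), xcross.end());
    for (size_t k = 0; k + 1 < xcross.size(); k += 2) {
      // pixel centers c + 0.5 in [xcross[k], xcross[k+1])
      int c0 = (int)std::ceil(xcross[k] - 0.5);
      int c1 = (int)std::ceil(xcross[k + 1] - 0.5) - 1;
      c0 = std::max(c0, 0);
      c1 = std::min(c1, W - 1);
      for (int c = c0; c <= c1; ++c)
        out.push_back(r + 1 + c * H);  // 1-based linear index
    }
  }
  return wrap(out);
}

// Paint polygons into an existing integer mask (modified copy returned).
// Polygons are painted in the order given; later polygons overwrite earlier
// ones, so the caller encodes label precedence by ordering.
// [[Rcpp::export]]
IntegerMatrix paint_polygons_cpp(IntegerMatrix mask, List xs_list,
                                 List ys_list, IntegerVector values) {
  IntegerMatrix m = clone(mask);
  const int H = m.nrow(), W = m.ncol();
  for (int p = 0; p < xs_list.size(); ++p) {
    NumericVector xs = xs_list[p], ys = ys_list[p];
    IntegerVector idx = fill_polygon_cpp(xs, ys, H, W);
    for (int k = 0; k < idx.size(); ++k) m[idx[k] - 1] = values[p];
  }
  return m;
}

// 8-connected labeling of a binary mask; two-pass union-find.
// Returns an integer matrix with labels 1..K (0 = background).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 1;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      // neighbors already visited in column-major order: (r-1,c), (r,c-1),
      // (r-1,c-1), (r+1,c-1)
      const int dr[4] = {-1, 0, -1, 1};
      const int dc[4] = {0, -1, -1, -1};
      int labs[4], nl = 0;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr >= 0 && rr < H && cc >= 0 && cc < W && lab(rr, cc) > 0)
          labs[nl++] = lab(rr, cc);
      }
      for (int k = 0; k < nl; ++k)
        if (best == 0 || find(labs[k]) < find(best)) best = labs[k];
      if (best == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = find(best);
        for (int k = 0; k < nl; ++k) unite(best, labs[k]);
      }
    }
  }
  // flatten and renumber 1..K
  std::vector<int> remap(parent.size(), 0);
  int K = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c) > 0) {
        int root = find(lab(r, c));
        if (remap[root] == 0) remap[root] = ++K;
        lab(r, c) = remap[root];
      }
  return lab;
}

// Outer outline of the region {labels == id}, traced along pixel edges
// keeping the region on the right (left-turn preference, so 8-connected
// regions yield a single outline). Returns an (n x 2) matrix of (x, y)
// lattice corners, collinear points removed, not closed (first != last).
// [[Rcpp::export]]
NumericMatrix trace_outline_cpp(IntegerMatrix labels, int id) {
  const int H = labels.nrow(), W = labels.ncol();
  auto inside = [&](int r, int c) {
    return r >= 0 && r < H && c >= 0 && c < W && labels(r, c) == id;
  };
  // start: top-left-most region pixel in (row, then col) scan
  int sr = -1, sc = -1;
  for (int r = 0; r < H && sr < 0; ++r)
    for (int c = 0; c < W; ++c)
      if (labels(r, c) == id) { sr = r; sc = c; break; }
  if (sr < 0) return NumericMatrix(0, 2);
  // directions 0=E,1=S,2=W,3=N; dx,dy per direction
  const int dx[4] = {1, 0, -1, 0};
  const int dy[4] = {0, 1, 0, -1};
  // pixel on the right / left of an edge leaving corner (x,y) in direction d
  auto rightPix = [&](int x, int y, int d, int &r, int &c) {
    switch (d) {
      case 0: r = y;     c = x;     break;  // E: south side
      case 1: r = y;     c = x - 1; break;  // S: west side
      case 2: r = y - 1; c = x - 1; break;  // W: north side
      case 3: r = y - 1; c = x;     break;  // N: east side
    }
  };
  auto leftPix = [&](int x, int y, int d, int &r, int &c) {
    switch (d) {
      case 0: r = y - 1; c = x;     break;
      case 1: r = y;     c = x;     break;
      case 2: r = y;     c = x - 1; break;
      case 3: r = y - 1; c = x - 1; break;
    }
  };
  auto edgeOK = [&](int x, int y, int d) {
    int rr, cc, rl, cl;
    rightPix(x, y, d, rr, cc);
    leftPix(x, y, d, rl, cl);
    return inside(rr, cc) && !inside(rl, cl);
  };
  int x = sc, y = sr, d = 0;  // top-left corner of start pixel, heading E
  std::vector<double> px, py;
  const int x0 = x, y0 = y, d0 = d;
  int guard = 0, guard_max = 4 * (H + 2) * (W + 2);
  do {
    px.push_back(x); py.push_back(y);
    x += dx[d]; y += dy[d];
    // preference: left turn, straight, right turn, back
    int dl = (d + 3) % 4, ds = d, dr2 = (d + 1) % 4, db = (d + 2) % 4;
    if (edgeOK(x, y, dl)) d = dl;
    else if (edgeOK(x, y, ds)) d = ds;
    else if (edgeOK(x, y, dr2)) d = dr2;
    else d = db;  // isolated dead end (cannot happen on a valid region)
    if (++guard > guard_max) stop("outline tracing failed to terminate");
  } while (!(x == x0 && y == y0 && d == d0));
  // drop collinear points
  const int n = px.size();
  std::vector<double> ox, oy;
  for (int i = 0; i < n; ++i) {
    double ax = px[(i + n - 1) % n], ay = py[(i + n - 1) % n];
    double bx = px[i], by = py[i];
    double cx = px[(i + 1) % n], cy = py[(i + 1) % n];
    if ((bx - ax) * (cy - by) != (by - ay) * (cx - bx)) {
      ox.push_back(bx); oy.push_back(by);
    }
  }
  NumericMatrix out(ox.size(), 2);
  for (size_t i = 0; i < ox.size(); ++i) { out(i, 0) = ox[i]; out(i, 1) = oy[i]; }
  return out;
}

// Contingency tally of two equally sized integer label matrices:
// counts of pixels per (a, b) pair with a > 0 and b > 0, plus marginal
// pixel counts per label. Used for coverage computations.
// [[Rcpp::export]]
List overlap_tally_cpp(IntegerMatrix A, IntegerMatrix B) {
  if (A.nrow() != B.nrow() || A.ncol() != B.ncol())
    stop("label matrices must have identical dimensions");
  int maxA = 0, maxB = 0;
  const int n = A.size();
  for (int i = 0; i < n; ++i) {
    if (A[i] > maxA) maxA = A[i];
    if (B[i] > maxB) maxB = B[i];
  }
  std::vector<double> sizeA(maxA + 1, 0), sizeB(maxB + 1, 0);
  std::map<std::pair<int, int>, double> tal;
  for (int i = 0; i < n; ++i) {
    if (A[i] > 0) sizeA[A[i]] += 1;
    if (B[i] > 0) sizeB[B[i]] += 1;
    if (A[i] > 0 && B[i] > 0) tal[{A[i], B[i]}] += 1;
  }
  const int m = tal.size();
  IntegerVector ia(m), ib(m);
  NumericVector cnt(m);
  int k = 0;
  for (auto &kv : tal) {
    ia[k] = kv.first.first; ib[k] = kv.first.second; cnt[k] = kv.second; ++k;
  }
  return List::create(_["a"] = ia, _["b"] = ib, _["n"] = cnt,
                      _["size_a"] = wrap(sizeA), _["size_b"] = wrap(sizeB));
}

// Stamp filled discs of one radius into an H x W x 3 numeric array
// (column-major, values 0..255). Used by the synthetic slide renderer.
// [[Rcpp::export]]
NumericVector stamp_discs_cpp(NumericVector img, int H, int W,
                              NumericVector cx, NumericVector cy,
                              double radius, NumericVector rgb) {
  NumericVector out = clone(img);
  const double r2 = radius * radius;
  for (int k = 0; k < cx.size(); ++k) {
    int rlo = std::max(0, (int)std::floor(cy[k] - radius - 1));
    int rhi = std::min(H - 1, (int)std::ceil(cy[k] + radius + 1));
    int clo = std::max(0, (int)std::floor(cx[k] - radius - 1));
    int chi = std::min(W - 1, (int)std::ceil(cx[k] + radius + 1));
    for (int c = clo; c <= chi; ++c) {
      double dx = c + 0.5 - cx[k];
      for (int r = rlo; r <= rhi; ++r) {
        double dy = r + 0.5 - cy[k];
        if (dx * dx + dy * dy <= r2)
          for (int ch = 0; ch < 3; ++ch)
            out[r + (size_t)H * (c + (size_t)W * ch)] = rgb[ch];
      }
    }
  }
  return out;
}
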