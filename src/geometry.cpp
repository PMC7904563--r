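// Geometry kernels: brute-force Delaunay enumeration for Voronoi vertices,
// rasterisation helpers, 8-connected labeling and Zhang-Suen thinning.
// Coordinates are 0-based pixel units, x = column, y = row.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Circumcentre of (ax,ay),(bx,by),(cx,cy); returns false if degenerate.
static bool circumcentre(double ax, double ay, double bx, double by,
                         double cx, double cy, double &ux, double &uy) {
  double d = 2.0 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-12) return false;
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by, c2 = cx * cx + cy * cy;
  ux = (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d;
  uy = (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d;
  return true;
}

// All triples of seeds whose circumcircle contains no other seed
// (the Delaunay triangles), with their circumcentres.
// [[Rcpp::export]]
List cpp_delaunay(NumericMatrix seeds) {
  int n = seeds.nrow();
  std::vector<int> ti, tj, tk;
  std::vector<double> cx, cy;
  const double eps = 1e-9;
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 1; j < n - 1; ++j) {
      for (int k = j + 1; k < n; ++k) {
        double ux, uy;
        if (!circumcentre(seeds(i, 0), seeds(i, 1), seeds(j, 0), seeds(j, 1),
                          seeds(k, 0), seeds(k, 1), ux, uy))
          continue;
        double dx = seeds(i, 0) - ux, dy = seeds(i, 1) - uy;
        double r2 = dx * dx + dy * dy;
        bool empty = true;
        for (int m = 0; m < n; ++m) {
          if (m == i || m == j || m == k) continue;
          double ex = seeds(m, 0) - ux, ey = seeds(m, 1) - uy;
          if (ex * ex + ey * ey < r2 - eps) { empty = false; break; }
        }
        if (empty) {
          ti.push_back(i + 1); tj.push_back(j + 1); tk.push_back(k + 1);
          cx.push_back(ux); cy.push_back(uy);
        }
      }
    }
  }
  IntegerMatrix tri(ti.size(), 3);
  NumericMatrix cc(ti.size(), 2);
  for (size_t t = 0; t < ti.size(); ++t) {
    tri(t, 0) = ti[t]; tri(t, 1) = tj[t]; tri(t, 2) = tk[t];
    cc(t, 0) = cx[t]; cc(t, 1) = cy[t];
  }
  return List::create(_["triangles"] = tri, _["circumcentres"] = cc);
}

// Minimum distance from each pixel centre to a set of segments
// (x1,y1,x2,y2 columns), computed only within max_dist of each segment's
// bounding box; pixels farther than max_dist from all segments get Inf.
// [[Rcpp::export]]
NumericMatrix cpp_segment_distance_map(int height, int width,
                                       NumericMatrix segs, double max_dist) {
  NumericMatrix out(height, width);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int s = 0; s < segs.nrow(); ++s) {
    double x1 = segs(s, 0), y1 = segs(s, 1), x2 = segs(s, 2), y2 = segs(s, 3);
    double vx = x2 - x1, vy = y2 - y1;
    double len2 = vx * vx + vy * vy;
    int c0 = std::max(0, (int)std::floor(std::min(x1, x2) - max_dist));
    int c1 = std::min(width - 1, (int)std::ceil(std::max(x1, x2) + max_dist));
    int r0 = std::max(0, (int)std::floor(std::min(y1, y2) - max_dist));
    int r1 = std::min(height - 1, (int)std::ceil(std::max(y1, y2) + max_dist));
    for (int r = r0; r <= r1; ++r) {
      for (int c = c0; c <= c1; ++c) {
        double px = (double)c, py = (double)r;
        double t = len2 > 0 ? ((px - x1) * vx + (py - y1) * vy) / len2 : 0.0;
        if (t < 0) t = 0; else if (t > 1) t = 1;
        double dx = px - (x1 + t * vx), dy = py - (y1 + t * vy);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < out(r, c)) out(r, c) = d;
      }
    }
  }
  return out;
}

// Label map of the nearest seed per pixel (1-based labels) and the
// distances to the nearest and second-nearest seed.
// [[Rcpp::export]]
List cpp_nearest_seed(int height, int width, NumericMatrix seeds) {
  int n = seeds.nrow();
  IntegerMatrix lab(height, width);
  NumericMatrix d1(height, width), d2(height, width);
  for (int r = 0; r < height; ++r) {
    for (int c = 0; c < width; ++c) {
      double best = R_PosInf, second = R_PosInf;
      int bi = 0;
      for (int m = 0; m < n; ++m) {
        double dx = c - seeds(m, 0), dy = r - seeds(m, 1);
        double d = dx * dx + dy * dy;
        if (d < best) { second = best; best = d; bi = m + 1; }
        else if (d < second) second = d;
      }
      lab(r, c) = bi;
      d1(r, c) = std::sqrt(best);
      d2(r, c) = std::sqrt(second);
    }
  }
  return List::create(_["labels"] = lab, _["d1"] = d1, _["d2"] = d2);
}

// 8-connected components of a binary matrix (BFS), labels 1..n.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix fg) {
  int H = fg.nrow(), W = fg.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!fg(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        int cr = q.front().first, cc = q.front().second;
        q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int nr = cr + dr, nc = cc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (fg(nr, nc) && !lab(nr, nc)) {
              lab(nr, nc) = next;
              q.push(std::make_pair(nr, nc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Zhang-Suen morphological thinning of a binary image to a 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix img) {
  int H = img.nrow(), W = img.ncol();
  LogicalMatrix a(clone(img));
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 1; r < H - 1; ++r) {
        for (int c = 1; c < W - 1; ++c) {
          if (!a(r, c)) continue;
          // neighbours p2..p9 clockwise from north
          int p[8] = { a(r - 1, c), a(r - 1, c + 1), a(r, c + 1),
                       a(r + 1, c + 1), a(r + 1, c), a(r + 1, c - 1),
                       a(r, c - 1), a(r - 1, c - 1) };
          int B = 0, A = 0;
          for (int t = 0; t < 8; ++t) {
            B += p[t];
            if (!p[t] && p[(t + 1) % 8]) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          if (pass == 0) {
            if (p[0] && p[2] && p[4]) continue;
            if (p[2] && p[4] && p[6]) continue;
          } else {
            if (p[0] && p[2] && p[6]) continue;
            if (p[0] && p[4] && p[6]) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t t = 0; t < kill.size(); ++t)
        a(kill[t].first, kill[t].second) = false;
    }
  }
  return a;
}
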