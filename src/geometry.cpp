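// Planar polygon primitives for activity-space exposure assessment.
// All polygons are simple rings given as n x 2 matrices (implicitly closed),
// coordinates in meters. No geographic CRS handling here: projection is the
// caller's job.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

static double ring_signed_area(const NumericMatrix& p) {
  const int n = p.nrow();
  double a = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    a += p(i, 0) * p(j, 1) - p(j, 0) * p(i, 1);
  }
  return 0.5 * a;
}

//' @noRd
// [[Rcpp::export(name = "poly_area_cpp")]]
double poly_area_cpp(NumericMatrix ring) {
  if (ring.nrow() < 3) return 0.0;
  return std::fabs(ring_signed_area(ring));
}

// Sutherland-Hodgman: clip a simple polygon by a CONVEX CCW polygon.
// Returns a ring with 0 rows when the intersection is empty.
// [[Rcpp::export(name = "clip_convex_cpp")]]
NumericMatrix clip_convex_cpp(NumericMatrix subject, NumericMatrix clip) {
  std::vector<double> sx, sy;
  const int ns = subject.nrow(), nc = clip.nrow();
  if (ns < 3 || nc < 3) return NumericMatrix(0, 2);
  sx.reserve(ns + nc); sy.reserve(ns + nc);
  for (int i = 0; i < ns; ++i) { sx.push_back(subject(i, 0)); sy.push_back(subject(i, 1)); }

  for (int e = 0; e < nc; ++e) {
    const double ax = clip(e, 0), ay = clip(e, 1);
    const double bx = clip((e + 1) % nc, 0), by = clip((e + 1) % nc, 1);
    const double ex = bx - ax, ey = by - ay;
    std::vector<double> ox, oy;
    const int m = (int) sx.size();
    if (m == 0) break;
    ox.reserve(m + 4); oy.reserve(m + 4);
    double px = sx[m - 1], py = sy[m - 1];
    double pside = cross2(ex, ey, px - ax, py - ay);
    for (int i = 0; i < m; ++i) {
      const double cx = sx[i], cy = sy[i];
      const double cside = cross2(ex, ey, cx - ax, cy - ay);
      if (cside >= 0) {
        if (pside < 0) { // entering: add intersection
          const double t = pside / (pside - cside);
          ox.push_back(px + t * (cx - px)); oy.push_back(py + t * (cy - py));
        }
        ox.push_back(cx); oy.push_back(cy);
      } else if (pside >= 0) { // leaving: add intersection
        const double t = pside / (pside - cside);
        ox.push_back(px + t * (cx - px)); oy.push_back(py + t * (cy - py));
      }
      px = cx; py = cy; pside = cside;
    }
    sx.swap(ox); sy.swap(oy);
  }
  const int m = (int) sx.size();
  if (m < 3) return NumericMatrix(0, 2);
  NumericMatrix out(m, 2);
  for (int i = 0; i < m; ++i) { out(i, 0) = sx[i]; out(i, 1) = sy[i]; }
  return out;
}

struct Edge { double x1, y1, x2, y2, xmin, xmax; int poly; };

// Exact area of the union of a set of simple rings, by slab decomposition:
// split the x axis at every vertex and every pairwise edge crossing, then
// integrate the union of the per-polygon y-interval cross sections, which is
// linear in x inside each slab.
// [[Rcpp::export(name = "union_area_cpp")]]
double union_area_cpp(List rings) {
  std::vector<Edge> edges;
  std::vector<double> events;
  const int K = rings.size();
  for (int k = 0; k < K; ++k) {
    NumericMatrix r = rings[k];
    const int n = r.nrow();
    if (n < 3) continue;
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      Edge e;
      e.x1 = r(i, 0); e.y1 = r(i, 1); e.x2 = r(j, 0); e.y2 = r(j, 1);
      e.xmin = std::min(e.x1, e.x2); e.xmax = std::max(e.x1, e.x2);
      e.poly = k;
      edges.push_back(e);
      events.push_back(e.x1);
    }
  }
  if (edges.empty()) return 0.0;

  std::sort(edges.begin(), edges.end(),
            [](const Edge& a, const Edge& b) { return a.xmin < b.xmin; });

  // pairwise proper crossings between edges of different polygons
  const int ne = (int) edges.size();
  for (int i = 0; i < ne; ++i) {
    const Edge& a = edges[i];
    for (int j = i + 1; j < ne && edges[j].xmin < a.xmax; ++j) {
      const Edge& b = edges[j];
      if (a.poly == b.poly) continue;
      if (std::max(a.y1, a.y2) < std::min(b.y1, b.y2)) continue;
      if (std::max(b.y1, b.y2) < std::min(a.y1, a.y2)) continue;
      const double d1x = a.x2 - a.x1, d1y = a.y2 - a.y1;
      const double d2x = b.x2 - b.x1, d2y = b.y2 - b.y1;
      const double den = cross2(d1x, d1y, d2x, d2y);
      if (std::fabs(den) < 1e-14) continue;
      const double t = cross2(b.x1 - a.x1, b.y1 - a.y1, d2x, d2y) / den;
      const double s = cross2(b.x1 - a.x1, b.y1 - a.y1, d1x, d1y) / den;
      if (t > 0.0 && t < 1.0 && s > 0.0 && s < 1.0)
        events.push_back(a.x1 + t * d1x);
    }
  }

  std::sort(events.begin(), events.end());
  events.erase(std::unique(events.begin(), events.end()), events.end());

  double area = 0.0;
  std::vector<const Edge*> active;
  size_t next_edge = 0;
  std::vector<std::pair<double, double>> ivals;
  std::vector<double> ys;

  for (size_t s = 0; s + 1 < events.size(); ++s) {
    const double a = events[s], b = events[s + 1];
    const double w = b - a;
    if (w <= 1e-13) continue;
    const double m = 0.5 * (a + b);
    while (next_edge < edges.size() && edges[next_edge].xmin < b) {
      active.push_back(&edges[next_edge]); ++next_edge;
    }
    active.erase(std::remove_if(active.begin(), active.end(),
                                [a](const Edge* e) { return e->xmax <= a; }),
                 active.end());
    // per-polygon crossings of the vertical line x = m (even-odd rule)
    ivals.clear();
    std::vector<std::pair<int, double>> crossings;
    for (size_t i = 0; i < active.size(); ++i) {
      const Edge* e = active[i];
      if ((e->x1 - m) * (e->x2 - m) < 0) {
        const double t = (m - e->x1) / (e->x2 - e->x1);
        crossings.push_back(std::make_pair(e->poly, e->y1 + t * (e->y2 - e->y1)));
      }
    }
    std::sort(crossings.begin(), crossings.end());
    for (size_t i = 0; i < crossings.size();) {
      const int k = crossings[i].first;
      ys.clear();
      while (i < crossings.size() && crossings[i].first == k) {
        ys.push_back(crossings[i].second); ++i;
      }
      for (size_t j = 0; j + 1 < ys.size(); j += 2)
        ivals.push_back(std::make_pair(ys[j], ys[j + 1]));
    }
    if (ivals.empty()) continue;
    std::sort(ivals.begin(), ivals.end());
    double len = 0.0, lo = ivals[0].first, hi = ivals[0].second;
    for (size_t i = 1; i < ivals.size(); ++i) {
      if (ivals[i].first > hi) { len += hi - lo; lo = ivals[i].first; hi = ivals[i].second; }
      else hi = std::max(hi, ivals[i].second);
    }
    len += hi - lo;
    area += w * len;
  }
  return area;
}

static double point_seg_dist(double px, double py, double x1, double y1,
                             double x2, double y2) {
  const double dx = x2 - x1, dy = y2 - y1;
  const double l2 = dx * dx + dy * dy;
  double t = 0.0;
  if (l2 > 0) t = std::max(0.0, std::min(1.0, ((px - x1) * dx + (py - y1) * dy) / l2));
  const double qx = x1 + t * dx - px, qy = y1 + t * dy - py;
  return std::sqrt(qx * qx + qy * qy);
}

// Euclidean distance from a point to a polygon: 0 when the point lies inside
// (even-odd rule), otherwise the minimum distance to the boundary.
// [[Rcpp::export(name = "point_poly_dist_cpp")]]
double point_poly_dist_cpp(double px, double py, NumericMatrix ring) {
  const int n = ring.nrow();
  if (n < 3) return R_PosInf;
  bool inside = false;
  double dmin = R_PosInf;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    const double xi = ring(i, 0), yi = ring(i, 1);
    const double xj = ring(j, 0), yj = ring(j, 1);
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
      inside = !inside;
    dmin = std::min(dmin, point_seg_dist(px, py, xi, yi, xj, yj));
  }
  return inside ? 0.0 : dmin;
}
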