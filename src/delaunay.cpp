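// Incremental Bowyer-Watson Delaunay triangulation in 2D, with the dual
// Voronoi quantities needed for tessellation-based density analysis:
// per-point cell area (NA for convex-hull points, whose cells are unbounded),
// the Delaunay edge list with the length of the dual Voronoi edge (zero-length
// duals arise from cocircular configurations and are reported so callers can
// drop them from adjacency), and a hull flag per point.
//
// Coordinates are normalised to the unit box before triangulating; the
// super-triangle is placed at distance ~1e3 so that incircle determinants stay
// well inside double precision while its vertices remain outside every
// circumcircle of interior triangles.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>

using namespace Rcpp;

namespace {

struct Tri {
  int v[3];   // vertex indices, CCW
  int nb[3];  // nb[i]: triangle across the edge opposite v[i], -1 if none
  bool alive;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// sign of orient2d with a floating-point error bound: -1, 0 (degenerate), +1
inline int orient_sign(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  const double t1 = (bx - ax) * (cy - ay);
  const double t2 = (by - ay) * (cx - ax);
  const double det = t1 - t2;
  const double bound = 4.0e-16 * (std::fabs(t1) + std::fabs(t2));
  if (det > bound) return 1;
  if (det < -bound) return -1;
  return 0;
}

// sign of the incircle determinant for CCW (a,b,c) against d, with a
// Shewchuk-style relative error bound; 0 means numerically cocircular
inline int incircle_sign(double ax, double ay, double bx, double by,
                         double cx, double cy, double dx, double dy) {
  const double adx = ax - dx, ady = ay - dy;
  const double bdx = bx - dx, bdy = by - dy;
  const double cdx = cx - dx, cdy = cy - dy;
  const double alift = adx * adx + ady * ady;
  const double blift = bdx * bdx + bdy * bdy;
  const double clift = cdx * cdx + cdy * cdy;
  const double det = alift * (bdx * cdy - bdy * cdx) +
                     blift * (cdx * ady - cdy * adx) +
                     clift * (adx * bdy - ady * bdx);
  const double perm =
      alift * (std::fabs(bdx * cdy) + std::fabs(bdy * cdx)) +
      blift * (std::fabs(cdx * ady) + std::fabs(cdy * adx)) +
      clift * (std::fabs(adx * bdy) + std::fabs(ady * bdx));
  const double bound = 1.2e-15 * perm;
  if (det > bound) return 1;
  if (det < -bound) return -1;
  return 0;
}

class Delaunay {
 public:
  std::vector<double> px, py;  // normalised coordinates, super verts appended
  std::vector<Tri> tris;
  int n;  // number of real points
  double eps;

  explicit Delaunay(const NumericMatrix& pts) {
    n = pts.nrow();
    px.resize(n + 3);
    py.resize(n + 3);
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, pts(i, 0)); xmax = std::max(xmax, pts(i, 0));
      ymin = std::min(ymin, pts(i, 1)); ymax = std::max(ymax, pts(i, 1));
    }
    scale = std::max(std::max(xmax - xmin, ymax - ymin), 1e-300);
    x0 = xmin; y0 = ymin;
    for (int i = 0; i < n; ++i) {
      px[i] = (pts(i, 0) - x0) / scale;
      py[i] = (pts(i, 1) - y0) / scale;
    }
    const double R = 1e3;
    px[n] = -R;      py[n] = -R;
    px[n + 1] = R;   py[n + 1] = -R;
    px[n + 2] = 0.5; py[n + 2] = R;
    eps = 1e-12;

    Tri t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2;
    t0.nb[0] = t0.nb[1] = t0.nb[2] = -1;
    t0.alive = true;
    tris.push_back(t0);
    last = 0;
    for (int i = 0; i < n; ++i) insert(i);
  }

  double unscale_area(double a) const { return a * scale * scale; }
  double unscale_len(double l) const { return l * scale; }

  bool is_super(int t) const {
    return tris[t].v[0] >= n || tris[t].v[1] >= n || tris[t].v[2] >= n;
  }

  // circumcenter in normalised coordinates
  void circumcenter(int t, double& cx, double& cy) const {
    const Tri& T = tris[t];
    const double ax = px[T.v[0]], ay = py[T.v[0]];
    const double bx = px[T.v[1]], by = py[T.v[1]];
    const double cx2 = px[T.v[2]], cy2 = py[T.v[2]];
    const double d = 2.0 * orient2d(ax, ay, bx, by, cx2, cy2);
    const double a2 = ax * ax + ay * ay;
    const double b2 = bx * bx + by * by;
    const double c2 = cx2 * cx2 + cy2 * cy2;
    cx = (a2 * (by - cy2) + b2 * (cy2 - ay) + c2 * (ay - by)) / d;
    cy = (a2 * (cx2 - bx) + b2 * (ax - cx2) + c2 * (bx - ax)) / d;
  }

 private:
  double scale, x0, y0;
  int last;  // triangle where the previous point landed (walk start)

  int locate(double x, double y) {
    int t = (last >= 0 && last < (int)tris.size() && tris[last].alive)
                ? last : first_alive();
    const int maxiter = (int)tris.size() + 16;
    for (int it = 0; it < maxiter; ++it) {
      bool moved = false;
      for (int e = 0; e < 3; ++e) {
        const int a = tris[t].v[(e + 1) % 3], b = tris[t].v[(e + 2) % 3];
        if (orient_sign(px[a], py[a], px[b], py[b], x, y) < 0) {
          const int nxt = tris[t].nb[e];
          if (nxt < 0) return scan(x, y);
          t = nxt;
          moved = true;
          break;
        }
      }
      if (!moved) return t;
    }
    return scan(x, y);
  }

  int first_alive() const {
    for (int t = (int)tris.size() - 1; t >= 0; --t)
      if (tris[t].alive) return t;
    return 0;
  }

  int scan(double x, double y) const {
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      bool in = true;
      for (int e = 0; e < 3 && in; ++e) {
        const int a = tris[t].v[(e + 1) % 3], b = tris[t].v[(e + 2) % 3];
        if (orient_sign(px[a], py[a], px[b], py[b], x, y) < 0) in = false;
      }
      if (in) return t;
    }
    Rcpp::stop("point location failed (degenerate input)");
    return -1;
  }

  bool bad_for(int t, double x, double y) const {
    const Tri& T = tris[t];
    // cocircular points count as "bad" (>= -tol) so that exact lattices do
    // not create zero-area slivers when a point lands on an existing circle
    return incircle_sign(px[T.v[0]], py[T.v[0]], px[T.v[1]], py[T.v[1]],
                         px[T.v[2]], py[T.v[2]], x, y) >= 0;
  }

  void insert(int p) {
    const double x = px[p], y = py[p];
    const int t0 = locate(x, y);

    // flood fill the cavity of circumcircle-violating triangles
    std::vector<int> bad;
    std::vector<char> inbad(tris.size(), 0);
    std::vector<int> stack;
    stack.push_back(t0);
    inbad[t0] = 1;
    while (!stack.empty()) {
      const int t = stack.back();
      stack.pop_back();
      bad.push_back(t);
      for (int e = 0; e < 3; ++e) {
        const int o = tris[t].nb[e];
        if (o >= 0 && !inbad[o] && bad_for(o, x, y)) {
          inbad[o] = 1;
          stack.push_back(o);
        }
      }
    }

    // cavity boundary: edges of bad triangles whose neighbour is not bad
    struct BEdge { int a, b, outer; };
    std::vector<BEdge> boundary;
    for (int t : bad) {
      for (int e = 0; e < 3; ++e) {
        const int o = tris[t].nb[e];
        if (o < 0 || !inbad[o]) {
          BEdge be;
          be.a = tris[t].v[(e + 1) % 3];
          be.b = tris[t].v[(e + 2) % 3];
          be.outer = o;
          boundary.push_back(be);
        }
      }
    }
    for (int t : bad) tris[t].alive = false;

    // fan the cavity from p; edges (a,b) are CCW as seen from p
    std::vector<int> newidx(boundary.size());
    for (size_t k = 0; k < boundary.size(); ++k) {
      Tri T;
      T.v[0] = p; T.v[1] = boundary[k].a; T.v[2] = boundary[k].b;
      T.nb[0] = boundary[k].outer;
      T.nb[1] = T.nb[2] = -1;
      T.alive = true;
      newidx[k] = (int)tris.size();
      tris.push_back(T);
      if (boundary[k].outer >= 0) {
        Tri& O = tris[boundary[k].outer];
        for (int e = 0; e < 3; ++e) {
          const int oa = O.v[(e + 1) % 3], ob = O.v[(e + 2) % 3];
          if ((oa == boundary[k].a && ob == boundary[k].b) ||
              (oa == boundary[k].b && ob == boundary[k].a)) {
            O.nb[e] = newidx[k];
            break;
          }
        }
      }
    }
    // stitch neighbouring fan triangles: edge (p, a) of T_k matches the fan
    // triangle whose third vertex equals a
    for (size_t k = 0; k < boundary.size(); ++k) {
      for (size_t j = 0; j < boundary.size(); ++j) {
        if (j == k) continue;
        if (boundary[j].b == boundary[k].a) tris[newidx[k]].nb[2] = newidx[j];
        if (boundary[j].a == boundary[k].b) tris[newidx[k]].nb[1] = newidx[j];
      }
    }
    last = newidx.empty() ? first_alive() : newidx[0];
  }
};

}  // namespace

// [[Rcpp::export(name = ".delaunay_voronoi")]]
List delaunay_voronoi(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) stop("need at least 3 points");
  Delaunay D(pts);

  // hull flag: incident to an alive triangle that uses a super vertex
  LogicalVector hull(n, false);
  const int ntri = (int)D.tris.size();
  std::vector<double> ccx(ntri, NA_REAL), ccy(ntri, NA_REAL);
  std::vector<int> incident(n, -1);
  for (int t = 0; t < ntri; ++t) {
    if (!D.tris[t].alive) continue;
    if (D.is_super(t)) {
      for (int e = 0; e < 3; ++e)
        if (D.tris[t].v[e] < n) hull[D.tris[t].v[e]] = true;
    } else {
      D.circumcenter(t, ccx[t], ccy[t]);
      for (int e = 0; e < 3; ++e) incident[D.tris[t].v[e]] = t;
    }
  }

  // Voronoi cell area of each interior point: walk the closed triangle fan
  NumericVector area(n, NA_REAL);
  for (int p = 0; p < n; ++p) {
    if (hull[p] || incident[p] < 0) continue;
    const int start = incident[p];
    int t = start;
    double a2 = 0.0;  // twice the shoelace area
    double fx = ccx[start], fy = ccy[start];
    double prevx = fx, prevy = fy;
    bool ok = true;
    int guard = 0;
    do {
      int i = -1;
      for (int e = 0; e < 3; ++e)
        if (D.tris[t].v[e] == p) { i = e; break; }
      if (i < 0) { ok = false; break; }
      const int nxt = D.tris[t].nb[(i + 2) % 3];  // across edge (p, v[i+1])
      if (nxt < 0 || D.is_super(nxt)) { ok = false; break; }
      t = nxt;
      a2 += prevx * ccy[t] - ccx[t] * prevy;
      prevx = ccx[t]; prevy = ccy[t];
      if (++guard > ntri) { ok = false; break; }
    } while (t != start);
    if (ok) area[p] = D.unscale_area(std::fabs(a2) / 2.0);
  }

  // Delaunay edges between real points with dual Voronoi edge length
  std::vector<int> ei, ej;
  std::vector<double> elen;
  for (int t = 0; t < ntri; ++t) {
    if (!D.tris[t].alive || D.is_super(t)) continue;
    for (int e = 0; e < 3; ++e) {
      const int u = D.tris[t].v[(e + 1) % 3], w = D.tris[t].v[(e + 2) % 3];
      const int o = D.tris[t].nb[e];
      const bool unbounded = (o < 0) || D.is_super(o);
      if (!unbounded && o < t) continue;  // emit shared edge once
      double vl;
      if (unbounded) {
        vl = -1.0;  // dual ray, infinite length
      } else {
        const double dx = ccx[t] - ccx[o], dy = ccy[t] - ccy[o];
        vl = D.unscale_len(std::sqrt(dx * dx + dy * dy));
      }
      ei.push_back(u + 1);
      ej.push_back(w + 1);
      elen.push_back(vl);
    }
  }

  return List::create(_["area"] = area, _["hull"] = hull,
                      _["edge_i"] = wrap(ei), _["edge_j"] = wrap(ej),
                      _["edge_vlen"] = wrap(elen));
}

// [[Rcpp::export(name = ".nn_index")]]
IntegerVector nn_index(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("empty reference point set");
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < nr; ++i) {
    xmin = std::min(xmin, ref(i, 0)); xmax = std::max(xmax, ref(i, 0));
    ymin = std::min(ymin, ref(i, 1)); ymax = std::max(ymax, ref(i, 1));
  }
  const int g = std::max(1, (int)std::floor(std::sqrt((double)nr)));
  const double dx = std::max((xmax - xmin) / g, 1e-300);
  const double dy = std::max((ymax - ymin) / g, 1e-300);
  std::vector<std::vector<int>> cells(g * g);
  for (int i = 0; i < nr; ++i) {
    int cx = std::min(g - 1, std::max(0, (int)((ref(i, 0) - xmin) / dx)));
    int cy = std::min(g - 1, std::max(0, (int)((ref(i, 1) - ymin) / dy)));
    cells[cy * g + cx].push_back(i);
  }
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    const double qx = query(q, 0), qy = query(q, 1);
    int ccx = std::min(g - 1, std::max(0, (int)((qx - xmin) / dx)));
    int ccy = std::min(g - 1, std::max(0, (int)((qy - ymin) / dy)));
    int best = -1;
    double bestd = R_PosInf;
    for (int ring = 0; ring < 2 * g; ++ring) {
      if (best >= 0) {
        // closest possible point in this ring
        const double mind = (ring - 1) * std::min(dx, dy);
        if (ring > 0 && mind > 0 && mind * mind > bestd) break;
      }
      bool any = false;
      for (int iy = ccy - ring; iy <= ccy + ring; ++iy) {
        if (iy < 0 || iy >= g) continue;
        for (int ix = ccx - ring; ix <= ccx + ring; ++ix) {
          if (ix < 0 || ix >= g) continue;
          if (std::max(std::abs(ix - ccx), std::abs(iy - ccy)) != ring)
            continue;
          any = true;
          for (int i : cells[iy * g + ix]) {
            const double ddx = ref(i, 0) - qx, ddy = ref(i, 1) - qy;
            const double d = ddx * ddx + ddy * ddy;
            if (d < bestd) { bestd = d; best = i; }
          }
        }
      }
      if (!any && best >= 0) break;
    }
    if (best < 0) {  // fallback (should not happen)
      for (int i = 0; i < nr; ++i) {
        const double ddx = ref(i, 0) - qx, ddy = ref(i, 1) - qy;
        const double d = ddx * ddx + ddy * ddy;
        if (d < bestd) { bestd = d; best = i; }
      }
    }
    out[q] = best + 1;
  }
  return out;
}
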