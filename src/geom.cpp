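// Low-level planar geometry used across the package:
//  - even-odd point-in-ring tests with boundary detection
//  - Bowyer-Watson Delaunay triangulation (characteristic hull, rubbersheet TIN)
//  - union of convex polygons via boundary fragments (k-LoCoH isopleths)
// All routines are planar Cartesian; tolerances scale with the data extent.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <map>
using namespace Rcpp;

static inline double cross3(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

static inline double seg_point_dist2(double px, double py, double ax, double ay,
                                     double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  double L2 = dx * dx + dy * dy;
  double t = L2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / L2 : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  double qx = ax + t * dx - px, qy = ay + t * dy - py;
  return qx * qx + qy * qy;
}

// Even-odd crossing-number classification of points against one ring.
// Returns 0 = outside, 1 = strictly inside, 2 = on boundary (within tol).
// [[Rcpp::export]]
IntegerVector points_in_ring_cpp(NumericVector px, NumericVector py,
                                 NumericMatrix ring, double tol) {
  int n = px.size(), m = ring.nrow();
  IntegerVector out(n);
  double tol2 = tol * tol;
  for (int i = 0; i < n; ++i) {
    double x = px[i], y = py[i];
    bool boundary = false, inside = false;
    for (int j = 0; j < m; ++j) {
      int k = (j + 1) % m;
      double ax = ring(j, 0), ay = ring(j, 1);
      double bx = ring(k, 0), by = ring(k, 1);
      if (seg_point_dist2(x, y, ax, ay, bx, by) <= tol2) { boundary = true; break; }
      // crossing test on the upward-open edge
      if ((ay > y) != (by > y)) {
        double xi = ax + (y - ay) / (by - ay) * (bx - ax);
        if (x < xi) inside = !inside;
      }
    }
    out[i] = boundary ? 2 : (inside ? 1 : 0);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bowyer-Watson Delaunay triangulation
// ---------------------------------------------------------------------------
// Coordinates are normalised to the unit box and all orientation/in-circle
// decisions are made with long-double determinants on the normalised
// coordinates (no cached circumcentres), which keeps the predicates
// consistent for the long collinear runs and cocircular rings that
// field-layout point patterns produce. A deterministic jitter of
// ~jitter_rel of the span enforces general position; the topology is
// returned against the original coordinates.

struct Tri {
  int a, b, c;   // vertex indices, counter-clockwise
  bool alive;
};

static inline long double orient_ld(long double ax, long double ay,
                                    long double bx, long double by,
                                    long double cx, long double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff p lies strictly inside the circumcircle of CCW triangle (a,b,c)
static inline long double incircle_ld(long double ax, long double ay,
                                      long double bx, long double by,
                                      long double cx, long double cy,
                                      long double px, long double py) {
  long double adx = ax - px, ady = ay - py;
  long double bdx = bx - px, bdy = by - py;
  long double cdx = cx - px, cdy = cy - py;
  long double ad = adx * adx + ady * ady;
  long double bd = bdx * bdx + bdy * bdy;
  long double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - cdy * bd)
       - ady * (bdx * cd - cdx * bd)
       + ad  * (bdx * cdy - cdx * bdy);
}

// Triangulate points; returns 1-based ntri x 3 index matrix, counter-clockwise.
// [[Rcpp::export]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y,
                           double jitter_rel = 1e-6) {
  int n = x.size();
  if (n < 3) stop("need at least 3 points for a triangulation");
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) stop("all points coincide");
  double cx0 = (xmin + xmax) / 2, cy0 = (ymin + ymax) / 2;

  // normalised, deterministically jittered coordinates
  std::vector<long double> X(n + 3), Y(n + 3);
  unsigned long long s = 88172645463325252ULL;
  for (int i = 0; i < n; ++i) {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    double u1 = (double)(s % 1000003) / 1000003.0;
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    double u2 = (double)(s % 1000003) / 1000003.0;
    X[i] = ((long double)x[i] - cx0) / span + (long double)((u1 - 0.5) * jitter_rel);
    Y[i] = ((long double)y[i] - cy0) / span + (long double)((u2 - 0.5) * jitter_rel);
  }
  // super-triangle, comfortably outside the unit box (CCW)
  X[n] = -40.0L; Y[n] = -20.0L;
  X[n + 1] = 40.0L; Y[n + 1] = -20.0L;
  X[n + 2] = 0.0L; Y[n + 2] = 40.0L;

  std::vector<Tri> tris;
  { Tri t; t.a = n; t.b = n + 1; t.c = n + 2; t.alive = true; tris.push_back(t); }

  for (int ip = 0; ip < n; ++ip) {
    long double px = X[ip], py = Y[ip];
    // directed edges of the dead (cavity) triangles
    std::map<std::pair<int,int>, int> dir;
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      if (incircle_ld(X[tris[t].a], Y[tris[t].a], X[tris[t].b], Y[tris[t].b],
                      X[tris[t].c], Y[tris[t].c], px, py) > 0.0L) {
        dir[std::make_pair(tris[t].a, tris[t].b)]++;
        dir[std::make_pair(tris[t].b, tris[t].c)]++;
        dir[std::make_pair(tris[t].c, tris[t].a)]++;
        tris[t].alive = false;
      }
    }
    // cavity boundary: directed edges whose reverse is not in the cavity
    for (std::map<std::pair<int,int>, int>::iterator it = dir.begin();
         it != dir.end(); ++it) {
      if (it->second > 1) stop("triangulation failed (inconsistent cavity)");
      int u = it->first.first, v = it->first.second;
      if (dir.count(std::make_pair(v, u))) continue;
      Tri t;
      long double cr = orient_ld(X[u], Y[u], X[v], Y[v], px, py);
      if (cr >= 0.0L) { t.a = u; t.b = v; }
      else            { t.a = v; t.b = u; }
      t.c = ip; t.alive = true;
      tris.push_back(t);
    }
  }

  // drop triangles using super-triangle vertices, compact
  std::vector<int> keep;
  for (size_t t = 0; t < tris.size(); ++t) {
    if (!tris[t].alive) continue;
    if (tris[t].a >= n || tris[t].b >= n || tris[t].c >= n) continue;
    keep.push_back((int)t);
  }
  std::vector<Tri> fin;
  for (size_t i = 0; i < keep.size(); ++i) fin.push_back(tris[keep[i]]);
  // make every triangle CCW in the jittered coordinates
  for (size_t i = 0; i < fin.size(); ++i) {
    if (orient_ld(X[fin[i].a], Y[fin[i].a], X[fin[i].b], Y[fin[i].b],
                  X[fin[i].c], Y[fin[i].c]) < 0.0L) {
      int tmp = fin[i].b; fin[i].b = fin[i].c; fin[i].c = tmp;
    }
  }
  // Convexification repair: a finite super-triangle can clip hull slivers
  // whose circumcircles are enormous, leaving shallow pockets on the hull.
  // Fill every boundary notch (right turn) with an ear triangle until the
  // boundary is convex, so the triangulation covers the convex hull.
  for (int pass = 0; pass < n + 8; ++pass) {
    std::map<std::pair<int,int>, int> und;
    for (size_t i = 0; i < fin.size(); ++i) {
      int vv[3] = { fin[i].a, fin[i].b, fin[i].c };
      for (int e = 0; e < 3; ++e) {
        int u = vv[e], v = vv[(e + 1) % 3];
        und[u < v ? std::make_pair(u, v) : std::make_pair(v, u)]++;
      }
    }
    // directed boundary edges and per-vertex degrees
    std::vector<std::pair<int,int> > bedge;
    std::map<int,int> outdeg;
    std::map<int,int> outedge; // from -> index in bedge (only if outdeg 1)
    for (size_t i = 0; i < fin.size(); ++i) {
      int vv[3] = { fin[i].a, fin[i].b, fin[i].c };
      for (int e = 0; e < 3; ++e) {
        int u = vv[e], v = vv[(e + 1) % 3];
        std::pair<int,int> k = u < v ? std::make_pair(u, v)
                                     : std::make_pair(v, u);
        if (und[k] == 1) {
          bedge.push_back(std::make_pair(u, v));
          outdeg[u]++;
          outedge[u] = (int)bedge.size() - 1;
        }
      }
    }
    std::vector<int> bverts;
    for (std::map<int,int>::iterator it = outdeg.begin(); it != outdeg.end();
         ++it) bverts.push_back(it->first);
    bool changed = false;
    for (size_t i = 0; i < bedge.size() && !changed; ++i) {
      int u = bedge[i].first, w = bedge[i].second;
      if (outdeg[w] != 1) continue; // skip pinch vertices
      int v = bedge[outedge[w]].second;
      if (v == u) continue;
      if (orient_ld(X[u], Y[u], X[w], Y[w], X[v], Y[v]) >= 0.0L) continue;
      // candidate ear (u, w, v): no other boundary vertex strictly inside
      bool blocked = false;
      for (size_t b = 0; b < bverts.size() && !blocked; ++b) {
        int q = bverts[b];
        if (q == u || q == w || q == v) continue;
        if (orient_ld(X[u], Y[u], X[v], Y[v], X[q], Y[q]) > 0.0L &&
            orient_ld(X[v], Y[v], X[w], Y[w], X[q], Y[q]) > 0.0L &&
            orient_ld(X[w], Y[w], X[u], Y[u], X[q], Y[q]) > 0.0L)
          blocked = true;
      }
      if (blocked) continue;
      Tri t; t.a = u; t.b = v; t.c = w; t.alive = true; // CCW filler
      fin.push_back(t);
      changed = true;
    }
    if (!changed) break;
  }
  IntegerMatrix out(fin.size(), 3);
  for (size_t i = 0; i < fin.size(); ++i) {
    Tri &t = fin[i];
    out(i, 0) = t.a + 1; out(i, 1) = t.b + 1; out(i, 2) = t.c + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Union of convex polygons
// ---------------------------------------------------------------------------
// Boundary-fragment construction: every hull edge is clipped against the
// strict interiors of all other hulls; surviving sub-segments whose right
// side is exterior to every hull form the directed boundary of the union
// (outer rings counter-clockwise, holes clockwise). Area follows from
// Green's theorem; rings are stitched for hole/component counts.

struct Frag { double ax, ay, bx, by; bool used; };

static inline bool point_in_convex_closed(const std::vector<double> &hx,
                                          const std::vector<double> &hy,
                                          double px, double py, double dtol) {
  int m = hx.size();
  for (int j = 0; j < m; ++j) {
    int k = (j + 1) % m;
    double ex = hx[k] - hx[j], ey = hy[k] - hy[j];
    double len = std::sqrt(ex * ex + ey * ey);
    if (len <= 0) continue;
    double d = ((px - hx[j]) * ey - (py - hy[j]) * ex) / len; // >0 right of edge
    if (d > dtol) return false;  // outside this half-plane (CCW interior left)
  }
  return true;
}

// [[Rcpp::export]]
List convex_union_cpp(List hulls, double snap_rel = 1e-7, bool debug_frags = false) {
  int H = hulls.size();
  std::vector< std::vector<double> > hx(H), hy(H);
  std::vector<double> bx0(H), bx1(H), by0(H), by1(H);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int h = 0; h < H; ++h) {
    NumericMatrix m = hulls[h];
    int n = m.nrow();
    hx[h].resize(n); hy[h].resize(n);
    bx0[h] = R_PosInf; bx1[h] = R_NegInf; by0[h] = R_PosInf; by1[h] = R_NegInf;
    for (int i = 0; i < n; ++i) {
      hx[h][i] = m(i, 0); hy[h][i] = m(i, 1);
      bx0[h] = std::min(bx0[h], m(i, 0)); bx1[h] = std::max(bx1[h], m(i, 0));
      by0[h] = std::min(by0[h], m(i, 1)); by1[h] = std::max(by1[h], m(i, 1));
    }
    xmin = std::min(xmin, bx0[h]); xmax = std::max(xmax, bx1[h]);
    ymin = std::min(ymin, by0[h]); ymax = std::max(ymax, by1[h]);
  }
  double scale = std::max(xmax - xmin, ymax - ymin);
  if (!(scale > 0)) scale = 1.0;
  double dtol = 1e-11 * scale;      // strict-interior band
  double eps_off = 1e-6 * scale;    // side-probe offset
  double snap = snap_rel * scale;   // node snapping for stitching

  std::vector<Frag> frags;
  std::vector<double> t0s, t1s;
  for (int h = 0; h < H; ++h) {
    int m = hx[h].size();
    for (int e = 0; e < m; ++e) {
      int f = (e + 1) % m;
      double ax = hx[h][e], ay = hy[h][e], bx = hx[h][f], by = hy[h][f];
      double ex = bx - ax, ey = by - ay;
      double elen = std::sqrt(ex * ex + ey * ey);
      if (elen <= snap) continue;
      // subtract strict-interior intervals of other hulls
      t0s.clear(); t1s.clear();
      for (int g = 0; g < H; ++g) {
        if (g == h) continue;
        // bbox prefilter
        if (std::max(ax, bx) < bx0[g] - dtol || std::min(ax, bx) > bx1[g] + dtol ||
            std::max(ay, by) < by0[g] - dtol || std::min(ay, by) > by1[g] + dtol)
          continue;
        double lo = 0.0, hi = 1.0;
        int mg = hx[g].size();
        bool empty = false;
        for (int j = 0; j < mg && !empty; ++j) {
          int k = (j + 1) % mg;
          double gx = hx[g][k] - hx[g][j], gy = hy[g][k] - hy[g][j];
          double glen = std::sqrt(gx * gx + gy * gy);
          if (glen <= 0) continue;
          // signed distance to the edge line: cross(p - j, g) / |g| is
          // positive when p lies RIGHT of the directed edge, so the (CCW)
          // interior side is v = -that > dtol.
          double da = ((ax - hx[g][j]) * gy - (ay - hy[g][j]) * gx) / glen;
          double db = ((bx - hx[g][j]) * gy - (by - hy[g][j]) * gx) / glen;
          double va = -da, vb = -db;
          if (std::fabs(va) <= dtol && std::fabs(vb) <= dtol) {
            // whole edge collinear with this g-edge's line: the line
            // supports g, so no part of the edge is strictly interior to g.
            // The shared stretch is removed when the two hulls face each
            // other across it (interior edge) and deduped by hull priority
            // when they lie on the same side (only the lowest-index hull
            // keeps it); then skip g.
            bool samedir = gx * ex + gy * ey > 0;
            if (!samedir || g < h) {
              double tl = ((hx[g][j] - ax) * ex + (hy[g][j] - ay) * ey) /
                          (elen * elen);
              double tu = ((hx[g][k] - ax) * ex + (hy[g][k] - ay) * ey) /
                          (elen * elen);
              if (tl > tu) std::swap(tl, tu);
              tl = std::max(tl, 0.0); tu = std::min(tu, 1.0);
              if (tu > tl) { t0s.push_back(tl); t1s.push_back(tu); }
            }
            empty = true; break;
          }
          if (va <= dtol && vb <= dtol) { empty = true; break; }
          if (va > dtol && vb > dtol) continue;
          double t = (dtol - va) / (vb - va); // crossing of v == dtol
          if (va <= dtol) lo = std::max(lo, t); else hi = std::min(hi, t);
          if (lo >= hi) { empty = true; break; }
        }
        if (!empty && lo < hi) { t0s.push_back(lo); t1s.push_back(hi); }
      }
      // merge intervals, take complement in [0,1]
      std::vector<std::pair<double,double> > iv;
      for (size_t i = 0; i < t0s.size(); ++i)
        iv.push_back(std::make_pair(t0s[i], t1s[i]));
      std::sort(iv.begin(), iv.end());
      std::vector<std::pair<double,double> > kept;
      double cur = 0.0;
      for (size_t i = 0; i < iv.size(); ++i) {
        if (iv[i].first > cur) kept.push_back(std::make_pair(cur, iv[i].first));
        cur = std::max(cur, iv[i].second);
      }
      if (cur < 1.0) kept.push_back(std::make_pair(cur, 1.0));
      double min_t = snap / elen;
      for (size_t i = 0; i < kept.size(); ++i) {
        double ta = kept[i].first, tb = kept[i].second;
        if (tb - ta <= min_t) continue;
        double fax = ax + ta * ex, fay = ay + ta * ey;
        double fbx = ax + tb * ex, fby = ay + tb * ey;
        // side probe: right of fragment direction must be outside every hull
        double mx = (fax + fbx) / 2, my = (fay + fby) / 2;
        double ux = ex / elen, uy = ey / elen;
        double prx = mx + eps_off * uy, pry = my - eps_off * ux;
        bool interior = false;
        for (int g = 0; g < H && !interior; ++g) {
          if (prx < bx0[g] - eps_off || prx > bx1[g] + eps_off ||
              pry < by0[g] - eps_off || pry > by1[g] + eps_off) continue;
          if (point_in_convex_closed(hx[g], hy[g], prx, pry, dtol))
            interior = true;
        }
        if (interior) continue;
        Frag fr; fr.ax = fax; fr.ay = fay; fr.bx = fbx; fr.by = fby;
        fr.used = false;
        frags.push_back(fr);
      }
    }
  }

  // dedupe collinear duplicates (identical directed fragments after snapping)
  std::map< std::pair< std::pair<long long,long long>,
                       std::pair<long long,long long> >, int > seen;
  std::vector<Frag> uf;
  for (size_t i = 0; i < frags.size(); ++i) {
    long long ka = (long long)std::llround(frags[i].ax / snap);
    long long kb = (long long)std::llround(frags[i].ay / snap);
    long long kc = (long long)std::llround(frags[i].bx / snap);
    long long kd = (long long)std::llround(frags[i].by / snap);
    std::pair< std::pair<long long,long long>, std::pair<long long,long long> >
      key(std::make_pair(ka, kb), std::make_pair(kc, kd));
    if (seen.count(key)) continue;
    seen[key] = 1;
    uf.push_back(frags[i]);
  }

  // Green's theorem area over directed boundary fragments
  double area2 = 0.0;
  for (size_t i = 0; i < uf.size(); ++i)
    area2 += uf[i].ax * uf[i].by - uf[i].bx * uf[i].ay;
  double area = area2 / 2.0;

  // stitch rings: junction coordinates computed from different hull pairs
  // can differ by ~dtol / sin(crossing angle), so matching is gap-tolerant:
  // candidate outgoing fragments are all unused fragments starting within
  // `join_tol` of the current endpoint; among them the sharpest left turn
  // continues the face traversal (interior kept on the left).
  double join_tol = 4.0 * snap;
  double jt2 = join_tol * join_tol;
  std::map< std::pair<long long,long long>, std::vector<int> > starts;
  for (size_t i = 0; i < uf.size(); ++i) {
    long long ka = (long long)std::llround(uf[i].ax / snap);
    long long kb = (long long)std::llround(uf[i].ay / snap);
    starts[std::make_pair(ka, kb)].push_back((int)i);
  }
  List rings;
  std::vector<double> ring_areas;
  int n_holes = 0, n_outer = 0;
  for (size_t i0 = 0; i0 < uf.size(); ++i0) {
    if (uf[i0].used) continue;
    std::vector<int> path;
    int cur = (int)i0;
    double sx = uf[i0].ax, sy = uf[i0].ay;
    bool closed = false;
    for (int guard = 0; guard < (int)uf.size() + 5; ++guard) {
      uf[cur].used = true;
      path.push_back(cur);
      double ex = uf[cur].bx, ey = uf[cur].by;
      if (path.size() >= 2 &&
          (ex - sx) * (ex - sx) + (ey - sy) * (ey - sy) <= jt2) {
        closed = true; break;
      }
      // choose the unused outgoing fragment making the sharpest left turn
      double inx = uf[cur].bx - uf[cur].ax, iny = uf[cur].by - uf[cur].ay;
      double ang_in = std::atan2(-iny, -inx); // reversed incoming
      int best = -1; double best_cw = 1e18;
      // fast path: fragments whose snapped start key matches this endpoint
      long long ka = (long long)std::llround(ex / snap);
      long long kb = (long long)std::llround(ey / snap);
      std::map< std::pair<long long,long long>, std::vector<int> >::iterator it =
        starts.find(std::make_pair(ka, kb));
      if (it != starts.end()) {
        for (size_t j = 0; j < it->second.size(); ++j) {
          int cand = it->second[j];
          if (uf[cand].used) continue;
          double dx = uf[cand].ax - ex, dy = uf[cand].ay - ey;
          if (dx * dx + dy * dy > jt2) continue;
          double ox = uf[cand].bx - uf[cand].ax, oy = uf[cand].by - uf[cand].ay;
          double ang = std::atan2(oy, ox);
          double cw = ang_in - ang;
          while (cw <= 1e-12) cw += 2 * M_PI;
          while (cw > 2 * M_PI) cw -= 2 * M_PI;
          if (cw < best_cw) { best_cw = cw; best = cand; }
        }
      }
      if (best < 0) {
        // gap-tolerant fallback over all unused fragments
        for (size_t j = 0; j < uf.size(); ++j) {
          if (uf[j].used) continue;
          double dx = uf[j].ax - ex, dy = uf[j].ay - ey;
          if (dx * dx + dy * dy > jt2) continue;
          double ox = uf[j].bx - uf[j].ax, oy = uf[j].by - uf[j].ay;
          double ang = std::atan2(oy, ox);
          double cw = ang_in - ang;
          while (cw <= 1e-12) cw += 2 * M_PI;
          while (cw > 2 * M_PI) cw -= 2 * M_PI;
          if (cw < best_cw) { best_cw = cw; best = (int)j; }
        }
      }
      if (best < 0) break;
      cur = best;
    }
    if (!closed || path.size() < 2) continue;
    NumericMatrix rm(path.size(), 2);
    double a2 = 0.0;
    for (size_t j = 0; j < path.size(); ++j) {
      rm(j, 0) = uf[path[j]].ax; rm(j, 1) = uf[path[j]].ay;
      a2 += uf[path[j]].ax * uf[path[j]].by - uf[path[j]].bx * uf[path[j]].ay;
    }
    double ra = a2 / 2.0;
    if (std::fabs(ra) < 1e-12 * scale * scale) continue; // sliver
    rings.push_back(rm);
    ring_areas.push_back(ra);
    if (ra < 0) n_holes++; else n_outer++;
  }

  NumericMatrix fragm(debug_frags ? (int)uf.size() : 0, 4);
  if (debug_frags) {
    for (size_t i = 0; i < uf.size(); ++i) {
      fragm(i, 0) = uf[i].ax; fragm(i, 1) = uf[i].ay;
      fragm(i, 2) = uf[i].bx; fragm(i, 3) = uf[i].by;
    }
  }
  return List::create(_["area"] = area,
                      _["rings"] = rings,
                      _["ring_areas"] = wrap(ring_areas),
                      _["n_holes"] = n_holes,
                      _["n_components"] = n_outer,
                      _["fragments"] = fragm);
}

// Incidence of points in convex hulls (closed: boundary counts as covered).
// [[Rcpp::export]]
LogicalMatrix points_in_hulls_cpp(List hulls, NumericVector px,
                                  NumericVector py, double tol) {
  int H = hulls.size(), n = px.size();
  LogicalMatrix out(n, H);
  for (int h = 0; h < H; ++h) {
    NumericMatrix m = hulls[h];
    int mv = m.nrow();
    std::vector<double> hx(mv), hy(mv);
    double b0 = R_PosInf, b1 = R_NegInf, c0 = R_PosInf, c1 = R_NegInf;
    for (int i = 0; i < mv; ++i) {
      hx[i] = m(i, 0); hy[i] = m(i, 1);
      b0 = std::min(b0, hx[i]); b1 = std::max(b1, hx[i]);
      c0 = std::min(c0, hy[i]); c1 = std::max(c1, hy[i]);
    }
    for (int i = 0; i < n; ++i) {
      if (px[i] < b0 - tol || px[i] > b1 + tol ||
          py[i] < c0 - tol || py[i] > c1 + tol) { out(i, h) = false; continue; }
      out(i, h) = point_in_convex_closed(hx, hy, px[i], py[i], tol);
    }
  }
  return out;
}

// Any segment of ring A properly intersecting any segment of ring B
// (used with point-containment tests for polygon overlap checks).
// [[Rcpp::export]]
bool rings_cross_cpp(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  for (int i = 0; i < na; ++i) {
    int i2 = (i + 1) % na;
    double ax = a(i, 0), ay = a(i, 1), bx = a(i2, 0), by = a(i2, 1);
    double lo_x = std::min(ax, bx), hi_x = std::max(ax, bx);
    double lo_y = std::min(ay, by), hi_y = std::max(ay, by);
    for (int j = 0; j < nb; ++j) {
      int j2 = (j + 1) % nb;
      double cx = b(j, 0), cy = b(j, 1), dx = b(j2, 0), dy = b(j2, 1);
      if (std::max(cx, dx) < lo_x || std::min(cx, dx) > hi_x ||
          std::max(cy, dy) < lo_y || std::min(cy, dy) > hi_y) continue;
      double d1 = cross3(cx, cy, dx, dy, ax, ay);
      double d2 = cross3(cx, cy, dx, dy, bx, by);
      double d3 = cross3(ax, ay, bx, by, cx, cy);
      double d4 = cross3(ax, ay, bx, by, dx, dy);
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
    }
  }
  return false;
}

// First properly crossing non-adjacent segment pair of a ring, 1-based
// (i, j) with i < j, or an empty vector when the ring is simple.
// [[Rcpp::export]]
IntegerVector ring_first_self_intersection_cpp(NumericMatrix r) {
  int n = r.nrow();
  for (int i = 0; i < n - 1; ++i) {
    int i2 = (i + 1) % n;
    double ax = r(i, 0), ay = r(i, 1), bx = r(i2, 0), by = r(i2, 1);
    for (int j = i + 1; j < n; ++j) {
      if (j == i + 1 || (i == 0 && j == n - 1)) continue;
      int j2 = (j + 1) % n;
      double cx = r(j, 0), cy = r(j, 1), dx = r(j2, 0), dy = r(j2, 1);
      double d1 = cross3(cx, cy, dx, dy, ax, ay);
      double d2 = cross3(cx, cy, dx, dy, bx, by);
      double d3 = cross3(ax, ay, bx, by, cx, cy);
      double d4 = cross3(ax, ay, bx, by, dx, dy);
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        IntegerVector out(2); out[0] = i + 1; out[1] = j + 1;
        return out;
      }
    }
  }
  return IntegerVector(0);
}
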