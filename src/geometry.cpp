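// Computational geometry core for the LIV adaptive-sampling engine:
// incremental (Bowyer-Watson) Delaunay triangulation, piecewise-linear
// barycentric interpolation with a nearest-support fallback outside the
// convex hull, Voronoi cells clipped to the map rectangle, and the
// leave-one-out rebuild loop.
//
// Determinism matters more than ultimate robustness here: every run must be
// bit-reproducible from (config, seed), and the R-level oracle in the test
// suite re-drives build/evaluate through the same primitives. Predicates use
// long double with scale-relative tolerances; triangles incident to the
// three far "super" vertices are classified by an orientation rule so that
// their huge coordinates never enter an incircle determinant with only one
// super vertex involved.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

typedef long double ld;

static inline ld orient_raw(ld ax, ld ay, ld bx, ld by, ld cx, ld cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

struct Triangulation {
  std::vector<double> px, py; // n real points followed by 3 super vertices
  int n;                      // number of real points
  double scale;               // coordinate span, for relative tolerances
  std::vector<int> tv;        // 3 vertex ids per triangle
  std::vector<int> ta;        // neighbour across edge opposite local vertex k
  std::vector<char> alive;
  int hint;

  int nt() const { return (int)tv.size() / 3; }
  bool is_super(int v) const { return v >= n; }

  ld orient(int a, int b, ld qx, ld qy) const {
    return orient_raw(px[a], py[a], px[b], py[b], qx, qy);
  }

  // strictly-inside-circumcircle test for CCW triangle t
  bool in_circle(int t, ld qx, ld qy) const {
    int v0 = tv[3 * t], v1 = tv[3 * t + 1], v2 = tv[3 * t + 2];
    int nsup = (int)is_super(v0) + is_super(v1) + is_super(v2);
    ld s2 = (ld)scale * scale;
    if (nsup == 1) {
      // one vertex at (near) infinity: the circumdisk degenerates to the
      // open half-plane left of the real edge, taken in CCW order
      int k = is_super(v0) ? 0 : (is_super(v1) ? 1 : 2);
      int a = tv[3 * t + (k + 1) % 3], b = tv[3 * t + (k + 2) % 3];
      return orient(a, b, qx, qy) > (ld)1e-12 * s2;
    }
    ld adx = (ld)px[v0] - qx, ady = (ld)py[v0] - qy;
    ld bdx = (ld)px[v1] - qx, bdy = (ld)py[v1] - qy;
    ld cdx = (ld)px[v2] - qx, cdy = (ld)py[v2] - qy;
    ld ad = adx * adx + ady * ady;
    ld bd = bdx * bdx + bdy * bdy;
    ld cd = cdx * cdx + cdy * cdy;
    ld det = adx * (bdy * cd - cdy * bd)
           - ady * (bdx * cd - cdx * bd)
           + ad  * (bdx * cdy - cdx * bdy);
    // cocircular-to-rounding cases count as "outside": the triangulation
    // stays valid and diagonal choice is decided by insertion order
    return det > (ld)1e-13 * s2 * s2;
  }

  // walk towards (qx, qy); falls back to an exhaustive scan when the walk
  // stalls (possible on highly degenerate, e.g. exactly cocircular, inputs)
  int locate(ld qx, ld qy) const {
    ld tol = (ld)1e-12 * scale * scale;
    int t = -1;
    if (hint >= 0 && hint < nt() && alive[hint]) t = hint;
    if (t < 0) {
      for (int i = nt() - 1; i >= 0; --i) if (alive[i]) { t = i; break; }
    }
    int guard = 4 * nt() + 64;
    while (guard-- > 0) {
      int worst = -1;
      ld worstv = -tol;
      for (int k = 0; k < 3; ++k) {
        int a = tv[3 * t + (k + 1) % 3], b = tv[3 * t + (k + 2) % 3];
        ld o = orient(a, b, qx, qy);
        if (o < worstv) { worstv = o; worst = k; }
      }
      if (worst < 0) return t;
      int nb = ta[3 * t + worst];
      if (nb < 0) break;
      t = nb;
    }
    // exhaustive fallback: triangle maximizing the minimum edge orientation
    int best = t;
    ld bestv = -1e300;
    for (int i = 0; i < nt(); ++i) {
      if (!alive[i]) continue;
      ld mn = 1e300L;
      for (int k = 0; k < 3; ++k) {
        int a = tv[3 * i + (k + 1) % 3], b = tv[3 * i + (k + 2) % 3];
        ld o = orient(a, b, qx, qy);
        if (o < mn) mn = o;
      }
      if (mn > bestv) { bestv = mn; best = i; }
    }
    return best;
  }

  void insert(int vi) {
    ld qx = px[vi], qy = py[vi];
    int t0 = locate(qx, qy);
    // grow the cavity of triangles whose circumcircle contains the point
    std::vector<char> inc(nt(), 0);
    std::vector<int> cav, stack;
    stack.push_back(t0);
    inc[t0] = 1;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      cav.push_back(t);
      for (int k = 0; k < 3; ++k) {
        int nb = ta[3 * t + k];
        if (nb >= 0 && !inc[nb] && in_circle(nb, qx, qy)) {
          inc[nb] = 1;
          stack.push_back(nb);
        }
      }
    }
    // enforce star-shapedness: every boundary edge must see the new point
    ld tol_edge = (ld)1e-13 * scale * scale;
    bool changed = true;
    int fix_guard = nt() + 8;
    while (changed && fix_guard-- > 0) {
      changed = false;
      for (size_t ci = 0; ci < cav.size() && !changed; ++ci) {
        int t = cav[ci];
        for (int k = 0; k < 3; ++k) {
          int nb = ta[3 * t + k];
          if (nb >= 0 && inc[nb]) continue;
          int a = tv[3 * t + (k + 1) % 3], b = tv[3 * t + (k + 2) % 3];
          if (orient(a, b, qx, qy) <= tol_edge && nb >= 0) {
            inc[nb] = 1;
            cav.push_back(nb);
            changed = true;
            break;
          }
        }
      }
    }
    // collect boundary edges (a, b) with their outer neighbour
    struct BE { int a, b, outer, oldt; };
    std::vector<BE> bes;
    for (size_t ci = 0; ci < cav.size(); ++ci) {
      int t = cav[ci];
      for (int k = 0; k < 3; ++k) {
        int nb = ta[3 * t + k];
        if (nb >= 0 && inc[nb]) continue;
        BE e;
        e.a = tv[3 * t + (k + 1) % 3];
        e.b = tv[3 * t + (k + 2) % 3];
        e.outer = nb;
        e.oldt = t;
        bes.push_back(e);
      }
    }
    // fan the cavity boundary to the new vertex
    std::unordered_map<int, int> start; // boundary vertex a -> new triangle
    std::vector<int> newt(bes.size());
    for (size_t i = 0; i < bes.size(); ++i) {
      int t = nt();
      tv.push_back(bes[i].a);
      tv.push_back(bes[i].b);
      tv.push_back(vi);
      ta.push_back(-1); ta.push_back(-1); ta.push_back(bes[i].outer);
      alive.push_back(1);
      if (bes[i].outer >= 0) {
        for (int k = 0; k < 3; ++k)
          if (ta[3 * bes[i].outer + k] == bes[i].oldt)
            ta[3 * bes[i].outer + k] = t;
      }
      start[bes[i].a] = t;
      newt[i] = t;
    }
    for (size_t i = 0; i < bes.size(); ++i) {
      int T = newt[i];
      std::unordered_map<int, int>::iterator it = start.find(bes[i].b);
      if (it != start.end()) {
        int S = it->second;
        ta[3 * T + 0] = S; // edge (b, vi), opposite local vertex 0 (= a)
        ta[3 * S + 1] = T; // edge (vi, b) in S, opposite its local vertex 1
      }
    }
    for (size_t ci = 0; ci < cav.size(); ++ci) alive[cav[ci]] = 0;
    if (!bes.empty()) hint = newt[0];
  }

  void build(const std::vector<double>& x, const std::vector<double>& y) {
    n = (int)x.size();
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
    }
    scale = std::max(xmax - xmin, ymax - ymin);
    if (scale <= 0) scale = std::max(std::fabs(xmax), std::fabs(ymax));
    if (scale <= 0) scale = 1.0;
    double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
    double R = 1e3 * scale;
    px = x; py = y;
    px.push_back(cx - 3.0 * R); py.push_back(cy - 3.0 * R);
    px.push_back(cx + 3.0 * R); py.push_back(cy - 3.0 * R);
    px.push_back(cx);           py.push_back(cy + 3.0 * R);
    tv.clear(); ta.clear(); alive.clear();
    tv.push_back(n); tv.push_back(n + 1); tv.push_back(n + 2);
    ta.push_back(-1); ta.push_back(-1); ta.push_back(-1);
    alive.push_back(1);
    hint = 0;
    for (int i = 0; i < n; ++i) insert(i);
  }
};

static void check_duplicates(const std::vector<double>& x,
                             const std::vector<double>& y) {
  int n = (int)x.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  for (int i = 1; i < n; ++i)
    if (x[idx[i]] == x[idx[i - 1]] && y[idx[i]] == y[idx[i - 1]])
      stop("duplicate point");
}

static bool is_collinear(const std::vector<double>& x,
                         const std::vector<double>& y) {
  int n = (int)x.size();
  if (n < 3) return true;
  int a = 0;
  for (int i = 1; i < n; ++i)
    if (x[i] < x[a] || (x[i] == x[a] && y[i] < y[a])) a = i;
  int b = a;
  ld best = -1;
  for (int i = 0; i < n; ++i) {
    ld dx = (ld)x[i] - x[a], dy = (ld)y[i] - y[a];
    ld d = dx * dx + dy * dy;
    if (d > best) { best = d; b = i; }
  }
  if (best <= 0) return true;
  ld span = std::sqrt((double)best);
  ld tol = (ld)1e-10 * span * span;
  for (int i = 0; i < n; ++i)
    if (std::fabs((double)orient_raw(x[a], y[a], x[b], y[b], x[i], y[i])) > tol)
      return false;
  return true;
}

// Andrew's monotone chain; returns hull vertex indices in CCW order
static std::vector<int> convex_hull(const std::vector<double>& x,
                                    const std::vector<double>& y) {
  int n = (int)x.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  std::vector<int> h(2 * n);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    while (k >= 2 && orient_raw(x[h[k - 2]], y[h[k - 2]],
                                x[h[k - 1]], y[h[k - 1]],
                                x[idx[i]], y[idx[i]]) <= 0) --k;
    h[k++] = idx[i];
  }
  int lower = k + 1;
  for (int i = n - 2; i >= 0; --i) {
    while (k >= lower && orient_raw(x[h[k - 2]], y[h[k - 2]],
                                    x[h[k - 1]], y[h[k - 1]],
                                    x[idx[i]], y[idx[i]]) <= 0) --k;
    h[k++] = idx[i];
  }
  h.resize(std::max(0, k - 1));
  return h;
}

static int nearest_point(const std::vector<double>& x,
                         const std::vector<double>& y,
                         double qx, double qy) {
  int best = 0;
  ld bestd = 1e300L;
  for (int i = 0; i < (int)x.size(); ++i) {
    ld dx = (ld)x[i] - qx, dy = (ld)y[i] - qy;
    ld d = dx * dx + dy * dy;
    if (d < bestd) { bestd = d; best = i; }
  }
  return best;
}

// shared evaluation of the piecewise-linear surrogate at many queries;
// V is n x d (one column per value dimension)
static void eval_queries(Triangulation& tri,
                         const std::vector<double>& x,
                         const std::vector<double>& y,
                         const NumericMatrix& V,
                         const NumericVector& qx,
                         const NumericVector& qy,
                         NumericMatrix& out) {
  int d = V.ncol();
  std::vector<int> hull = convex_hull(x, y);
  int H = (int)hull.size();
  ld s2 = (ld)tri.scale * tri.scale;
  ld tol_hull = (ld)1e-12 * s2;
  for (int q = 0; q < qx.size(); ++q) {
    double gx = qx[q], gy = qy[q];
    // exact-vertex shortcut keeps support queries bit-identical
    bool done = false;
    for (int i = 0; i < (int)x.size(); ++i) {
      if (x[i] == gx && y[i] == gy) {
        for (int j = 0; j < d; ++j) out(q, j) = V(i, j);
        done = true;
        break;
      }
    }
    if (done) continue;
    bool outside = false;
    for (int h = 0; h < H; ++h) {
      int a = hull[h], b = hull[(h + 1) % H];
      if (orient_raw(x[a], y[a], x[b], y[b], gx, gy) < -tol_hull) {
        outside = true;
        break;
      }
    }
    int va = -1, vb = -1, vc = -1;
    if (!outside) {
      int t = tri.locate(gx, gy);
      int v0 = tri.tv[3 * t], v1 = tri.tv[3 * t + 1], v2 = tri.tv[3 * t + 2];
      if (!tri.is_super(v0) && !tri.is_super(v1) && !tri.is_super(v2)) {
        va = v0; vb = v1; vc = v2;
      } else {
        // landed on a fringe triangle: exhaustive scan of real triangles
        ld tol_in = (ld)1e-9 * s2;
        for (int i = 0; i < tri.nt() && va < 0; ++i) {
          if (!tri.alive[i]) continue;
          int w0 = tri.tv[3 * i], w1 = tri.tv[3 * i + 1], w2 = tri.tv[3 * i + 2];
          if (tri.is_super(w0) || tri.is_super(w1) || tri.is_super(w2)) continue;
          if (tri.orient(w0, w1, gx, gy) >= -tol_in &&
              tri.orient(w1, w2, gx, gy) >= -tol_in &&
              tri.orient(w2, w0, gx, gy) >= -tol_in) {
            va = w0; vb = w1; vc = w2;
          }
        }
        if (va < 0) outside = true;
      }
    }
    if (outside) {
      int i = nearest_point(x, y, gx, gy);
      for (int j = 0; j < d; ++j) out(q, j) = V(i, j);
      continue;
    }
    ld w0 = orient_raw(x[vb], y[vb], x[vc], y[vc], gx, gy);
    ld w1 = orient_raw(x[vc], y[vc], x[va], y[va], gx, gy);
    ld w2 = orient_raw(x[va], y[va], x[vb], y[vb], gx, gy);
    if (w0 < 0) w0 = 0;
    if (w1 < 0) w1 = 0;
    if (w2 < 0) w2 = 0;
    ld tot = w0 + w1 + w2;
    if (tot <= 0) { // degenerate sliver; fall back to the nearest vertex
      int i = nearest_point(x, y, gx, gy);
      for (int j = 0; j < d; ++j) out(q, j) = V(i, j);
      continue;
    }
    for (int j = 0; j < d; ++j)
      out(q, j) = (double)((w0 * V(va, j) + w1 * V(vb, j) + w2 * V(vc, j)) / tot);
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_triangulate(NumericVector x, NumericVector y) {
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  if ((int)vx.size() < 3) stop("degenerate support");
  check_duplicates(vx, vy);
  if (is_collinear(vx, vy)) stop("degenerate support");
  Triangulation tri;
  tri.build(vx, vy);
  int m = 0;
  for (int t = 0; t < tri.nt(); ++t) {
    if (!tri.alive[t]) continue;
    if (tri.is_super(tri.tv[3 * t]) || tri.is_super(tri.tv[3 * t + 1]) ||
        tri.is_super(tri.tv[3 * t + 2])) continue;
    ++m;
  }
  IntegerMatrix out(m, 3);
  int r = 0;
  for (int t = 0; t < tri.nt(); ++t) {
    if (!tri.alive[t]) continue;
    int v0 = tri.tv[3 * t], v1 = tri.tv[3 * t + 1], v2 = tri.tv[3 * t + 2];
    if (tri.is_super(v0) || tri.is_super(v1) || tri.is_super(v2)) continue;
    out(r, 0) = v0 + 1;
    out(r, 1) = v1 + 1;
    out(r, 2) = v2 + 1;
    ++r;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_interp(NumericVector x, NumericVector y, NumericMatrix V,
                         NumericVector qx, NumericVector qy) {
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  if ((int)vx.size() < 3) stop("degenerate support");
  check_duplicates(vx, vy);
  if (is_collinear(vx, vy)) stop("degenerate support");
  Triangulation tri;
  tri.build(vx, vy);
  NumericMatrix out(qx.size(), V.ncol());
  eval_queries(tri, vx, vy, V, qx, qy, out);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_loo(NumericVector x, NumericVector y, NumericMatrix V) {
  int n = x.size(), d = V.ncol();
  if (n < 3) stop("need at least 3 points");
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  check_duplicates(vx, vy);
  NumericVector eps(n);
  std::vector<double> sx(n - 1), sy(n - 1);
  NumericMatrix SV(n - 1, d);
  NumericVector qx(1), qy(1);
  NumericMatrix val(1, d);
  for (int i = 0; i < n; ++i) {
    int r = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      sx[r] = vx[j];
      sy[r] = vy[j];
      for (int c = 0; c < d; ++c) SV(r, c) = V(j, c);
      ++r;
    }
    bool degenerate = (n - 1 < 3) || is_collinear(sx, sy);
    if (degenerate) {
      int nb = nearest_point(sx, sy, vx[i], vy[i]);
      for (int c = 0; c < d; ++c) val(0, c) = SV(nb, c);
    } else {
      Triangulation tri;
      tri.build(sx, sy);
      qx[0] = vx[i];
      qy[0] = vy[i];
      eval_queries(tri, sx, sy, SV, qx, qy, val);
    }
    // square in double, accumulate in long double: exactly R's
    // sqrt(sum((v - pred)^2)), so the R-level rebuild oracle agrees
    // bit-for-bit
    ld acc = 0;
    for (int c = 0; c < d; ++c) {
      double dv = V(i, c) - val(0, c);
      double sq = dv * dv;
      acc += (ld)sq;
    }
    eps[i] = std::sqrt((double)acc);
  }
  return eps;
}

// [[Rcpp::export]]
List cpp_voronoi(NumericVector x, NumericVector y,
                 double xmin, double xmax, double ymin, double ymax) {
  int n = x.size();
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  check_duplicates(vx, vy);
  double scale = std::max(xmax - xmin, ymax - ymin);
  NumericVector areas(n);
  List polys(n);
  std::vector<double> cxv, cyv, nxv, nyv;
  for (int i = 0; i < n; ++i) {
    cxv.assign({xmin, xmax, xmax, xmin});
    cyv.assign({ymin, ymin, ymax, ymax});
    for (int j = 0; j < n; ++j) {
      if (j == i || cxv.empty()) continue;
      // keep the half-plane closer to i than to j
      double dx = vx[j] - vx[i], dy = vy[j] - vy[i];
      double mx = 0.5 * (vx[i] + vx[j]), my = 0.5 * (vy[i] + vy[j]);
      nxv.clear(); nyv.clear();
      int m = (int)cxv.size();
      for (int k = 0; k < m; ++k) {
        int k2 = (k + 1) % m;
        ld fa = ((ld)cxv[k] - mx) * dx + ((ld)cyv[k] - my) * dy;
        ld fb = ((ld)cxv[k2] - mx) * dx + ((ld)cyv[k2] - my) * dy;
        if (fa <= 0) {
          nxv.push_back(cxv[k]);
          nyv.push_back(cyv[k]);
        }
        if ((fa < 0 && fb > 0) || (fa > 0 && fb < 0)) {
          ld s = fa / (fa - fb);
          nxv.push_back((double)(cxv[k] + s * ((ld)cxv[k2] - cxv[k])));
          nyv.push_back((double)(cyv[k] + s * ((ld)cyv[k2] - cyv[k])));
        }
      }
      cxv = nxv;
      cyv = nyv;
    }
    int m = (int)cxv.size();
    ld a = 0;
    for (int k = 0; k < m; ++k) {
      int k2 = (k + 1) % m;
      a += (ld)cxv[k] * cyv[k2] - (ld)cxv[k2] * cyv[k];
    }
    areas[i] = (double)(0.5L * a);
    NumericMatrix poly(m, 2);
    for (int k = 0; k < m; ++k) {
      poly(k, 0) = cxv[k];
      poly(k, 1) = cyv[k];
    }
    polys[i] = poly;
  }
  (void)scale;
  return List::create(_["areas"] = areas, _["polygons"] = polys);
}

// [[Rcpp::export]]
IntegerVector cpp_nearest_index(NumericVector x, NumericVector y,
                                NumericVector qx, NumericVector qy) {
  IntegerVector out(qx.size());
  std::vector<double> vx(x.begin(), x.end()), vy(y.begin(), y.end());
  for (int q = 0; q < qx.size(); ++q)
    out[q] = nearest_point(vx, vy, qx[q], qy[q]) + 1;
  return out;
}
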